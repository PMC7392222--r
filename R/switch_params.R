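#' Switch parameter sets
#'
#' Constructs the parameter set of a regulatory switch with `m` elements per
#' group (two groups: the x-group and the y-group; `m = 1, 2, 3` gives the
#' two-, four-, and six-element switch). Each element has its own
#' self-activation rate (`alpha_A`) and inhibition-relief rate (`alpha_I`);
#' production of element i follows
#' `alpha_A[i] * Sx^n / (beta^n + Sx^n) + alpha_I[i] * beta^n / (beta^n + Sy^n)`
#' with `Sx`, `Sy` the group totals, and every element degrades at rate
#' `gamma` times its own level.
#'
#' @param alpha_A self-activation rates of the x-group elements
#'   (molecules/time); recycled to length `m`.
#' @param alpha_I inhibition-relief rates of the x-group elements; recycled.
#' @param beta half-saturation constant of the Hill terms (molecules).
#' @param gamma first-order degradation rate (1/time).
#' @param n Hill coefficient (integer, >= 1).
#' @param m elements per group (1, 2 or 3).
#' @param alpha_A_y,alpha_I_y y-group rates; default to the x-group values
#'   (symmetric switch).
#' @return An object of class `switch_params`.
#' @examples
#' p <- switch_params(alpha_A = 35, alpha_I = 35, beta = 45, gamma = 0.38,
#'                    n = 4, m = 1)
#' @seealso [switch_preset()] for the homeostasis parameter presets.
#' @export
switch_params <- function(alpha_A, alpha_I, beta, gamma, n, m = 1L,
                          alpha_A_y = alpha_A, alpha_I_y = alpha_I) {
  m <- as.integer(m)
  if (length(m) != 1L || is.na(m) || !m %in% 1:3)
    stop("'m' must be 1, 2 or 3 (two-, four-, six-element switch)")
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L)
    stop("'n' must be an integer >= 1")
  chk_rate <- function(x, nm, len = 1L, strict = FALSE) {
    x <- as.numeric(x)
    if (length(x) == 1L && len > 1L) x <- rep(x, len)
    if (length(x) != len) stop(sprintf("'%s' must have length 1 or %d", nm, len))
    if (any(!is.finite(x))) stop(sprintf("'%s' must be finite", nm))
    if (any(if (strict) x <= 0 else x < 0))
      stop(sprintf("'%s' must be %s", nm, if (strict) "> 0" else ">= 0"))
    x
  }
  obj <- structure(list(
    m = m, n = n,
    beta = chk_rate(beta, "beta", strict = TRUE),
    gamma = chk_rate(gamma, "gamma", strict = TRUE),
    alpha_A = chk_rate(alpha_A, "alpha_A", m),
    alpha_I = chk_rate(alpha_I, "alpha_I", m),
    alpha_A_y = chk_rate(alpha_A_y, "alpha_A_y", m),
    alpha_I_y = chk_rate(alpha_I_y, "alpha_I_y", m)
  ), class = "switch_params")
  obj
}

#' Homeostasis parameter presets
#'
#' The calibrated parameter sets for which the stem-cell birth rate is 0.5
#' (proliferation/differentiation balance): all alphas equal 35, gamma = 0.38,
#' n = 4, and beta = 45, 47.3, 48.5 for the two-, four-, and six-element
#' switch respectively.
#'
#' @param name one of `"two-element"`, `"four-element"`, `"six-element"`.
#' @return A [switch_params()] object.
#' @examples
#' switch_preset("two-element")
#' @export
switch_preset <- function(name = c("two-element", "four-element", "six-element")) {
  name <- match.arg(name)
  beta <- c("two-element" = 45, "four-element" = 47.3, "six-element" = 48.5)[[name]]
  m <- c("two-element" = 1L, "four-element" = 2L, "six-element" = 3L)[[name]]
  p <- switch_params(alpha_A = 35, alpha_I = 35, beta = beta, gamma = 0.38,
                     n = 4L, m = m)
  attr(p, "preset") <- name
  p
}

#' @export
print.switch_params <- function(x, ...) {
  nm <- attr(x, "preset")
  cat(sprintf("switch_params: %d-element switch%s\n", 2L * x$m,
              if (is.null(nm)) "" else sprintf(" (preset '%s')", nm)))
  cat(sprintf("  alpha_A (x): %s   alpha_I (x): %s\n",
              paste(x$alpha_A, collapse = ", "), paste(x$alpha_I, collapse = ", ")))
  cat(sprintf("  alpha_A (y): %s   alpha_I (y): %s\n",
              paste(x$alpha_A_y, collapse = ", "), paste(x$alpha_I_y, collapse = ", ")))
  cat(sprintf("  beta = %g, gamma = %g, n = %d\n", x$beta, x$gamma, x$n))
  invisible(x)
}

# The 2-D master-pair fate system of a switch: the tri-stable circuit of the
# two master indicators x1 and y1 alone, with their own rate constants and
# the shared beta/gamma/n. Daughter-cell fate is decided in this plane; for
# m = 1 it is the switch itself.
master_system <- function(params) {
  if (params$m == 1L) return(params)
  switch_params(alpha_A = params$alpha_A[1], alpha_I = params$alpha_I[1],
                beta = params$beta, gamma = params$gamma, n = params$n, m = 1L,
                alpha_A_y = params$alpha_A_y[1], alpha_I_y = params$alpha_I_y[1])
}

# flat alpha vector in the engine's layout:
# aA_x[1..m], aI_x[1..m], aA_y[1..m], aI_y[1..m]
alpha_vector <- function(params) {
  c(params$alpha_A, params$alpha_I, params$alpha_A_y, params$alpha_I_y)
}

alphas_to_params <- function(alpha, template) {
  m <- template$m
  switch_params(alpha_A = alpha[seq_len(m)], alpha_I = alpha[m + seq_len(m)],
                beta = template$beta, gamma = template$gamma, n = template$n,
                m = m, alpha_A_y = alpha[2 * m + seq_len(m)],
                alpha_I_y = alpha[3 * m + seq_len(m)])
}

param_key <- function(params) {
  paste(c(params$m, params$n, params$beta, params$gamma, alpha_vector(params)),
        collapse = "|")
}

state_names <- function(m) {
  c(paste0("x", seq_len(m)), paste0("y", seq_len(m)))
}

check_state <- function(state, params, integer = FALSE) {
  state <- as.numeric(state)
  if (length(state) != 2L * params$m)
    stop(sprintf("state must have length %d (x1..x%d, y1..y%d)",
                 2L * params$m, params$m, params$m))
  if (any(!is.finite(state)) || any(state < 0))
    stop("state entries must be finite and nonnegative")
  if (integer && any(state != round(state)))
    stop("stochastic states must be nonnegative integers")
  state
}
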