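# group activities and the four Hill factors shared by rhs and propensities
hill_terms <- function(state, params) {
  m <- params$m
  bn <- params$beta^params$n
  u <- sum(state[seq_len(m)]^params$n)
  v <- sum(state[m + seq_len(m)]^params$n)
  list(Hx = u / (bn + u), Rx = bn / (bn + u),
       Hy = v / (bn + v), Ry = bn / (bn + v))
}

#' Deterministic right-hand side of the switch ODEs
#'
#' Time derivative of every determinant level. Production of x-group element
#' i is `alpha_A[i] * u/(beta^n + u) + alpha_I[i] * beta^n/(beta^n + v)`,
#' where `u = x1^n + ... + xm^n` and `v = y1^n + ... + ym^n` are the group
#' activities (cooperative self-activation by the whole group, repression
#' relief against the opposing group); each element decays at `gamma` times
#' its own level. The y-group is the mirror image.
#'
#' @param state numeric vector of determinant levels, ordered
#'   `x1..xm, y1..ym` (real-valued in the deterministic setting).
#' @param params a [switch_params()] object.
#' @return Named numeric vector of derivatives, one per element.
#' @examples
#' switch_rhs(c(0, 0), switch_preset("two-element"))  # (35, 35)
#' @export
switch_rhs <- function(state, params) {
  state <- check_state(state, params)
  m <- params$m
  h <- hill_terms(state, params)
  d <- c(params$alpha_A * h$Hx + params$alpha_I * h$Ry -
           params$gamma * state[seq_len(m)],
         params$alpha_A_y * h$Hy + params$alpha_I_y * h$Rx -
           params$gamma * state[m + seq_len(m)])
  setNames(d, state_names(m))
}

#' Stochastic reaction propensities of a single cell
#'
#' The reaction channels of one cell in the Gillespie simulation: one
#' production and one degradation channel per determinant, plus one division
#' channel at rate `1 / cycle_time`. Production propensities equal the
#' deterministic production terms evaluated at the current counts;
#' degradation propensities are `gamma` times the count (zero at count
#' zero). Channels are ordered x-productions, x-degradations, y-productions,
#' y-degradations, division.
#'
#' @param state nonnegative integer determinant counts (`x1..xm, y1..ym`).
#' @param params a [switch_params()] object.
#' @param cycle_time the cell-cycle time T (> 0); the division propensity is
#'   `1 / cycle_time`.
#' @return Named numeric vector of `4 m + 1` propensities.
#' @examples
#' p <- switch_preset("two-element")
#' switch_propensities(c(45, 45), p, cycle_time(p))
#' @export
switch_propensities <- function(state, params, cycle_time) {
  state <- check_state(state, params, integer = TRUE)
  if (!is.numeric(cycle_time) || length(cycle_time) != 1L || cycle_time <= 0)
    stop("'cycle_time' must be a single positive duration")
  m <- params$m
  h <- hill_terms(state, params)
  w <- c(params$alpha_A * h$Hx + params$alpha_I * h$Ry,
         params$gamma * state[seq_len(m)],
         params$alpha_A_y * h$Hy + params$alpha_I_y * h$Rx,
         params$gamma * state[m + seq_len(m)],
         1 / cycle_time)
  setNames(w, c(paste0("prod_x", seq_len(m)), paste0("deg_x", seq_len(m)),
                paste0("prod_y", seq_len(m)), paste0("deg_y", seq_len(m)),
                "division"))
}

#' Maximum steady-state determinant content
#'
#' The largest per-group total (sum of a group's determinant levels) over all
#' stable fixed points of the switch, rounded to the nearest integer. For the
#' homeostasis presets this is the familiar scale N of the switch: 184 for
#' the two-element and 368 for the four-element switch. The value is cached
#' per parameter set.
#'
#' @param params a [switch_params()] object.
#' @return Integer N (molecules).
#' @examples
#' steady_state_max(switch_preset("two-element"))  # 184
#' @export
steady_state_max <- function(params) {
  key <- paste0("N|", param_key(params))
  if (!is.null(.tristem_cache[[key]])) return(.tristem_cache[[key]])
  fp <- find_fixed_points(params)
  st <- fp[fp$stability == "stable", , drop = FALSE]
  if (nrow(st) == 0L) stop("no stable fixed point found for these parameters")
  N <- as.integer(round(max(st$Sx, st$Sy)))
  .tristem_cache[[key]] <- N
  N
}

#' Cell-cycle time
#'
#' `T = 1.1 * ln(N)`, with N the maximum steady-state determinant content of
#' the switch ([steady_state_max()]). The natural logarithm is used, matching
#' the exponential waiting-time convention of the stochastic simulation.
#' T is a property of the (unmutated) switch family: it is computed once from
#' the founding parameter set and is not recomputed for mutated cells.
#'
#' @param x a [switch_params()] object, or a single number N.
#' @return The cycle duration T.
#' @examples
#' cycle_time(184)                          # 5.738...
#' cycle_time(switch_preset("two-element")) # same
#' @export
cycle_time <- function(x) {
  N <- if (inherits(x, "switch_params")) steady_state_max(x) else as.numeric(x)
  if (length(N) != 1L || !is.finite(N) || N <= 1)
    stop("N must be a single value > 1")
  1.1 * log(N)
}
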