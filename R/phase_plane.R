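# Deterministic phase-plane analysis: fixed points, stability, nullclines,
# attractor basins, parameter sweeps.
#
# The fixed-point problem of the 2m-dimensional switch reduces exactly to two
# dimensions. Production depends on the levels only through the group
# activities u = sum_i x_i^n and v = sum_i y_i^n, so at a fixed point
#   x_i = (alpha_A[i] * u/(b+u) + alpha_I[i] * b/(b+v)) / gamma,  b = beta^n,
# and substituting back into u, v closes a 2-D root problem. The dynamics
# Jacobian is -gamma I plus a rank-2 update, so its spectrum is
# {-gamma + eig(M)} for a 2x2 matrix M, plus -gamma with multiplicity 2m - 2;
# stability is decided by the same reduction.

uv_terms <- function(params) {
  list(bn = params$beta^params$n, n = params$n, g = params$gamma,
       aAx = params$alpha_A, aIx = params$alpha_I,
       aAy = params$alpha_A_y, aIy = params$alpha_I_y, m = params$m)
}

# element levels implied by activities (u, v); u, v may be vectors
uv_levels <- function(u, v, rt) {
  H <- u / (rt$bn + u)
  Rv <- rt$bn / (rt$bn + v)
  Hy <- v / (rt$bn + v)
  Ru <- rt$bn / (rt$bn + u)
  x <- lapply(seq_len(rt$m), function(i) pmax((rt$aAx[i] * H + rt$aIx[i] * Rv) / rt$g, 0))
  y <- lapply(seq_len(rt$m), function(i) pmax((rt$aAy[i] * Hy + rt$aIy[i] * Ru) / rt$g, 0))
  list(x = x, y = y)
}

uv_residual <- function(u, v, rt) {
  lv <- uv_levels(u, v, rt)
  list(F1 = Reduce(`+`, lapply(lv$x, function(x) x^rt$n)) - u,
       F2 = Reduce(`+`, lapply(lv$y, function(y) y^rt$n)) - v,
       levels = lv)
}

# Newton Jacobian of the (u, v) root problem and the 2x2 stability matrix M
uv_jacobians <- function(u, v, lv, rt) {
  du <- rt$bn + u
  dv <- rt$bn + v
  Hp <- rt$bn / du^2    # d(u/(b+u))/du
  Rvp <- -rt$bn / dv^2  # d(b/(b+v))/dv
  Hyp <- rt$bn / dv^2
  Rup <- -rt$bn / du^2
  Sx1 <- Sx2 <- Sy1 <- Sy2 <- 0
  for (i in seq_len(rt$m)) {
    xp <- rt$n * lv$x[[i]]^(rt$n - 1)
    yp <- rt$n * lv$y[[i]]^(rt$n - 1)
    Sx1 <- Sx1 + xp * rt$aAx[i]; Sx2 <- Sx2 + xp * rt$aIx[i]
    Sy1 <- Sy1 + yp * rt$aAy[i]; Sy2 <- Sy2 + yp * rt$aIy[i]
  }
  list(J11 = Sx1 * Hp / rt$g - 1, J12 = Sx2 * Rvp / rt$g,
       J21 = Sy2 * Rup / rt$g, J22 = Sy1 * Hyp / rt$g - 1,
       M11 = Hp * Sx1, M12 = Rvp * Sx2, M21 = Rup * Sy2, M22 = Hyp * Sy1)
}

#' Fixed points of the switch and their stability
#'
#' Enumerates the nonnegative fixed points of the switch ODEs by multi-start
#' Newton refinement of the exactly-reduced group-activity system, seeded on
#' a dense per-element grid over `[0, 1.3 * (alpha_A + alpha_I) / gamma]`.
#' Roots are deduplicated at 1e-3 (element levels) and labelled by the
#' Jacobian eigenvalues: `stable` when every real part is below -1e-9,
#' `saddle` when real parts straddle zero, `unstable` when all are positive,
#' `marginal` when any real part lies within 1e-9 of zero.
#'
#' @param params a [switch_params()] object.
#' @param grid number of Newton starts per axis (default 50).
#' @return A data frame of class `switch_fixed_points`: one row per fixed
#'   point with the full location (`x1..ym`), group totals `Sx`, `Sy`,
#'   `stability`, and the largest eigenvalue real part `max_re`. The full
#'   eigenvalue spectra are in `attr(, "eigenvalues")`.
#' @examples
#' fp <- find_fixed_points(switch_preset("two-element"))
#' table(fp$stability)  # 3 stable, 2 saddle
#' @export
find_fixed_points <- function(params, grid = 50L) {
  rt <- uv_terms(params)
  xmax <- 1.3 * (max(sum(rt$aAx), sum(rt$aAy)) + max(sum(rt$aIx), sum(rt$aIy))) /
    (rt$g * params$m)
  ax <- seq(0, xmax, length.out = grid)
  st <- expand.grid(a = ax, b = ax)
  u <- rt$m * st$a^rt$n
  v <- rt$m * st$b^rt$n
  for (it in 1:120) {
    f <- uv_residual(u, v, rt)
    J <- uv_jacobians(u, v, f$levels, rt)
    det <- J$J11 * J$J22 - J$J12 * J$J21
    det[det == 0 | !is.finite(det)] <- NA
    su <- (f$F1 * J$J22 - J$J12 * f$F2) / det
    sv <- (J$J11 * f$F2 - f$F1 * J$J21) / det
    u <- pmax(u - su, 0)
    v <- pmax(v - sv, 0)
    u[!is.finite(u)] <- NA
    v[!is.finite(v)] <- NA
  }
  ok <- is.finite(u) & is.finite(v)
  f <- uv_residual(u[ok], v[ok], rt)
  conv <- abs(f$F1) < 1e-7 * (1 + u[ok]) & abs(f$F2) < 1e-7 * (1 + v[ok])
  if (!any(conv)) {
    warning("fixed-point refinement did not converge from any start")
    return(empty_fixed_points(params))
  }
  roots <- unique(cbind(round(u[ok][conv], 4), round(v[ok][conv], 4)))
  # dedupe on the master-pair levels at 1e-3
  lv <- uv_levels(roots[, 1], roots[, 2], rt)
  x1 <- lv$x[[1]]
  y1 <- lv$y[[1]]
  keep <- integer(0)
  for (i in seq_len(nrow(roots))) {
    if (!length(keep) ||
        all(abs(x1[keep] - x1[i]) + abs(y1[keep] - y1[i]) >= 1e-3))
      keep <- c(keep, i)
  }
  roots <- roots[keep, , drop = FALSE]
  m <- params$m
  nfp <- nrow(roots)
  loc <- matrix(NA_real_, nfp, 2 * m, dimnames = list(NULL, state_names(m)))
  stability <- character(nfp)
  max_re <- numeric(nfp)
  eigs <- vector("list", nfp)
  for (i in seq_len(nfp)) {
    f <- uv_residual(roots[i, 1], roots[i, 2], rt)
    loc[i, ] <- c(unlist(f$levels$x), unlist(f$levels$y))
    J <- uv_jacobians(roots[i, 1], roots[i, 2], f$levels, rt)
    ev2 <- eigen(matrix(c(J$M11, J$M12, J$M21, J$M22), 2, 2, byrow = TRUE),
                 only.values = TRUE)$values - params$gamma
    ev <- c(ev2, rep(-params$gamma, 2 * m - 2))
    eigs[[i]] <- ev
    re <- Re(ev)
    max_re[i] <- max(re)
    stability[i] <-
      if (any(abs(re) <= 1e-9)) "marginal"
      else if (all(re < 0)) "stable"
      else if (all(re > 0)) "unstable"
      else "saddle"
  }
  ord <- order(-(rowSums(loc[, seq_len(m), drop = FALSE])),
               rowSums(loc[, m + seq_len(m), drop = FALSE]))
  loc <- loc[ord, , drop = FALSE]
  out <- data.frame(loc,
                    Sx = rowSums(loc[, seq_len(m), drop = FALSE]),
                    Sy = rowSums(loc[, m + seq_len(m), drop = FALSE]),
                    stability = stability[ord], max_re = max_re[ord])
  attr(out, "eigenvalues") <- eigs[ord]
  attr(out, "params") <- params
  class(out) <- c("switch_fixed_points", "data.frame")
  out
}

empty_fixed_points <- function(params) {
  m <- params$m
  out <- data.frame(matrix(numeric(0), 0, 2 * m,
                           dimnames = list(NULL, state_names(m))),
                    Sx = numeric(0), Sy = numeric(0),
                    stability = character(0), max_re = numeric(0))
  attr(out, "eigenvalues") <- list()
  attr(out, "params") <- params
  class(out) <- c("switch_fixed_points", "data.frame")
  out
}

#' @export
print.switch_fixed_points <- function(x, ...) {
  cat(sprintf("%d fixed point(s): %d stable, %d other\n", nrow(x),
              sum(x$stability == "stable"), sum(x$stability != "stable")))
  print.data.frame(x, digits = 5)
  invisible(x)
}

# Assign attractor identities to the stable fixed points.
# With three stable points, the one with the largest Sx - Sy is A
# (x-dominant), the smallest is B, and the middle one is C (stem). With
# fewer, points are labelled by dominance; a point within 1 molecule of the
# diagonal counts as C.
label_attractors <- function(fp) {
  st <- fp[fp$stability == "stable", , drop = FALSE]
  out <- list(A = NULL, B = NULL, C = NULL)
  if (nrow(st) == 0L) return(out)
  d <- st$Sx - st$Sy
  mk <- function(i) list(Sx = st$Sx[i], Sy = st$Sy[i],
                         location = as.numeric(st[i, seq_len(ncol(st) - 4L)]))
  if (nrow(st) == 3L) {
    ord <- order(-d)
    out$A <- mk(ord[1]); out$C <- mk(ord[2]); out$B <- mk(ord[3])
  } else {
    for (i in seq_len(nrow(st))) {
      lab <- if (abs(d[i]) <= 1) "C" else if (d[i] > 0) "A" else "B"
      if (is.null(out[[lab]])) out[[lab]] <- mk(i)
    }
  }
  out
}

# attractor record in the engine's 21-column layout: seven slots per
# attractor (x1, x2, x3, y1, y2, y3, exists), A then B then C
attr_row <- function(attractors, m) {
  row <- numeric(21)
  for (k in seq_along(c("A", "B", "C"))) {
    a <- attractors[[c("A", "B", "C")[k]]]
    if (is.null(a)) next
    base <- 7 * (k - 1)
    row[base + seq_len(m)] <- a$location[seq_len(m)]
    row[base + 3 + seq_len(m)] <- a$location[m + seq_len(m)]
    row[base + 7] <- 1
  }
  row
}

fate_levels <- c("A", "B", "C")

decode_fates <- function(codes) {
  factor(ifelse(codes >= 0 & codes <= 2, fate_levels[codes + 1], NA),
         levels = fate_levels)
}

#' Classify the fate of a daughter cell state
#'
#' The fate of a cell is decided by its master indicators: the master pair
#' (x1, y1) is integrated under the 2-D master-pair fate system (the
#' tri-stable circuit of x1 and y1 alone, with their own rate constants and
#' the shared beta/gamma/n; for the two-element switch this is the switch
#' itself) until the trajectory is captured by a stable attractor (distance
#' below `radius`), and that attractor's label is returned: `A` (x-dominant
#' differentiated), `B` (y-dominant differentiated) or `C` (stem, the middle
#' attractor). If the trajectory is not captured within the horizon the
#' nearest attractor at the horizon is returned with a warning. The call is
#' deterministic: identical inputs always give the identical label.
#'
#' @param initial nonnegative determinant levels (`x1..xm, y1..ym`); only
#'   the master pair enters the fate decision.
#' @param params a [switch_params()] object.
#' @param fixed_points optional precomputed [find_fixed_points()] result of
#'   the master-pair fate system.
#' @param radius capture radius in master-pair coordinates (molecules).
#' @param horizon integration horizon; default `10 * cycle_time(params)`.
#' @param dt RK4 step size.
#' @return A factor level among `A`, `B`, `C`.
#' @examples
#' classify_fate(c(92, 92), switch_preset("two-element"))  # C
#' @export
classify_fate <- function(initial, params, fixed_points = NULL,
                          radius = 1, horizon = NULL, dt = 0.05) {
  initial <- check_state(initial, params)
  ms <- master_system(params)
  if (is.null(fixed_points)) fixed_points <- find_fixed_points(ms)
  attractors <- label_attractors(fixed_points)
  if (sum(!vapply(attractors, is.null, logical(1))) < 3L)
    warning("fewer than three stable attractors; classification by dominance identity")
  if (is.null(horizon)) horizon <- 10 * cycle_time(params)
  mp <- initial[c(1L, params$m + 1L)]
  code <- cpp_classify_batch(matrix(mp, nrow = 1), alpha_vector(ms),
                             ms$beta, ms$n, ms$gamma, 1L,
                             attr_row(attractors, 1L), radius, horizon, dt)
  if (attr(code, "warnings") > 0)
    warning("trajectory not captured within the horizon; nearest attractor used")
  decode_fates(as.integer(code))
}

#' Nullclines of the switch in the master-pair plane
#'
#' Zero-level contours of the selected time derivative over a regular grid
#' of the master pair (x1, y1). For extended switches (m > 1) the support
#' elements are held at their middle-attractor values, giving the standard
#' master-pair slice of the phase plane.
#'
#' @param params a [switch_params()] object.
#' @param axis which derivative: `"x"` (dx1/dt) or `"y"` (dy1/dt).
#' @param upper upper grid limit per axis; defaults to
#'   `1.3 * (alpha_A[1] + alpha_I[1]) / gamma`.
#' @param resolution grid points per axis.
#' @return A list of polylines, each a data frame with columns `x`, `y`
#'   (empty when the contour is empty).
#' @export
nullclines <- function(params, axis = c("x", "y"), upper = NULL,
                       resolution = 400L) {
  axis <- match.arg(axis)
  m <- params$m
  if (is.null(upper))
    upper <- 1.3 * (params$alpha_A[1] + params$alpha_I[1]) / params$gamma
  support <- if (m > 1L) {
    at <- label_attractors(find_fixed_points(params))
    if (is.null(at$C)) stop("master-pair slice needs the middle attractor for m > 1")
    at$C$location
  } else NULL
  g <- seq(0, upper, length.out = resolution)
  idx <- if (axis == "x") 1L else m + 1L
  deriv <- matrix(NA_real_, resolution, resolution)
  for (j in seq_along(g)) {
    for (i in seq_along(g)) {
      s <- if (m == 1L) c(g[i], g[j]) else {
        full <- support
        full[1] <- g[i]
        full[m + 1] <- g[j]
        full
      }
      deriv[i, j] <- switch_rhs(s, params)[idx]
    }
  }
  cl <- grDevices::contourLines(g, g, deriv, levels = 0)
  lapply(cl, function(p) data.frame(x = p$x, y = p$y))
}

#' Fate-domain map over the master-pair plane
#'
#' Classifies every point of a regular (x1, y1) grid with [classify_fate()],
#' producing the raster of the three fate domains of the master-pair fate
#' system. For symmetric parameters the map is symmetric under reflection
#' across the diagonal with the A and B labels exchanged.
#'
#' @param params a [switch_params()] object.
#' @param resolution grid cells per axis.
#' @param upper upper limit of both axes; defaults to `round(1.25 * N)` of
#'   the master-pair fate system, so the lattice raster (resolution
#'   `upper + 1`) has one cell per molecule.
#' @param radius,dt passed to the classifier.
#' @return An object of class `basin_map`: list with grid coordinates `x`,
#'   `y`, factor matrix `labels` (rows index x), the labelled master-pair
#'   `attractors`, and `params`.
#' @examples \donttest{
#' bm <- basin_map(switch_preset("two-element"), resolution = 51)
#' table(bm$labels)
#' }
#' @export
basin_map <- function(params, resolution = 101L, upper = NULL,
                      radius = 1, dt = 0.05) {
  ms <- master_system(params)
  fp <- find_fixed_points(ms)
  at <- label_attractors(fp)
  if (sum(!vapply(at, is.null, logical(1))) < 3L)
    stop("fate-domain map requires three stable attractors")
  if (is.null(upper)) upper <- round(1.25 * steady_state_max(ms))
  g <- seq(0, upper, length.out = resolution)
  states <- as.matrix(expand.grid(x = g, y = g))
  horizon <- 10 * cycle_time(params)
  codes <- cpp_classify_batch(states, alpha_vector(ms), ms$beta,
                              ms$n, ms$gamma, 1L,
                              attr_row(at, 1L), radius, horizon, dt)
  if (attr(codes, "warnings") > 0)
    warning(sprintf("%d grid point(s) not captured within the horizon",
                    attr(codes, "warnings")))
  labels <- matrix(decode_fates(as.integer(codes)), resolution, resolution)
  structure(list(x = g, y = g, labels = labels, attractors = at,
                 params = params, resolution = resolution, upper = upper),
            class = "basin_map")
}

#' @export
print.basin_map <- function(x, ...) {
  tb <- table(factor(x$labels, levels = fate_levels))
  cat(sprintf("basin_map: %dx%d grid over [0, %g]^2\n",
              x$resolution, x$resolution, x$upper))
  cat(sprintf("  label fractions: A %.3f, B %.3f, C %.3f\n",
              tb["A"] / sum(tb), tb["B"] / sum(tb), tb["C"] / sum(tb)))
  invisible(x)
}

#' @export
plot.basin_map <- function(x, ...) {
  z <- matrix(as.integer(factor(x$labels, levels = fate_levels)),
              x$resolution, x$resolution)
  graphics::image(x$x, x$y, z, col = c("#66c2a5", "#fc8d62", "#ffd92f"),
                  xlab = "x1", ylab = "y1", ...)
  for (lab in fate_levels) {
    a <- x$attractors[[lab]]
    if (!is.null(a)) graphics::points(a$location[1], a$location[2], pch = 19)
  }
  invisible(x)
}

#' One-parameter sweeps of the fixed-point structure
#'
#' Re-solves the fixed-point problem for each value of one parameter and
#' reports every fixed point found (machine-readable counterpart of the
#' usual panel-of-phase-planes figure). Sweeping an alpha changes all
#' elements of that group/type together.
#'
#' @param params base [switch_params()] object.
#' @param which one of `"alpha_A_x"`, `"alpha_I_x"`, `"alpha_A_y"`,
#'   `"alpha_I_y"`, `"beta"`, `"gamma"`.
#' @param values numeric vector of parameter values.
#' @return A data frame, one row per fixed point per value: `param`, `value`,
#'   the location columns, `Sx`, `Sy`, `stability`, `max_re`, plus the
#'   per-value counts `n_fixed` and `n_stable`.
#' @export
parameter_sweep <- function(params, which, values) {
  which <- match.arg(which, c("alpha_A_x", "alpha_I_x", "alpha_A_y",
                              "alpha_I_y", "beta", "gamma"))
  rows <- lapply(values, function(v) {
    p <- params
    slot <- switch(which, alpha_A_x = "alpha_A", alpha_I_x = "alpha_I",
                   alpha_A_y = "alpha_A_y", alpha_I_y = "alpha_I_y", which)
    p[[slot]] <- if (startsWith(which, "alpha")) rep(v, params$m) else v
    p <- do.call(switch_params,
                 p[c("alpha_A", "alpha_I", "beta", "gamma", "n", "m",
                     "alpha_A_y", "alpha_I_y")])
    fp <- find_fixed_points(p)
    if (nrow(fp) == 0L) {
      return(data.frame(param = which, value = v, n_fixed = 0L, n_stable = 0L))
    }
    cbind(param = which, value = v, as.data.frame(fp),
          n_fixed = nrow(fp), n_stable = sum(fp$stability == "stable"))
  })
  out <- do.call(rbind, lapply(rows, function(r) {
    if (!"Sx" %in% names(r)) {
      tmpl <- c(setNames(rep(NA_real_, 2 * params$m), state_names(params$m)),
                Sx = NA_real_, Sy = NA_real_)
      for (nm in names(tmpl)) r[[nm]] <- tmpl[[nm]]
      r$stability <- NA_character_
      r$max_re <- NA_real_
    }
    r[, c("param", "value", state_names(params$m), "Sx", "Sy",
          "stability", "max_re", "n_fixed", "n_stable")]
  }))
  rownames(out) <- NULL
  out
}
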