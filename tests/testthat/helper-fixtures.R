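# Shared fixtures and independent oracles for the test suite. Expensive
# simulation results are memoized so several test files can share one run.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

preset2 <- function() switch_preset("two-element")
preset4 <- function() switch_preset("four-element")
preset6 <- function() switch_preset("six-element")

# Independent fixed-point oracle: dense sign-change scan of both nullcline
# surfaces on a grid (separable for the two-element switch), followed by
# Nelder-Mead refinement of |rhs|^2 from each candidate cell. Shares no code
# with the package's Newton solver.
oracle_fixed_points <- function(params, ngrid = 2000, upper = 250) {
  stopifnot(params$m == 1L)
  g <- seq(0, upper, length.out = ngrid)
  bn <- params$beta^params$n
  H <- function(s) s^params$n / (bn + s^params$n)
  R <- function(s) bn / (bn + s^params$n)
  # dx(x, y) = a(x) + b(y), dy(x, y) = c(y) + d(x)
  a <- params$alpha_A * H(g) - params$gamma * g
  b <- params$alpha_I * R(g)
  cc <- params$alpha_A_y * H(g) - params$gamma * g
  d <- params$alpha_I_y * R(g)
  sdx <- outer(a, b, `+`) > 0
  sdy <- outer(d, cc, `+`) > 0
  flip <- function(s) {
    (s[-nrow(s), -ncol(s)] != s[-1, -ncol(s)]) |
      (s[-nrow(s), -ncol(s)] != s[-nrow(s), -1]) |
      (s[-nrow(s), -ncol(s)] != s[-1, -1])
  }
  cand <- which(flip(sdx) & flip(sdy), arr.ind = TRUE)
  if (nrow(cand) == 0L) return(matrix(numeric(0), 0, 2))
  pts <- cbind(g[cand[, 1]], g[cand[, 2]])
  obj <- function(v) {
    if (any(v < -1)) return(1e6)
    sum(switch_rhs(pmax(v, 0), params)^2)
  }
  roots <- t(apply(pts, 1, function(p0)
    pmax(stats::optim(p0, obj, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))$par, 0)))
  good <- apply(roots, 1, function(v) sqrt(obj(v)) < 1e-6)
  roots <- roots[good, , drop = FALSE]
  keep <- matrix(numeric(0), 0, 2)
  for (i in seq_len(nrow(roots))) {
    if (nrow(keep) == 0L ||
        min(abs(keep[, 1] - roots[i, 1]) + abs(keep[, 2] - roots[i, 2])) >= 1e-2)
      keep <- rbind(keep, roots[i, ])
  }
  keep[order(-keep[, 1]), , drop = FALSE]
}

# deSolve endpoint of the switch ODEs: the independent integration oracle
desolve_endpoint <- function(state, params, t_end) {
  f <- function(t, y, p) list(unname(switch_rhs(pmax(y, 0), params)))
  out <- deSolve::ode(y = state, times = c(0, t_end), func = f, parms = NULL,
                      method = "lsoda", rtol = 1e-8, atol = 1e-8)
  unname(out[nrow(out), -1])
}

# memoized heavy runs shared between regular and acceptance tests ----------

homeostasis_run <- function(preset, n_pop = 100, seed = 1) {
  memo(paste("homeo", preset, n_pop, seed),
       simulate_homeostasis(population_config(n_pop, 50, preset, seed = seed)))
}

protocol_run <- function(seed = 1, n_pop = 200) {
  memo(paste("protocol", seed, n_pop),
       run_phases(population_config(n_pop, 50, "two-element", seed = seed),
                  mutation_config(p = 0.85, lambda = 5, phases = 11)))
}

ordering_run <- function(preset, seed = 3) {
  memo(paste("ordering", preset, seed),
       run_phases(population_config(100, 50, preset, seed = seed,
                                    population_cap = 200),
                  mutation_config(p = 0.85, lambda = 5, phases = 11)))
}
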