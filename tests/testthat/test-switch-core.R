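test_that("parameter construction enforces the model invariants", {
  expect_error(switch_params(35, 35, beta = 45, gamma = -0.1, n = 4),
               "gamma")
  expect_error(switch_params(35, 35, beta = 0, gamma = 0.38, n = 4), "beta")
  expect_error(switch_params(35, 35, beta = 45, gamma = 0.38, n = 0), "'n'")
  expect_error(switch_params(35, 35, beta = 45, gamma = 0.38, n = 4, m = 4),
               "'m'")
  expect_error(switch_params(-1, 35, beta = 45, gamma = 0.38, n = 4),
               "alpha_A")
  p <- switch_params(35, 35, beta = 47.3, gamma = 0.38, n = 4, m = 2)
  expect_equal(p$alpha_A, c(35, 35))
  expect_equal(p$alpha_I_y, c(35, 35))
})

test_that("homeostasis presets carry the published parameter values", {
  expect_equal(switch_preset("two-element")$beta, 45)
  expect_equal(switch_preset("four-element")$beta, 47.3)
  expect_equal(switch_preset("six-element")$beta, 48.5)
  for (nm in c("two-element", "four-element", "six-element")) {
    p <- switch_preset(nm)
    expect_true(all(c(p$alpha_A, p$alpha_I, p$alpha_A_y, p$alpha_I_y) == 35))
    expect_equal(p$gamma, 0.38)
    expect_equal(p$n, 4L)
  }
})

test_that("the deterministic rhs matches direct evaluation and symmetry", {
  p <- preset2()
  # at the origin the activation terms vanish and repression relief is full
  expect_equal(unname(switch_rhs(c(0, 0), p)), c(35, 35))
  # x<->y exchange symmetry for symmetric parameters
  set.seed(4)
  for (i in 1:20) {
    s <- runif(2, 0, 250)
    d <- switch_rhs(s, p)
    expect_equal(unname(d[1]), unname(switch_rhs(rev(s), p)[2]), tolerance = 1e-12)
  }
  p4 <- preset4()
  for (i in 1:10) {
    s <- runif(4, 0, 200)
    d <- switch_rhs(s, p4)
    dsw <- switch_rhs(s[c(3, 4, 1, 2)], p4)
    expect_equal(unname(d[1:2]), unname(dsw[3:4]), tolerance = 1e-12)
  }
  expect_error(switch_rhs(c(1, 2, 3), p), "length")
  expect_error(switch_rhs(c(-1, 2), p), "nonnegative")
})

test_that("the rhs vanishes at the independently located high-x fixed point", {
  p <- preset2()
  # independent oracle: 1-D bisection on the nullcline composition
  bn <- p$beta^p$n
  y_of_x <- function(x) {
    stats::uniroot(function(y) switch_rhs(c(x, y), p)[2],
                   c(0, 250), tol = 1e-12)$root
  }
  gx <- function(x) switch_rhs(c(x, y_of_x(x)), p)[1]
  root <- stats::uniroot(gx, c(150, 220), tol = 1e-12)$root
  fp_state <- c(root, y_of_x(root))
  expect_lt(max(abs(switch_rhs(fp_state, p))), 1e-8)
  fp <- find_fixed_points(p)
  expect_lt(min(abs(fp$x1 - fp_state[1]) + abs(fp$y1 - fp_state[2])), 1e-3)
})

test_that("propensities follow the reaction-channel definitions", {
  p <- preset2()
  Tc <- cycle_time(p)
  # degradation channel is zero at zero count
  w <- switch_propensities(c(0, 10), p, Tc)
  expect_equal(unname(w["deg_x1"]), 0)
  # half-saturation symmetry: x1 = y1 = beta gives production 35/2 + 35/2
  w <- switch_propensities(c(45, 45), p, Tc)
  expect_equal(unname(w["prod_x1"]), 35)
  expect_equal(unname(w["prod_y1"]), 35)
  # division channel is 1/T with T = 1.1 ln(184)
  expect_equal(unname(w["division"]), 1 / (1.1 * log(184)))
  expect_equal(unname(w["division"]), 0.1743, tolerance = 1e-3)
  # channel count and order for the four-element switch
  p4 <- preset4()
  w4 <- switch_propensities(c(10, 20, 30, 40), p4, cycle_time(p4))
  expect_length(w4, 9)
  expect_named(w4, c("prod_x1", "prod_x2", "deg_x1", "deg_x2",
                     "prod_y1", "prod_y2", "deg_y1", "deg_y2", "division"))
  expect_error(switch_propensities(c(1.5, 2), p, Tc), "integers")
})

test_that("propensities are finite, nonnegative and bounded by alpha_A + alpha_I", {
  set.seed(11)
  for (p in list(preset2(), preset4(), preset6())) {
    N <- steady_state_max(p)
    Tc <- cycle_time(p)
    for (i in 1:25) {
      s <- sample.int(2 * N, 2 * p$m, replace = TRUE)
      w <- switch_propensities(s, p, Tc)
      expect_true(all(is.finite(w)) && all(w >= 0))
      prods <- w[grep("^prod", names(w))]
      expect_true(all(prods <= 35 + 35 + 1e-9))
    }
  }
})

test_that("steady-state maxima reproduce the published scales", {
  expect_identical(steady_state_max(preset2()), 184L)
  expect_identical(steady_state_max(preset4()), 368L)
})

test_that("steady-state maximum obeys the closed-form bound and gamma monotonicity", {
  # both Hill factors are at most 1, so N <= (alpha_A + alpha_I) * m / gamma
  for (p in list(preset2(), preset4(), preset6()))
    expect_lte(steady_state_max(p), (35 + 35) * p$m / p$gamma + 0.5)
  Ns <- vapply(c(0.30, 0.34, 0.38, 0.42, 0.46), function(g)
    steady_state_max(switch_params(35, 35, 45, g, 4)), integer(1))
  expect_true(all(diff(Ns) <= 0))
})

test_that("cycle time is 1.1 times the natural log of N", {
  expect_equal(cycle_time(exp(1)), 1.1)
  expect_equal(cycle_time(184), 1.1 * log(184))
  expect_equal(cycle_time(184), 5.736, tolerance = 1e-3)
  expect_equal(cycle_time(368), 6.50, tolerance = 1e-2)
  expect_equal(cycle_time(preset2()), cycle_time(184))
  expect_error(cycle_time(1), "> 1")
})

test_that("switch parameters survive a JSON config round trip", {
  p <- switch_params(c(30, 40), c(35, 25), beta = 47.3, gamma = 0.38, n = 4,
                     m = 2, alpha_A_y = c(36, 34), alpha_I_y = 35)
  tmp <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(switch = switch_to_config(p)), tmp,
                       auto_unbox = TRUE, digits = NA)
  q <- load_config(tmp)$params
  expect_equal(q[names(q)], p[names(p)])
})
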