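test_that("initial populations are stem cells drawn from the C domain", {
  cfg <- population_config(1, 30, "two-element", seed = 5)
  set.seed(5)
  pop <- init_population(cfg)
  expect_equal(nrow(pop$states), 30)
  fp_ms <- find_fixed_points(preset2())
  for (i in seq_len(10))
    expect_identical(as.character(classify_fate(pop$states[i, ], pop$params, fp_ms)),
                     "C")
  # seeded determinism
  set.seed(5)
  pop2 <- init_population(cfg)
  expect_identical(pop$states, pop2$states)
})

test_that("initial draws are uniform over the stem-domain lattice", {
  cfg <- population_config(1, 10000, "two-element", seed = 8,
                           population_cap = 10000)
  bm <- tristem:::lattice_basin(preset2())
  set.seed(8)
  pop <- init_population(cfg, bm)
  cidx <- which(bm$labels == "C", arr.ind = TRUE)
  centroid <- c(mean(bm$x[cidx[, 1]]), mean(bm$y[cidx[, 2]]))
  spread <- c(stats::sd(bm$x[cidx[, 1]]), stats::sd(bm$y[cidx[, 2]]))
  se <- spread / sqrt(nrow(pop$states))
  expect_lt(abs(mean(pop$states[, 1]) - centroid[1]), 2 * se[1] + 1e-9)
  expect_lt(abs(mean(pop$states[, 2]) - centroid[2]), 2 * se[2] + 1e-9)
})

test_that("extended-switch initialization puts supports at the middle attractor", {
  cfg <- population_config(1, 20, "four-element", seed = 2)
  set.seed(2)
  pop <- init_population(cfg)
  expect_true(all(pop$states[, 2] == 92L))
  expect_true(all(pop$states[, 4] == 92L))
})

test_that("reaction selection follows the prefix-sum rule", {
  expect_identical(select_reaction(c(1, 1), 0.25), 1L)
  expect_identical(select_reaction(c(1, 1), 0.75), 2L)
  expect_identical(select_reaction(c(1, 1), 0.5), 1L)  # right-closed boundary
  # zero-rate channels are never selected
  set.seed(3)
  r <- vapply(runif(2000), function(u) select_reaction(c(0, 1, 0, 2), u),
              integer(1))
  expect_true(all(r %in% c(2L, 4L)))
  expect_error(select_reaction(c(0, 0), 0.5), "positive")
  # empirical selection frequencies match the rates
  set.seed(4)
  rates <- c(1, 3, 0.5, 5.5)
  n <- 20000
  sel <- vapply(runif(n), function(u) select_reaction(rates, u), integer(1))
  freq <- tabulate(sel, 4) / n
  pr <- rates / sum(rates)
  se <- sqrt(pr * (1 - pr) / n)
  expect_true(all(abs(freq - pr) < 3 * se + 1e-12))
})

test_that("waiting times are exponential with the correct mean", {
  expect_equal(waiting_time(5, 1), 0)
  expect_equal(waiting_time(2, exp(-2)), 1)
  expect_error(waiting_time(0, 0.5), "positive")
  expect_error(waiting_time(2, 0), "u2")
  set.seed(6)
  n <- 100000
  R <- 3.7
  dts <- waiting_time(R, runif(n))
  expect_lt(abs(mean(dts) - 1 / R), 3 * (1 / R) / sqrt(n))
})

test_that("division partitions determinants binomially and conserves them", {
  p <- preset2()
  fp_ms <- find_fixed_points(p)
  set.seed(7)
  for (i in 1:15) {
    s <- sample.int(200, 2)
    d <- divide_cell(s, p, fp_ms)
    expect_equal(unname(colSums(d$daughters)), as.numeric(s))
  }
  p4 <- preset4()
  fp4 <- find_fixed_points(tristem:::master_system(p4))
  s4 <- c(92L, 92L, 92L, 92L)
  d4 <- divide_cell(s4, p4, fp4)
  expect_equal(unname(colSums(d4$daughters)), as.numeric(s4))
  # zero counts stay zero in both daughters
  d0 <- divide_cell(c(0L, 150L), p, fp_ms)
  expect_true(all(d0$daughters[, 1] == 0))
  # per-determinant daughter mean is half the mother over many splits
  set.seed(8)
  means <- replicate(2000, divide_cell(c(92L, 92L), p, fp_ms)$daughters[1, 1])
  se <- sqrt(92 * 0.25 / 2000)
  expect_lt(abs(mean(means) - 46), 3 * se)
})

test_that("a 50-cell two-element population enumerates 200 + 50 channels", {
  cfg <- population_config(1, 50, "two-element", seed = 1)
  set.seed(1)
  pop <- init_population(cfg)
  ch <- enumerate_channels(pop)
  expect_identical(nrow(ch), 250L)
  expect_identical(sum(ch$kind == "update"), 200L)
  expect_identical(sum(ch$kind == "division"), 50L)
  # updating reactions come first, divisions last
  expect_true(all(which(ch$kind == "division") > 200))
})

test_that("population runs audit cleanly and never go negative", {
  cfg <- population_config(1, 30, "two-element", seed = 9)
  set.seed(9)
  pop <- init_population(cfg)
  pop <- run_population(pop)
  expect_true(all(pop$states >= 0))
  expect_identical(as.integer(pop$events["division"]), nrow(pop$log))
  # size identity: final = initial + sum over divisions of (stem daughters - 1)
  stems <- rowSums(cbind(pop$log$daughter1_fate == "C",
                         pop$log$daughter2_fate == "C"))
  expect_identical(nrow(pop$states), 30L + as.integer(sum(stems - 1)))
  # daughters with a zero-count mother element stay zero (conservation floor)
  z <- pop$log[pop$log$d1_x1 + pop$log$d2_x1 == 0, ]
  if (nrow(z)) expect_true(all(z$d1_x1 == 0 & z$d2_x1 == 0))
})

test_that("seeded population runs are bit-reproducible", {
  cfg <- population_config(1, 25, "two-element", seed = 10)
  run_once <- function() {
    set.seed(10)
    pop <- init_population(cfg)
    run_population(pop)
  }
  a <- run_once()
  b <- run_once()
  expect_identical(a$states, b$states)
  expect_identical(a$log, b$log)
  expect_identical(a$time, b$time)
})

test_that("without division the SSA mean tracks the deterministic trajectory", {
  p <- preset2()
  cfg <- population_config(1, 1, "two-element", seed = 1)
  bm <- tristem:::lattice_basin(p)
  Tc <- cycle_time(p)
  start <- c(46L, 46L)
  nrep <- 500
  finals <- matrix(NA_real_, nrep, 2)
  set.seed(123)
  for (r in seq_len(nrep)) {
    pop <- init_population(cfg, bm)
    pop$states[1, ] <- start
    pop <- run_population(pop, t = Tc, division = FALSE)
    finals[r, ] <- pop$states[1, ]
  }
  ref <- desolve_endpoint(as.numeric(start), p, Tc)
  expect_lt(max(abs(colMeans(finals) - ref)), 0.05 * 184)
})

test_that("non-dividing cells settle near a stable attractor", {
  p <- preset2()
  at <- tristem:::label_attractors(find_fixed_points(p))
  locs <- rbind(at$A$location, at$B$location, at$C$location)
  cfg <- population_config(1, 100, "two-element", seed = 14)
  set.seed(14)
  pop <- init_population(cfg)
  pop <- run_population(pop, t = 3 * pop$T, division = FALSE)
  d <- apply(pop$states, 1, function(s)
    min(sqrt(colSums((t(locs) - s)^2))))
  expect_gt(mean(d < 30), 0.9)
})

test_that("the pooled stem-cell birth rate summarizes division logs", {
  ss <- data.frame(daughter1_fate = rep("C", 4), daughter2_fate = rep("C", 4))
  dd <- data.frame(daughter1_fate = rep("A", 3), daughter2_fate = rep("B", 3))
  expect_equal(scb_rate(ss), 1)
  expect_equal(scb_rate(dd), 0)
  expect_equal(scb_rate(list(ss, dd)), 8 / 14)
  expect_error(scb_rate(list(NULL)), "no divisions")
})
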