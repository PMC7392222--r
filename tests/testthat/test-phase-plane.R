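test_that("fixed-point locations agree with the brute-force scan oracle", {
  p <- preset2()
  fp <- find_fixed_points(p)
  oracle <- oracle_fixed_points(p)
  expect_equal(nrow(fp), nrow(oracle))
  for (i in seq_len(nrow(oracle))) {
    d <- abs(fp$x1 - oracle[i, 1]) + abs(fp$y1 - oracle[i, 2])
    expect_lt(min(d), 1e-3)
  }
})

test_that("fixed-point sets are symmetric and the middle attractor is diagonal", {
  for (p in list(preset2(), preset4())) {
    fp <- find_fixed_points(p)
    # closed under (x, y) -> (y, x)
    for (i in seq_len(nrow(fp)))
      expect_lt(min(abs(fp$Sx - fp$Sy[i]) + abs(fp$Sy - fp$Sx[i])), 1e-3)
    at <- tristem:::label_attractors(fp)
    expect_equal(at$C$Sx, at$C$Sy, tolerance = 1e-6)
  }
  # the middle attractor sits at alpha (A + I) / gamma per element exactly:
  # on the diagonal the activation and repression-relief terms sum to one
  at2 <- tristem:::label_attractors(find_fixed_points(preset2()))
  expect_equal(at2$C$location, c(35 / 0.38, 35 / 0.38) * 1, tolerance = 1e-6)
})

test_that("strong degradation collapses the tri-stable structure", {
  p <- switch_params(35, 35, beta = 45, gamma = 10, n = 4)
  fp <- find_fixed_points(p)
  expect_lt(nrow(fp), 5)
})

test_that("the internal integrator matches deSolve trajectories", {
  set.seed(21)
  for (p in list(preset2(), preset4())) {
    for (i in 1:4) {
      s0 <- runif(2 * p$m, 0, 200)
      mine <- tristem:::cpp_ode_endpoint(s0, tristem:::alpha_vector(p),
                                         p$beta, p$n, p$gamma, p$m, 5, 0.05)
      ref <- desolve_endpoint(s0, p, 5)
      expect_equal(mine, ref, tolerance = 1e-4)
    }
  }
})

test_that("fate classification is deterministic and labels the attractors themselves", {
  p <- preset2()
  fp_ms <- find_fixed_points(p)
  expect_identical(as.character(classify_fate(c(184, 0), p, fp_ms)), "A")
  expect_identical(as.character(classify_fate(c(0, 184), p, fp_ms)), "B")
  expect_identical(as.character(classify_fate(c(92, 92), p, fp_ms)), "C")
  # idempotent/deterministic
  expect_identical(classify_fate(c(60, 40), p, fp_ms),
                   classify_fate(c(60, 40), p, fp_ms))
  # every stable fixed point maps to its own label
  at <- tristem:::label_attractors(fp_ms)
  for (lab in c("A", "B", "C"))
    expect_identical(as.character(classify_fate(round(at[[lab]]$location), p, fp_ms)),
                     lab)
})

test_that("fate of extended-switch states is read from the master pair", {
  p4 <- preset4()
  expect_identical(as.character(classify_fate(c(184, 92, 0, 92), p4)), "A")
  expect_identical(as.character(classify_fate(c(92, 92, 92, 92), p4)), "C")
  expect_identical(as.character(classify_fate(c(0, 92, 184, 92), p4)), "B")
})

test_that("nullclines mirror across the diagonal and vanish only off the contour", {
  p <- preset2()
  nx <- nullclines(p, "x", resolution = 200)
  ny <- nullclines(p, "y", resolution = 200)
  expect_gt(length(nx), 0)
  expect_gt(length(ny), 0)
  # y-nullcline is the mirror image of the x-nullcline for symmetric params
  xpts <- do.call(rbind, nx)
  ypts <- do.call(rbind, ny)
  samp <- xpts[seq(1, nrow(xpts), length.out = 40), ]
  for (i in seq_len(nrow(samp))) {
    d <- sqrt((ypts$x - samp$y[i])^2 + (ypts$y - samp$x[i])^2)
    expect_lt(min(d), 2)
  }
  # points on the x-nullcline annihilate dx1/dt
  for (i in seq(1, nrow(xpts), length.out = 10))
    expect_lt(abs(switch_rhs(c(xpts$x[i], xpts$y[i]), p)[1]), 0.5)
})

test_that("the fate-domain map is diagonal-symmetric with A and B exchanged", {
  bm <- memo("bm101", basin_map(preset2(), resolution = 101))
  lab <- matrix(as.character(bm$labels), bm$resolution)
  swapped <- t(lab)
  swapped[lab == "A" & t(lab) == "B"] <- "ok"
  expect_identical(lab[lab == "C"], swapped[lab == "C"])
  ab <- lab %in% c("A", "B")
  expect_true(all((lab == "A" & t(lab) == "B") | (lab == "B" & t(lab) == "A") |
                    (lab == t(lab)) | !ab))
  # each attractor cell carries its own label
  for (l in c("A", "B", "C")) {
    a <- bm$attractors[[l]]
    ix <- which.min(abs(bm$x - a$location[1]))
    iy <- which.min(abs(bm$y - a$location[2]))
    expect_identical(as.character(bm$labels[ix, iy]), l)
  }
})

test_that("the stem domain is one contiguous region containing the diagonal", {
  bm <- memo("bm101", basin_map(preset2(), resolution = 101))
  lab <- matrix(as.character(bm$labels), bm$resolution)
  expect_true(all(diag(lab) == "C"))
  # flood fill from the middle attractor cell reaches every C cell
  n <- bm$resolution
  seen <- matrix(FALSE, n, n)
  ix <- which.min(abs(bm$x - bm$attractors$C$location[1]))
  stack <- list(c(ix, ix))
  seen[ix, ix] <- TRUE
  while (length(stack)) {
    cur <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
      q <- cur + d
      if (all(q >= 1) && all(q <= n) && !seen[q[1], q[2]] &&
          lab[q[1], q[2]] == "C") {
        seen[q[1], q[2]] <- TRUE
        stack[[length(stack) + 1L]] <- q
      }
    }
  }
  expect_identical(sum(seen), sum(lab == "C"))
})

test_that("fate-domain fractions vary continuously under small beta changes", {
  bm1 <- memo("bm101", basin_map(preset2(), resolution = 101))
  p2 <- switch_params(35, 35, beta = 45.1, gamma = 0.38, n = 4)
  bm2 <- basin_map(p2, resolution = 101, upper = bm1$upper)
  flips <- mean(bm1$labels != bm2$labels)
  expect_lt(flips, 0.05)
})

test_that("parameter sweeps recover the baseline and break symmetry off it", {
  p <- preset2()
  sw <- parameter_sweep(p, "beta", c(40, 45, 50))
  base <- sw[sw$value == 45, ]
  expect_equal(unique(base$n_fixed), 5)
  expect_equal(unique(base$n_stable), 3)
  # sweep counts agree with the brute-force oracle at each value
  for (v in c(40, 50)) {
    pv <- switch_params(35, 35, beta = v, gamma = 0.38, n = 4)
    expect_equal(unique(sw$n_fixed[sw$value == v]), nrow(oracle_fixed_points(pv)))
  }
  # an asymmetric alpha destroys the A<->B mirror of fixed-point locations
  swa <- parameter_sweep(p, "alpha_A_x", 28)
  pts <- swa[, c("x1", "y1")]
  mirrored <- vapply(seq_len(nrow(pts)), function(i)
    min(abs(pts$x1 - pts$y1[i]) + abs(pts$y1 - pts$x1[i])), numeric(1))
  expect_gt(max(mirrored), 0.1)
})
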