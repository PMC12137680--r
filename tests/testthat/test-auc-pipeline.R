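test_that("baseline adjustment subtracts the pre-meal mean and floors at zero", {
  s <- make_series(times = c(-60, -1, 5, 15),
                   F = c(1.0, 1.0, 1.5, 0.8), T = c(3.0, 3.2, 3.0, 4.0))
  adj <- baseline_adjust(s)
  expect_equal(attr(adj, "baseline_F"), 1.0)
  expect_equal(attr(adj, "baseline_T"), 3.1)
  expect_equal(adj$F_adj, c(0.5, 0))
  expect_equal(adj$T_adj, c(0, 0.9))
  expect_identical(adj$flag, c("floored_at_0", "floored_at_0"))

  # constant series adjusts to all zeros
  s <- make_series(F = rep(2, 8), T = rep(4, 8))
  adj <- baseline_adjust(s)
  expect_true(all(adj$F_adj == 0) && all(adj$T_adj == 0))

  expect_error(baseline_adjust(make_series(times = c(5, 15, 30),
                                           F = 1:3, T = 2:4)), "pre-meal")
  expect_error(baseline_adjust(make_series(times = c(-1, 5, 5, 30),
                                           F = 1:4, T = 2:5)), "duplicate")
})

test_that("trapezoid rule integrates piecewise-linear curves", {
  expect_equal(trapezoid_auc(c(0, 10), c(1, 1)), 10)
  expect_equal(trapezoid_auc(c(0, 10), c(0, 2)), 10)
  expect_equal(trapezoid_auc(c(5, 15, 30), c(2, 4, 0)), 60)
  expect_error(trapezoid_auc(c(10, 5), c(1, 1)), "increasing")

  # refining the grid with a linearly interpolated point changes nothing
  set.seed(14)
  for (i in 1:10) {
    tms <- sort(stats::runif(5, 0, 120))
    v <- stats::runif(5)
    mid <- (tms[2] + tms[3]) / 2
    vmid <- stats::approx(tms, v, xout = mid)$y
    expect_equal(trapezoid_auc(sort(c(tms, mid)), append(v, vmid, after = 2)),
                 trapezoid_auc(tms, v), tolerance = 1e-12)
  }
})

test_that("decompose_series honours the W = 1 and W = 3 limits", {
  f <- c(10, 10, 20, 30, 25, 15, 12, 10)
  s <- make_series(F = f, T = f)                 # only free amino acids
  d <- decompose_series(s, fast_config())
  expect_equal(d$auc_DD, 0)
  expect_equal(d$auc_TD, 0)
  expect_equal(d$auc_F, d$auc_T)

  s <- make_series(F = f, T = 3 * f)             # pure y1 tripeptides
  d <- decompose_series(s, fast_config())
  expect_equal(d$auc_F, 0, tolerance = 1e-9)
  expect_equal(d$auc_DD, 0, tolerance = 1e-9)
  expect_equal(d$auc_TD, d$auc_T, tolerance = 1e-9)
})

test_that("constant-W series factorize through the mean structure", {
  f <- c(10, 10, 20, 30, 25, 15, 12, 10)
  s <- make_series(F = f, T = 2 * f)             # W = 2 at every point
  cfg <- fast_config(400)
  d <- decompose_series(s, cfg)
  sh <- mean_structure(2)$after
  expect_equal(c(d$auc_F, d$auc_DD, d$auc_TD), unname(d$auc_T * sh),
               tolerance = 1e-9)
  # pointwise and aggregate agree exactly when W is constant
  da <- decompose_series(s, cfg, mode = "aggregate")
  expect_equal(da$auc_T, d$auc_T, tolerance = 1e-9)
  expect_equal(da$auc_TD, d$auc_TD, tolerance = 1e-9)
})

test_that("AUC additivity and scale equivariance hold on noisy series", {
  set.seed(23)
  cfg <- fast_config()
  for (i in 1:5) {
    f <- c(10, 10, stats::runif(6, 12, 40))
    w <- c(1, 1, stats::runif(6, 1.05, 2.9))
    s <- make_series(F = f, T = f * w)
    d <- decompose_series(s, cfg)
    expect_equal(d$auc_T, d$auc_F + d$auc_DD + d$auc_TD, tolerance = 1e-9)
    expect_true(all(c(d$auc_F, d$auc_DD, d$auc_TD) >= 0))

    s2 <- s; s2$F <- 3.7 * s$F; s2$T <- 3.7 * s$T
    d2 <- decompose_series(s2, cfg)
    expect_equal(as.numeric(d2[c("auc_T", "auc_F", "auc_DD", "auc_TD")]),
                 3.7 * as.numeric(d[c("auc_T", "auc_F", "auc_DD", "auc_TD")]),
                 tolerance = 1e-9)
  }
})

test_that("a point with zero adjusted F is skipped with a flag", {
  # post-meal F stays at baseline while T rises: W undefined there
  s <- make_series(times = c(-60, -1, 5, 15, 30),
                   F = c(10, 10, 10, 20, 15), T = c(10, 10, 14, 42, 31))
  d <- decompose_series(s, fast_config())
  expect_match(d$flags, "W_undefined")
  expect_equal(d$auc_T, d$auc_F + d$auc_DD + d$auc_TD, tolerance = 1e-9)
})

test_that("cohort decomposition and group summaries track the simulation truth", {
  sc <- sim_scenario(seed = 310, n_subjects = 8, noise_cv = 0.05,
                     subject_cv = 0)
  sim <- simulate_readings(sc)
  dec <- decompose_mmtt(sim, fast_config())
  expect_s3_class(dec, "mmtt_decomposition")
  expect_equal(nrow(dec), 8)
  expect_equal(dec$auc_T, dec$auc_F + dec$auc_DD + dec$auc_TD,
               tolerance = 1e-9)

  smry <- summarize_groups(dec)
  expect_s3_class(smry, "mmtt_summary")
  expect_equal(nrow(smry), 4)  # one cell x four components

  # noise-free reference for the same scenario
  sc0 <- sc; sc0$noise_cv <- 0; sc0$n_subjects <- 1
  d0 <- decompose_mmtt(simulate_readings(sc0), fast_config())
  for (cc in c("AUC_T", "AUC_F", "AUC_DD", "AUC_TD")) {
    row <- smry[smry$component == cc, ]
    ref <- d0[[sub("AUC_", "auc_", cc)]]
    se <- row$sd / sqrt(row$n)
    expect_lt(abs(row$mean - ref), max(3 * se, 0.02 * abs(ref) + 1e-8))
  }
})

test_that("summaries handle single and identical subjects", {
  f <- c(10, 10, 20, 30, 25, 15, 12, 10)
  one <- make_series(F = f, T = 1.8 * f)
  d1 <- decompose_mmtt(one, fast_config())
  s1 <- summarize_groups(d1)
  expect_true(all(s1$sd == 0))
  expect_true(all(s1$flag == "n=1"))

  two <- rbind(one, make_series(F = f, T = 1.8 * f, subject = "S02"))
  s2 <- summarize_groups(decompose_mmtt(two, fast_config()))
  expect_true(all(s2$sd == 0))
  expect_true(all(s2$n == 2))

  expect_error(decompose_mmtt(one[-(1:8), ]), "no assay records")
  expect_error(summarize_groups(d1[0, ]), "summarize")
})
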