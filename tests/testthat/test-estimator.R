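test_that("w_ratio computes T/F and applies the clamping policy with flags", {
  w <- w_ratio(1, 2)
  expect_equal(as.numeric(w), 2)
  expect_identical(attr(w, "flags"), "")

  w <- w_ratio(1, 3.2)
  expect_equal(as.numeric(w), 3)
  expect_match(attr(w, "flags"), "longer_peptides")

  expect_warning(w <- w_ratio(1, 0.9), "clamped")
  expect_equal(as.numeric(w), 1)
  expect_match(attr(w, "flags"), "W<1")

  expect_error(w_ratio(0, 1), "positive")
  expect_error(w_ratio(1, NA), "non-finite")
  expect_error(w_ratio(1, 3.5, w_policy(above_max = "error")), "above 3")

  # vectorized with per-element flags
  expect_warning(w <- w_ratio(c(1, 2, 1), c(2, 1, 4)))
  expect_equal(as.numeric(w), c(2, 1, 3))
  expect_identical(attr(w, "flags") == "", c(TRUE, FALSE, FALSE))
})

test_that("a_bounds matches a brute-force feasibility scan", {
  b <- a_bounds(0, 0, 1)
  expect_equal(c(b$lo, b$hi), c(1, 1))
  b <- a_bounds(0, 0, 2)
  expect_equal(c(b$lo, b$hi), c(0, 0.5))
  expect_false(a_bounds(0, 0.1, 3)$feasible)  # A_hi = -0.2

  # independent oracle: scan A on a fine grid and test x, y >= 0 directly
  brute_bounds <- function(alpha, beta, W) {
    A <- seq(0, 1, by = 1e-4)
    x <- (1 - A - (1 + 2 * beta) * (W - 1) / 2) / (0.5 + 1.5 * alpha - beta)
    y <- (W - 1 - x) / 2
    ok <- x >= -1e-12 & y >= -1e-12
    if (!any(ok)) NULL else range(A[ok])
  }
  set.seed(52)
  for (i in 1:25) {
    al <- stats::runif(1, 0, 0.3); be <- stats::runif(1, 0, 0.3)
    W <- stats::runif(1, 1, 3)
    b <- a_bounds(al, be, W)
    br <- brute_bounds(al, be, W)
    if (is.null(br)) {
      expect_false(b$feasible)
    } else {
      expect_lt(abs(b$lo - br[1]), 2e-4)  # grid quantization slack
      expect_lt(abs(b$hi - br[2]), 2e-4)
    }
  }
})

test_that("solve_xy satisfies the amine balance and round-trips the forward model", {
  expect_equal(solve_xy(1, 0.2, 0.1, 1), c(x = 0, y = 0))
  expect_equal(solve_xy(0, 0, 0, 3), c(x = 0, y = 1))
  expect_equal(solve_xy(0.25, 0, 0, 2), c(x = 0.5, y = 0.25))
  expect_error(solve_xy(0.9, 0, 0, 2), "upper bound")
  expect_error(solve_xy(0, 0, 0, 1.2), "lower bound")

  # round trip: rebuild the class composition and push through the forward model
  set.seed(77)
  for (i in 1:40) {
    W <- stats::runif(1, 1.01, 2.99)
    al <- stats::runif(1, 0, 0.3)
    b <- a_bounds(al, 0, W)   # beta = 0 keeps every draw feasible
    A <- stats::runif(1, b$lo, b$hi)
    xy <- solve_xy(A, al, 0, W)
    cmp <- composition(A = A,
                       x1 = (1 - al) * xy["x"], x2 = al * xy["x"] / 2,
                       x3 = al * xy["x"] / 2, y1 = xy["y"])
    r <- forward_readings(cmp)
    expect_equal(r[["F"]], 1, tolerance = 1e-9)
    expect_equal(r[["T"]], W, tolerance = 1e-9)
    expect_equal(xy[["x"]] + 2 * xy[["y"]], W - 1, tolerance = 1e-12)
  }
})

test_that("shares_at_point gives convex before/after splits", {
  s <- shares_at_point(1, 0.1, 0.1, 1)
  expect_equal(s$before, c(free = 1, di = 0, tri = 0))
  expect_equal(s$after, c(free = 1, di = 0, tri = 0))

  s <- shares_at_point(0, 0, 0, 3)
  expect_equal(s$after, c(free = 0, di = 0, tri = 1))

  s <- shares_at_point(0.25, 0, 0, 2)
  expect_equal(s$before, c(free = 0.25, di = 0.5, tri = 0.25))
  expect_equal(s$after, c(free = 0.125, di = 0.5, tri = 0.375))

  set.seed(91)
  for (i in 1:20) {
    W <- stats::runif(1, 1.05, 2.5)
    al <- stats::runif(1, 0, 0.3); be <- stats::runif(1, 0, 0.05)
    b <- a_bounds(al, be, W)
    if (!b$feasible) next
    s <- shares_at_point(stats::runif(1, b$lo, b$hi), al, be, W)
    expect_equal(sum(s$before), 1, tolerance = 1e-12)
    expect_equal(sum(s$after), 1, tolerance = 1e-12)
    expect_true(all(c(s$before, s$after) >= -1e-12))
  }
})

test_that("mean_structure reproduces the degenerate limits exactly", {
  s1 <- mean_structure(1)
  expect_equal(s1$before, c(free = 1, di = 0, tri = 0))
  expect_equal(s1$after, c(free = 1, di = 0, tri = 0))
  s3 <- mean_structure(3)
  expect_equal(s3$after, c(free = 0, di = 0, tri = 1))
  expect_error(mean_structure(3.5), "\\[1, 3\\]")
})

test_that("quadrature matches the frozen independent-sampler values at W = 2", {
  s <- mean_structure(2, resolution = 400)
  expect_equal(s$before, ORACLE_W2$before, tolerance = 1e-3)
  expect_equal(s$after, ORACLE_W2$after, tolerance = 1e-3)
})

test_that("both integration routes conserve shares and the hydrolysis gain", {
  for (W in c(1.3, 1.9, 2.5)) {
    q <- mean_structure(W, resolution = 200)
    expect_equal(sum(q$before), 1, tolerance = 1e-9)
    expect_equal(sum(q$after), 1, tolerance = 1e-9)
    expect_equal(q$x_mean + 2 * q$y_mean, W - 1, tolerance = 1e-9)

    m <- mean_structure(W, method = "mc", n_samples = 1e5, seed = 3)
    expect_equal(sum(m$before), 1, tolerance = 3 * sum(m$se_before))
    expect_equal(sum(m$after), 1, tolerance = 3 * sum(m$se_after))
    expect_equal(m$x_mean + 2 * m$y_mean, W - 1, tolerance = 1e-9)
    # the two routes approximate the same expectation
    expect_equal(m$after, q$after, tolerance = 0.01)
  }
})

test_that("Monte-Carlo route needs a seed and is reproducible under it", {
  expect_error(mean_structure(2, method = "mc"), "seed")
  a <- mean_structure(2, method = "mc", n_samples = 5e4, seed = 99)
  b <- mean_structure(2, method = "mc", n_samples = 5e4, seed = 99)
  expect_identical(a$after, b$after)
})

test_that("after-shares shift monotonically from free amino acids to tripeptides in W", {
  grid <- seq(1, 3, by = 0.1)
  sh <- t(vapply(grid, function(w) mean_structure(w, resolution = 150)$after,
                 numeric(3)))
  expect_true(all(diff(sh[, "free"]) <= 1e-9))
  expect_true(all(diff(sh[, "tri"]) >= -1e-9))
})

test_that("decompose_reading scales the after-structure by the total signal", {
  d <- decompose_reading(1, 1)
  expect_equal(as.numeric(d), c(1, 0, 0))
  expect_identical(attr(d, "W"), 1)

  d <- decompose_reading(2, 6)
  expect_equal(as.numeric(d), c(0, 0, 6))

  d <- decompose_reading(1, 2, fast_config(400))
  expect_equal(as.numeric(d), unname(2 * mean_structure(2)$after),
               tolerance = 1e-12)
  expect_equal(sum(d), 2)
})

test_that("legacy F/W heuristic equals F squared over T", {
  expect_equal(legacy_free_aa(2, 4), 1)
  expect_equal(legacy_free_aa(1.5, 3), 0.75)
})
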