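#' Policy for out-of-range W ratios
#'
#' The model admits 1 <= W <= 3: W = 1 means only free amino acids and W = 3
#' is the ceiling reached by single-amine (class y1) tripeptides alone. Assay
#' noise can push measured W below 1; W above 3 is evidence of a small amount
#' of peptides longer than three residues. Neither is silently dropped.
#'
#' @param below_min,above_max `"clamp"` (default; record a flag) or `"error"`.
#' @return object of class `w_policy`.
#' @export
w_policy <- function(below_min = c("clamp", "error"),
                     above_max = c("clamp", "error")) {
  structure(list(below_min = match.arg(below_min),
                 above_max = match.arg(above_max),
                 w_min = 1, w_max = 3),
            class = "w_policy")
}

FLAG_SUB_UNITY <- "W<1_clamped_noise"
FLAG_LONG_PEPTIDE <- "W>3_possible_longer_peptides"

#' Ratio of total to free amine-group equivalents
#'
#' Factor W is the quotient T / F of the after- and before-hydrolysis
#' readings, clamped to the model range according to `policy`.
#'
#' @param f,t numeric vectors of before- and after-hydrolysis readings
#'   (µg/mL amine-group equivalents); recycled to common length.
#' @param policy a [w_policy()].
#' @return numeric vector of W values with attribute `"flags"`, a character
#'   vector (empty string = no flag).
#' @examples
#' w_ratio(1, 2)             # 2, no flag
#' w_ratio(1, 3.2)           # clamped to 3, longer-peptide flag
#' @export
w_ratio <- function(f, t, policy = w_policy()) {
  n <- max(length(f), length(t))
  f <- rep_len(as.numeric(f), n); t <- rep_len(as.numeric(t), n)
  if (any(!is.finite(f)) || any(!is.finite(t)))
    stop("non-finite readings")
  if (any(f <= 0)) stop("F must be positive (got F <= 0)")
  w <- t / f
  flags <- character(n)
  lo <- w < policy$w_min
  hi <- w > policy$w_max
  if (any(lo)) {
    if (policy$below_min == "error") stop("W below 1: T < F")
    w[lo] <- policy$w_min
    flags[lo] <- FLAG_SUB_UNITY
    warning(sum(lo), " reading(s) with T < F clamped to W = 1", call. = FALSE)
  }
  if (any(hi)) {
    if (policy$above_max == "error") stop("W above 3")
    w[hi] <- policy$w_max
    flags[hi] <- FLAG_LONG_PEPTIDE
  }
  attr(w, "flags") <- flags
  w
}

#' Feasible range of the free-amino-acid count A
#'
#' For fixed two-amine fractions `alpha` (dipeptides) and `beta` (tripeptides)
#' and ratio W, non-negativity of the dipeptide and tripeptide pools bounds the
#' normalized (F = 1) free-amino-acid count:
#' `max(1 - (1 + 1.5 alpha)(W - 1), 0) <= A <= 1 - (1 + 2 beta)(W - 1)/2`.
#' An (alpha, beta) cell with `lo > hi` supports no composition.
#'
#' @param alpha,beta two-amine fractions in \[0, 0.3\] (vectorized).
#' @param W scalar ratio in \[1, 3\].
#' @return list with numeric `lo`, `hi` and logical `feasible`.
#' @export
a_bounds <- function(alpha, beta, W) {
  stopifnot(length(W) == 1L, is.finite(W))
  if (W < 1 || W > 3) stop("W must lie in [1, 3]; apply w_ratio() first")
  if (any(alpha < 0 | alpha > 0.3) || any(beta < 0 | beta > 0.3))
    stop("alpha and beta must lie in [0, 0.3]")
  lo <- pmax(1 - (1 + 1.5 * alpha) * (W - 1), 0)
  hi <- 1 - (1 + 2 * beta) * (W - 1) / 2
  list(lo = lo, hi = hi, feasible = lo <= hi + 1e-15)
}

#' Solve for dipeptide and tripeptide pools
#'
#' Given a feasible point (A, alpha, beta) at ratio W, the amine-group balance
#' before hydrolysis (F = 1) and the hydrolysis gain x + 2y = W - 1 determine
#' the pools: `x = (1 - A - (1 + 2 beta)(W - 1)/2) / (0.5 + 1.5 alpha - beta)`
#' and `y = (W - 1 - x)/2`.
#'
#' @param A normalized free-amino-acid count.
#' @inheritParams a_bounds
#' @return named numeric `c(x = , y = )`, both non-negative.
#' @export
solve_xy <- function(A, alpha, beta, W) {
  b <- a_bounds(alpha, beta, W)
  if (any(A < b$lo - 1e-9))
    stop("A below feasible lower bound (tripeptide pool would be negative)")
  if (any(A > b$hi + 1e-9))
    stop("A above feasible upper bound (dipeptide pool would be negative)")
  x <- (1 - A - (1 + 2 * beta) * (W - 1) / 2) / (0.5 + 1.5 * alpha - beta)
  y <- (W - 1 - x) / 2
  c(x = max(x, 0), y = max(y, 0))
}

# Shares of F (before) and T (after) at feasible points; vectorized over
# equal-length A, alpha, beta. Linear in A for fixed (alpha, beta, W).
.shares <- function(A, alpha, beta, W) {
  x <- (1 - A - (1 + 2 * beta) * (W - 1) / 2) / (0.5 + 1.5 * alpha - beta)
  y <- (W - 1 - x) / 2
  list(before = cbind(free = A, di = x * (1 + 1.5 * alpha), tri = y * (1 + 2 * beta)),
       after  = cbind(free = A / W, di = x * (2 + 1.5 * alpha) / W,
                      tri = y * (3 + 2 * beta) / W),
       x = x, y = y)
}

#' Amine-group shares at one feasible point
#'
#' Before hydrolysis the F signal splits as (A, x(1 + 1.5 alpha),
#' y(1 + 2 beta)); hydrolysis adds x groups from dipeptides and 2y from
#' tripeptides, so the T signal splits as (A, x(2 + 1.5 alpha),
#' y(3 + 2 beta))/W. Both triples sum to one.
#'
#' @inheritParams solve_xy
#' @return list with numeric triples `before` and `after` (`free`, `di`, `tri`).
#' @export
shares_at_point <- function(A, alpha, beta, W) {
  xy <- solve_xy(A, alpha, beta, W)  # validates feasibility
  s <- .shares(A, alpha, beta, W)
  list(before = s$before[1, ], after = s$after[1, ], x = unname(xy["x"]),
       y = unname(xy["y"]))
}

#' Uniform-average mean structure for a given W
#'
#' With no information beyond W, every composition consistent with the
#' amine-group balance is taken as equally probable: the estimator is the
#' expectation of the share triples under the uniform distribution on the
#' three-dimensional feasible set of (alpha, beta, A). Two interchangeable
#' integration routes are provided: a deterministic nested quadrature
#' (midpoint rule over an (alpha, beta) grid, exact closed-form inner mean
#' over A, cells weighted by the length of their A interval) and Monte-Carlo
#' rejection sampling with an explicit seed. At the boundary values W = 1 and
#' W = 3 the set degenerates and the exact limits (pure free amino acids,
#' pure y1 tripeptides) are returned.
#'
#' @param W ratio in \[1, 3\] (apply [w_ratio()] to raw readings first).
#' @param method `"quadrature"` (default) or `"mc"`.
#' @param resolution grid points per axis for the quadrature (default 400).
#' @param n_samples Monte-Carlo sample budget (default 1e6).
#' @param seed integer seed, required when `method = "mc"`.
#' @param alpha_max,beta_max upper bounds of the two-amine fractions (0.3).
#' @return object of class `mean_structure`: list with `W`, `before` and
#'   `after` share triples (`free`, `di`, `tri`), pool means `A_mean`,
#'   `x_mean`, `y_mean`, `method`, and for MC the number of accepted samples
#'   `n_accepted`, Monte-Carlo standard errors `se_before`/`se_after`, `seed`.
#' @examples
#' mean_structure(2)
#' @export
mean_structure <- function(W, method = c("quadrature", "mc"),
                           resolution = 400L, n_samples = 1e6, seed = NULL,
                           alpha_max = 0.3, beta_max = 0.3) {
  method <- match.arg(method)
  stopifnot(length(W) == 1L, is.finite(W))
  if (W < 1 || W > 3) stop("W must lie in [1, 3]; apply w_ratio() first")
  eps <- 1e-9
  if (W - 1 < eps || 3 - W < eps) {
    # degenerate limits: the 3-D set collapses to measure zero
    pure <- if (W - 1 < eps) c(free = 1, di = 0, tri = 0)
            else             c(free = 0, di = 0, tri = 1)
    out <- list(W = W, before = pure, after = pure,
                A_mean = pure[["free"]], x_mean = 0,
                y_mean = if (W - 1 < eps) 0 else (W - 1) / 2,
                method = "limit")
    return(structure(out, class = "mean_structure"))
  }

  if (method == "quadrature") {
    m <- as.integer(resolution)
    stopifnot(m >= 2L)
    a_mid <- (seq_len(m) - 0.5) / m * alpha_max
    b_mid <- (seq_len(m) - 0.5) / m * beta_max
    g <- expand.grid(alpha = a_mid, beta = b_mid)
    bb <- a_bounds(g$alpha, g$beta, W)
    len <- pmax(bb$hi - bb$lo, 0)           # uniform-on-set weight per cell
    keep <- len > 0
    A_mid <- (bb$lo + bb$hi) / 2            # shares linear in A: exact inner mean
    s <- .shares(A_mid[keep], g$alpha[keep], g$beta[keep], W)
    wgt <- len[keep] / sum(len[keep])
    before <- colSums(s$before * wgt)
    after <- colSums(s$after * wgt)
    out <- list(W = W, before = before, after = after,
                A_mean = sum(A_mid[keep] * wgt),
                x_mean = sum(s$x * wgt), y_mean = sum(s$y * wgt),
                method = "quadrature", resolution = m)
  } else {
    if (is.null(seed)) stop("method = \"mc\" requires an explicit seed")
    # sample uniformly in a tight bounding box, reject outside the set
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(as.integer(seed))
    b_cap <- min(beta_max, max((2 / (W - 1) - 1) / 2, 0))  # A_hi >= 0 needs this
    A_top <- 1 - (W - 1) / 2
    A_bot <- max(1 - (1 + 1.5 * alpha_max) * (W - 1), 0)
    acc_a <- acc_b <- acc_A <- numeric(0)
    n_draw <- as.integer(n_samples)
    tries <- 0L
    while (length(acc_a) < n_samples && tries < 50L) {
      tries <- tries + 1L
      al <- stats::runif(n_draw, 0, alpha_max)
      be <- stats::runif(n_draw, 0, b_cap)
      A <- stats::runif(n_draw, A_bot, A_top)
      bb <- a_bounds(al, be, W)
      ok <- A >= bb$lo & A <= bb$hi
      acc_a <- c(acc_a, al[ok]); acc_b <- c(acc_b, be[ok]); acc_A <- c(acc_A, A[ok])
    }
    if (length(acc_a) < 100L)
      stop("rejection sampler accepted too few points; use method = \"quadrature\"")
    if (length(acc_a) > n_samples) {
      acc_a <- acc_a[seq_len(n_samples)]
      acc_b <- acc_b[seq_len(n_samples)]
      acc_A <- acc_A[seq_len(n_samples)]
    }
    s <- .shares(acc_A, acc_a, acc_b, W)
    n <- length(acc_A)
    out <- list(W = W, before = colMeans(s$before), after = colMeans(s$after),
                A_mean = mean(acc_A), x_mean = mean(s$x), y_mean = mean(s$y),
                method = "mc", n_accepted = n,
                se_before = apply(s$before, 2, stats::sd) / sqrt(n),
                se_after = apply(s$after, 2, stats::sd) / sqrt(n),
                seed = as.integer(seed))
  }
  structure(out, class = "mean_structure")
}

#' @export
print.mean_structure <- function(x, digits = 4, ...) {
  cat("Mean amine-group structure at W =", format(x$W, digits = 6),
      "(", x$method, ")\n")
  m <- rbind(`before hydrolysis (F)` = x$before,
             `after hydrolysis (T)` = x$after)
  colnames(m) <- c("free AA", "dipeptide", "tripeptide")
  print(round(m, digits))
  invisible(x)
}

#' @export
summary.mean_structure <- function(object, ...) {
  print(object, ...)
  cat("pool means: A =", format(object$A_mean, digits = 4),
      " x =", format(object$x_mean, digits = 4),
      " y =", format(object$y_mean, digits = 4),
      " (x + 2y =", format(object$x_mean + 2 * object$y_mean, digits = 6),
      "= W - 1)\n")
  invisible(object)
}

#' Estimator configuration
#'
#' Bundles the mean-structure settings and W policy used by the AUC pipeline
#' and recovery experiments.
#'
#' @inheritParams mean_structure
#' @param policy a [w_policy()].
#' @export
estimator_config <- function(method = c("quadrature", "mc"),
                             resolution = 400L, n_samples = 1e6, seed = NULL,
                             alpha_max = 0.3, beta_max = 0.3,
                             policy = w_policy()) {
  method <- match.arg(method)
  if (method == "mc" && is.null(seed))
    stop("estimator_config with method = \"mc\" requires an explicit seed")
  structure(list(method = method, resolution = as.integer(resolution),
                 n_samples = n_samples, seed = seed,
                 alpha_max = alpha_max, beta_max = beta_max, policy = policy),
            class = "estimator_config")
}

.mean_structure_cfg <- function(W, config) {
  mean_structure(W, method = config$method, resolution = config$resolution,
                 n_samples = config$n_samples, seed = config$seed,
                 alpha_max = config$alpha_max, beta_max = config$beta_max)
}

#' Split one reading pair into absolute amine-group equivalents
#'
#' Computes W from the readings (policy applied), evaluates the mean structure
#' at that W, and returns the after-hydrolysis split of the total signal T —
#' the "total amino acids" equivalents attributable to free amino acids,
#' dipeptide-derived and tripeptide-derived amino acids, in the reading's
#' units.
#'
#' @param f,t scalar before-/after-hydrolysis readings (µg/mL).
#' @param config an [estimator_config()].
#' @return named numeric `c(free = , di = , tri = )` summing to `t`, with
#'   attribute `"flags"` carrying any W-policy flag.
#' @export
decompose_reading <- function(f, t, config = estimator_config()) {
  w <- w_ratio(f, t, config$policy)
  s <- .mean_structure_cfg(as.numeric(w), config)
  out <- t * s$after  # split the measured total so the components sum to T
  attr(out, "flags") <- attr(w, "flags")
  attr(out, "W") <- as.numeric(w)
  out
}

#' Heuristic free-amino-acid estimate (historical)
#'
#' An early rule of thumb: divide the before-hydrolysis reading F by W to
#' approximate the amine groups on free amino acids (equivalently F^2 / T).
#' Kept for comparison; it is not consistent with the uniform-average
#' estimator and is not used by the pipeline.
#'
#' @param f,t readings as in [w_ratio()].
#' @return numeric estimate of free-amino-acid amine-group equivalents.
#' @export
legacy_free_aa <- function(f, t) {
  w <- w_ratio(f, t)
  as.numeric(f / w)
}

# Range of attainable after-hydrolysis shares over the feasible set at W
# (support of the uniform distribution); shares are linear in A, so extremes
# sit at interval endpoints. Used for coverage reporting.
.share_support <- function(W, resolution = 100L, alpha_max = 0.3, beta_max = 0.3) {
  if (W - 1 < 1e-9) return(cbind(lo = c(1, 0, 0), hi = c(1, 0, 0)))
  if (3 - W < 1e-9) return(cbind(lo = c(0, 0, 1), hi = c(0, 0, 1)))
  m <- as.integer(resolution)
  a_mid <- (seq_len(m) - 0.5) / m * alpha_max
  b_mid <- (seq_len(m) - 0.5) / m * beta_max
  g <- expand.grid(alpha = a_mid, beta = b_mid)
  bb <- a_bounds(g$alpha, g$beta, W)
  keep <- bb$feasible
  s_lo <- .shares(bb$lo[keep], g$alpha[keep], g$beta[keep], W)$after
  s_hi <- .shares(bb$hi[keep], g$alpha[keep], g$beta[keep], W)$after
  all <- rbind(s_lo, s_hi)
  cbind(lo = apply(all, 2, min), hi = apply(all, 2, max))
}
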