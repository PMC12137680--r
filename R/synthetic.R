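#' Synthetic MMTT scenario
#'
#' Ground truth for simulation: each of the three pools (free amino acids,
#' dipeptides, tripeptides; abundances in amine-group-equivalent µg/mL on the
#' molecule-count scale) follows a gamma-type rise-and-fall kernel
#' `amplitude * (t/tau) * exp(1 - t/tau)` after the meal, on top of a constant
#' baseline. Dipeptides split into classes x1-x3 by `alpha_true`
#' (x1 = (1-alpha) x, x2 = x3 = alpha x / 2) and tripeptides into y1-y4 by
#' `beta_true` (y1 = (1-beta) y, y2 = y3 = y4 = beta y / 3). Readings carry
#' independent multiplicative lognormal noise on F and T, plus an optional
#' lognormal subject-level random effect on the amplitudes.
#'
#' The default schedule matches the pig MMTT design (-60 and -1 min pre-meal,
#' then 5, 15, 30, 45, 60, 120 min); default kinetics give a postprandial W
#' sweeping roughly 1.2 to 2.4, with free amino acids absorbed fastest and
#' tripeptides slowest.
#'
#' @param schedule sampling times in minutes (negative = pre-meal).
#' @param amp_free,amp_di,amp_tri peak pool amplitudes (µg/mL equivalents).
#' @param tau_free,tau_di,tau_tri times-to-peak (min).
#' @param base_free,base_di,base_tri fasting baselines (µg/mL equivalents).
#' @param alpha_true,beta_true two-amine fractions in \[0, 0.3\].
#' @param noise_cv coefficient of variation of the multiplicative assay noise.
#' @param subject_cv coefficient of variation of the subject-level amplitude
#'   random effect (0 = identical subjects).
#' @param n_subjects cohort size.
#' @param seed integer seed (mandatory).
#' @param group,health_state,mmtt metadata labels for the generated records.
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(schedule = c(-60, -1, 5, 15, 30, 45, 60, 120),
                         amp_free = 50, amp_di = 25, amp_tri = 35,
                         tau_free = 20, tau_di = 40, tau_tri = 60,
                         base_free = 20, base_di = 2, base_tri = 2,
                         alpha_true = 0.15, beta_true = 0.15,
                         noise_cv = 0.1, subject_cv = 0.15,
                         n_subjects = 6, seed,
                         group = "Control", health_state = "Healthy",
                         mmtt = "HFD") {
  if (missing(seed)) stop("sim_scenario requires an explicit seed")
  amps <- c(free = amp_free, di = amp_di, tri = amp_tri)
  taus <- c(free = tau_free, di = tau_di, tri = tau_tri)
  bases <- c(free = base_free, di = base_di, tri = base_tri)
  stopifnot(all(amps >= 0), all(taus > 0), all(bases >= 0),
            noise_cv >= 0, subject_cv >= 0, n_subjects >= 1,
            alpha_true >= 0, alpha_true <= 0.3,
            beta_true >= 0, beta_true <= 0.3)
  structure(list(schedule = sort(schedule), amps = amps, taus = taus,
                 bases = bases, alpha_true = alpha_true, beta_true = beta_true,
                 noise_cv = noise_cv, subject_cv = subject_cv,
                 n_subjects = as.integer(n_subjects), seed = as.integer(seed),
                 group = group, health_state = health_state, mmtt = mmtt),
            class = "sim_scenario")
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("Synthetic MMTT scenario:", x$n_subjects, "subjects, seed", x$seed, "\n")
  cat("  schedule (min):", paste(x$schedule, collapse = ", "), "\n")
  cat("  amplitudes:", paste(names(x$amps), x$amps, collapse = "  "),
      " taus:", paste(x$taus, collapse = "/"), "\n")
  cat("  alpha_true =", x$alpha_true, " beta_true =", x$beta_true,
      " noise_cv =", x$noise_cv, "\n")
  invisible(x)
}

# rise-and-fall kinetic kernel, peak 1 at t = tau, 0 for t <= 0;
# shape-safe for scalar t with vector tau
.kernel <- function(t, tau) (t > 0) * (t / tau) * exp(1 - t / tau)

#' True composition at one time point
#'
#' Noise-free pool levels at time `t`, split into the model's species classes
#' by the scenario's true two-amine fractions.
#'
#' @param scenario a [sim_scenario()].
#' @param time time in minutes.
#' @param amp_scale optional length-3 multiplier (free, di, tri) for
#'   subject-level effects.
#' @return a [composition()].
#' @export
simulate_composition <- function(scenario, time, amp_scale = c(1, 1, 1)) {
  k <- .kernel(time, scenario$taus)
  pools <- scenario$bases + scenario$amps * amp_scale * k
  a <- scenario$alpha_true; b <- scenario$beta_true
  x <- pools[["di"]]; y <- pools[["tri"]]
  composition(A = pools[["free"]],
              x1 = (1 - a) * x, x2 = a * x / 2, x3 = a * x / 2,
              y1 = (1 - b) * y, y2 = b * y / 3, y3 = b * y / 3, y4 = b * y / 3)
}

#' Simulate an assay table for a cohort
#'
#' Runs the forward model on the true composition at every subject × time and
#' applies independent multiplicative lognormal noise (mean 1, CV
#' `noise_cv`) to F and T. Deterministic under the scenario's seed.
#'
#' @param scenario a [sim_scenario()].
#' @return data.frame in the assay-record schema (`subject_id`, `group`,
#'   `health_state`, `mmtt`, `time_min`, `F`, `T`) with attribute `"truth"`:
#'   the noise-free per-row true readings and after-hydrolysis components.
#' @export
simulate_readings <- function(scenario) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scenario$seed)
  sdl_n <- sqrt(log(1 + scenario$noise_cv^2))
  sdl_s <- sqrt(log(1 + scenario$subject_cv^2))
  rows <- truth <- vector("list", scenario$n_subjects)
  for (s in seq_len(scenario$n_subjects)) {
    scale <- exp(stats::rnorm(3, -sdl_s^2 / 2, sdl_s))
    per_t <- lapply(scenario$schedule, function(tm) {
      comp <- simulate_composition(scenario, tm, scale)
      r <- forward_readings(comp)
      a <- scenario$alpha_true; b <- scenario$beta_true
      x <- sum(comp[c("x1", "x2", "x3")]); y <- sum(comp[c("y1", "y2", "y3", "y4")])
      list(F = r[["F"]], T = r[["T"]],
           free_after = comp[["A"]], di_after = x * (2 + 1.5 * a),
           tri_after = y * (3 + 2 * b))
    })
    tt <- do.call(rbind, lapply(per_t, as.data.frame))
    noise_F <- exp(stats::rnorm(nrow(tt), -sdl_n^2 / 2, sdl_n))
    noise_T <- exp(stats::rnorm(nrow(tt), -sdl_n^2 / 2, sdl_n))
    id <- sprintf("S%02d", s)
    rows[[s]] <- data.frame(subject_id = id, group = scenario$group,
                            health_state = scenario$health_state,
                            mmtt = scenario$mmtt,
                            time_min = scenario$schedule,
                            F = tt$F * noise_F, T = tt$T * noise_T,
                            stringsAsFactors = FALSE)
    truth[[s]] <- cbind(data.frame(subject_id = id,
                                   time_min = scenario$schedule), tt)
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "truth") <- do.call(rbind, c(truth, list(make.row.names = FALSE)))
  out
}

# True baseline-adjusted AUC shares for one subject's truth rows
.true_auc_shares <- function(tr) {
  pre <- tr$time_min < 0
  post <- tr[!pre, , drop = FALSE]
  comp <- cbind(free = post$free_after - mean(tr$free_after[pre]),
                di = post$di_after - mean(tr$di_after[pre]),
                tri = post$tri_after - mean(tr$tri_after[pre]))
  comp <- pmax(comp, 0)
  auc <- apply(comp, 2, function(v) pracma::trapz(post$time_min, v))
  auc / sum(auc)
}

#' Parameter-recovery experiment
#'
#' Simulates a cohort, runs the AUC decomposition pipeline on the noisy
#' readings, and compares the estimated after-hydrolysis AUC shares
#' (AUC_F, AUC_DD, AUC_TD relative to AUC_T) per subject against the true
#' shares computed noise-free from the scenario's composition curves.
#' Coverage is the fraction of post-meal points whose true after-hydrolysis
#' share triple lies inside the attainable share range of the feasible set at
#' the estimated W.
#'
#' @param scenario a [sim_scenario()].
#' @param config an [estimator_config()].
#' @param mode decomposition mode, see [decompose_series()].
#' @return object of class `recovery_report`: data.frame with one row per
#'   component (`free`, `di`, `tri`) giving `bias`, `rmse` and `coverage`,
#'   with attributes `per_subject` (share errors) and `scenario`.
#' @export
run_recovery <- function(scenario, config = estimator_config(),
                         mode = "pointwise") {
  sim <- simulate_readings(scenario)
  truth <- attr(sim, "truth")
  dec <- decompose_mmtt(sim, config, mode)
  est <- coef(dec) / dec$auc_T
  colnames(est) <- c("free", "di", "tri")
  tru <- t(vapply(split(truth, truth$subject_id), .true_auc_shares,
                  numeric(3)))
  tru <- tru[match(dec$subject_id, rownames(tru)), , drop = FALSE]
  err <- est - tru
  # coverage: true pointwise shares vs attainable range at the estimated W
  inside <- total <- 0L
  for (s in unique(truth$subject_id)) {
    tr <- truth[truth$subject_id == s & truth$time_min > 0, ]
    obs <- sim[sim$subject_id == s & sim$time_min > 0, ]
    for (i in seq_len(nrow(tr))) {
      tshare <- c(tr$free_after[i], tr$di_after[i], tr$tri_after[i])
      tshare <- tshare / sum(tshare)
      w <- suppressWarnings(w_ratio(obs$F[i], obs$T[i], config$policy))
      sup <- .share_support(as.numeric(w))
      total <- total + 1L
      if (all(tshare >= sup[, "lo"] - 1e-9 & tshare <= sup[, "hi"] + 1e-9))
        inside <- inside + 1L
    }
  }
  rep <- data.frame(component = colnames(err),
                    bias = colMeans(err),
                    rmse = sqrt(colMeans(err^2)),
                    coverage = inside / total,
                    row.names = NULL)
  structure(rep, class = c("recovery_report", "data.frame"),
            per_subject = err, scenario = scenario, mode = mode)
}

#' @export
print.recovery_report <- function(x, digits = 4, ...) {
  sc <- attr(x, "scenario")
  cat("Recovery report:", sc$n_subjects, "subjects, noise_cv =", sc$noise_cv,
      ", mode =", attr(x, "mode"), "\n")
  df <- as.data.frame(x)
  df$bias <- round(df$bias, digits); df$rmse <- round(df$rmse, digits)
  df$coverage <- round(df$coverage, digits)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Cohort-size sweep of recovery error
#'
#' Estimates, for each cohort size, the root-mean-square error of the
#' cohort-mean after-hydrolysis AUC shares around the cohort-mean truth,
#' over `reps` replicate cohorts. Replicates draw the largest cohort once and
#' evaluate nested subsets, so the sizes are compared on common noise draws.
#'
#' @param scenario a [sim_scenario()]; its `n_subjects` is ignored.
#' @param sizes increasing cohort sizes (default 3, 6, 12).
#' @param reps number of replicate cohorts.
#' @param config an [estimator_config()].
#' @return data.frame with one row per cohort size and per-component RMSE of
#'   the cohort-mean share (columns `rmse_free`, `rmse_di`, `rmse_tri`,
#'   `rmse_overall`).
#' @export
recovery_by_cohort_size <- function(scenario, sizes = c(3, 6, 12), reps = 50,
                                    config = estimator_config()) {
  sizes <- sort(as.integer(sizes))
  nmax <- max(sizes)
  err_by_size <- lapply(sizes, function(n) matrix(NA_real_, reps, 3))
  names(err_by_size) <- as.character(sizes)
  for (r in seq_len(reps)) {
    sc <- scenario
    sc$n_subjects <- nmax
    sc$seed <- scenario$seed + r - 1L
    rep_r <- run_recovery(sc, config)
    err <- attr(rep_r, "per_subject")
    for (n in sizes) {
      e <- colMeans(err[seq_len(n), , drop = FALSE])
      err_by_size[[as.character(n)]][r, ] <- e
    }
  }
  out <- do.call(rbind, lapply(sizes, function(n) {
    e <- err_by_size[[as.character(n)]]
    r <- sqrt(colMeans(e^2))
    data.frame(n_subjects = n, rmse_free = r[1], rmse_di = r[2],
               rmse_tri = r[3], rmse_overall = sqrt(mean(e^2)))
  }))
  rownames(out) <- NULL
  out
}
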