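# Synthetic EMA cohorts with the exact statistical structure the mixed-effects
# analysis assumes, so calibration / identifiability / sensitivity are testable
# end to end with known ground truth.

#' Specification of a synthetic EMA cohort
#'
#' Defaults emulate the reference study conditions: 37 patients over an 84-day
#' diary window; population parameters from [population_params()]; per-patient
#' effective parameters `beta_i = beta + b_i` with `b_i ~ N(0, Psi)` over the
#' varying subset `{a2, a3, d2, d3}` ([psi_fixture()]); initial conditions
#' drawn from truncated normals matching the reference cohort's summary
#' statistics ([ic_stats()]); additive Gaussian observation noise with one
#' shared variance on both outcomes; configurable per-day missingness; and
#' optional observation-scale rounding/clipping (drinks to integers in 0..17,
#' desire to integers in 0..12).
#'
#' @param n_patients Cohort size (default 37).
#' @param horizon Diary window length in days (default 84).
#' @param beta Fixed-effects parameter vector (all six coefficients).
#' @param psi Random-effects covariance over `varying` (symmetric PSD).
#' @param sigma2 Observation-noise variance (shared by both outcomes).
#' @param sigma2_desire Optional separate desire-noise variance (default
#'   `NULL`: single shared variance, matching the calibration likelihood).
#' @param varying Parameters receiving random effects.
#' @param ic_table IC distribution table as in [ic_stats()].
#' @param missingness Per-day masking probability in \[0, 1). Day 1 is never
#'   masked (it is the in-person baseline visit and pins the initial
#'   conditions).
#' @param round_and_clip Round/clip observations to the reporting scale.
#' @param trajectory_bounds Named vector `c(A = , D = )`: a candidate
#'   patient's noiseless latent trajectory must stay within these magnitudes
#'   over the horizon, or the random effect is redrawn. Defaults anchor to
#'   the observation scale of the reference cohort: 101 drinks (the largest
#'   raw count ever reported there) and twice the 0-12 desire scale. Without
#'   such a bound, independent normal draws of the four varying coefficients
#'   routinely land past the unit root of the dynamics and produce "diary"
#'   entries of 10^8 or more drinks per night — not an EMA cohort by any
#'   standard, and numerically degenerate to fit. Set to `NULL` to disable.
#' @param seed Optional integer seed (identical seed, identical cohort).
#' @return List of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 37, horizon = 84,
                        beta = population_params(),
                        psi = psi_fixture(),
                        sigma2 = 1.0,
                        sigma2_desire = NULL,
                        varying = c("a2", "a3", "d2", "d3"),
                        ic_table = ic_stats(),
                        missingness = 0.25,
                        round_and_clip = FALSE,
                        trajectory_bounds = c(A = 101, D = 24),
                        seed = NULL) {
  beta <- .as_params(beta)
  psi <- as.matrix(psi)
  if (nrow(psi) != length(varying) || ncol(psi) != length(varying))
    stop("psi must be ", length(varying), "x", length(varying), call. = FALSE)
  if (max(abs(psi - t(psi))) > 1e-10)
    stop("psi must be symmetric", call. = FALSE)
  if (min(eigen(psi, symmetric = TRUE, only.values = TRUE)$values) < -1e-10)
    stop("psi must be positive semi-definite", call. = FALSE)
  if (sigma2 < 0) stop("sigma2 must be >= 0", call. = FALSE)
  if (missingness < 0 || missingness >= 1)
    stop("missingness must lie in [0, 1)", call. = FALSE)
  structure(list(n_patients = n_patients, horizon = horizon, beta = beta,
                 psi = psi, sigma2 = sigma2, sigma2_desire = sigma2_desire,
                 varying = varying, ic_table = ic_table,
                 missingness = missingness,
                 round_and_clip = isTRUE(round_and_clip),
                 trajectory_bounds = trajectory_bounds, seed = seed),
            class = "cohort_spec")
}

# inverse-CDF draw from N(mean, sd) truncated to [lo, hi]
.rtruncnorm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  stats::qnorm(plo + stats::runif(n) * (phi - plo), mean, sd)
}

#' Draw per-patient effective parameters
#'
#' `beta_i = beta + b_i` with `b_i ~ N(0, Psi)` on the varying subset; the
#' fixed coefficients are copied from `beta`. Nonnegativity of `a2` and `d2`
#' is enforced by rejection (re-draw until valid). The trajectory-realism
#' bound of [cohort_spec()] is *not* applied here (it depends on each
#' patient's initial conditions); [generate_cohort()] applies it.
#'
#' @param spec A [cohort_spec()].
#' @return Matrix `n_patients x 6` with parameter columns.
#' @export
draw_effective_parameters <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients
  beta_mat <- matrix(rep(spec$beta, each = n), nrow = n,
                     dimnames = list(NULL, names(spec$beta)))
  for (i in seq_len(n)) beta_mat[i, spec$varying] <- .draw_one_effective(spec)
  beta_mat
}

# one rejection-sampled random-effect draw (nonnegativity only)
.draw_one_effective <- function(spec) {
  nonneg <- intersect(spec$varying, c("a1", "a2", "d1", "d2"))
  repeat {
    b <- MASS::mvrnorm(1, mu = rep(0, length(spec$varying)), Sigma = spec$psi)
    cand <- spec$beta[spec$varying] + b
    if (all(cand[nonneg] >= 0)) return(cand)
  }
}

# accept a candidate patient iff its noiseless trajectory stays within the
# realism bounds (always TRUE when bounds are disabled)
.traj_ok <- function(params, ics, horizon, bounds) {
  if (is.null(bounds)) return(TRUE)
  m <- sim_core(unname(params), ics[["A0"]], ics[["A1"]], ics[["D1"]],
                as.integer(horizon), FALSE)
  all(is.finite(m)) && max(abs(m[, 1])) <= bounds[["A"]] &&
    max(abs(m[, 2])) <= bounds[["D"]]
}

#' Population mean of the generator's effective parameters
#'
#' The fixed effect a calibration should recover is the mean of the
#' distribution the effective parameters are actually drawn from. With the
#' trajectory-realism bound active that distribution is a truncated normal
#' (mixed over the initial-condition distribution), so its mean differs
#' slightly from the nominal `beta`; this helper estimates it by Monte Carlo
#' from the generator's own draw rule.
#'
#' @param spec A [cohort_spec()].
#' @param n_draws Number of Monte Carlo patients (default 20000).
#' @param seed Optional integer seed.
#' @return Named numeric vector over all six coefficients (fixed ones equal
#'   their `beta` values exactly).
#' @export
effective_population_mean <- function(spec, n_draws = 20000, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(seed)) set.seed(seed)
  it <- spec$ic_table
  acc <- matrix(NA_real_, n_draws, length(spec$varying))
  for (i in seq_len(n_draws)) {
    ics <- c(A0 = .draw_ic_one(it, "A0"), A1 = .draw_ic_one(it, "A1"),
             D1 = .draw_ic_one(it, "D1"))
    repeat {
      cand <- .draw_one_effective(spec)
      p <- spec$beta
      p[spec$varying] <- cand
      if (.traj_ok(p, ics, spec$horizon, spec$trajectory_bounds)) break
    }
    acc[i, ] <- cand
  }
  out <- spec$beta
  out[spec$varying] <- colMeans(acc)
  out
}

.draw_ic_one <- function(ic_table, cond) {
  r <- ic_table[ic_table$condition == cond, ]
  .rtruncnorm(1, r$mean, r$sd, r$min, r$max)
}

#' Generate a synthetic EMA cohort with attached ground truth
#'
#' Per patient: draws initial conditions from the truncated IC distributions,
#' simulates the noiseless trajectory under the patient's effective
#' parameters, adds independent Gaussian observation noise to each day's
#' drinks and desire (except day 1, whose reported values define the
#' initial conditions the analysis conditions on), optionally rounds/clips
#' to the reporting scale, and masks days as missing. The generating parameters, initial conditions, and
#' noiseless trajectories are attached as the `ground_truth` attribute for
#' recovery testing.
#'
#' @param spec A [cohort_spec()].
#' @return List of [patient_series()] with attribute `ground_truth`
#'   (list with `beta_i` matrix, `ics` matrix, `trajectories` list, `spec`).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_patients
  h <- spec$horizon
  it <- spec$ic_table
  beta_i <- matrix(rep(spec$beta, each = n), nrow = n,
                   dimnames = list(NULL, names(spec$beta)))
  ics <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("A0", "A1", "D1")))
  for (i in seq_len(n)) {
    ics[i, ] <- c(.draw_ic_one(it, "A0"), .draw_ic_one(it, "A1"),
                  .draw_ic_one(it, "D1"))
    repeat {
      cand <- .draw_one_effective(spec)
      p <- spec$beta
      p[spec$varying] <- cand
      if (.traj_ok(p, ics[i, ], h, spec$trajectory_bounds)) break
    }
    beta_i[i, spec$varying] <- cand
  }
  sdA <- sqrt(spec$sigma2)
  sdD <- if (is.null(spec$sigma2_desire)) sdA else sqrt(spec$sigma2_desire)
  trajectories <- vector("list", n)
  cohort <- vector("list", n)
  ids <- sprintf("S%03d", seq_len(n))
  for (i in seq_len(n)) {
    traj <- simulate_trajectory(beta_i[i, ], ics[i, ], h, clip_nonneg = FALSE)
    trajectories[[i]] <- traj
    # noise on days 2..horizon only: the day-1 diary values are what define
    # the initial conditions in the downstream analysis, which conditions on
    # them as known. Noise on day 1 would make the generative process
    # inconsistent with the assumed likelihood (an initial-condition error
    # amplifies geometrically for near-unit-root patients).
    noiseA <- stats::rnorm(h, 0, sdA); noiseA[1] <- 0
    noiseD <- stats::rnorm(h, 0, sdD); noiseD[1] <- 0
    obsA <- traj$A + noiseA
    obsD <- traj$D + noiseD
    if (spec$round_and_clip) {
      obsA <- pmin(pmax(round(obsA), 0), 17)
      obsD <- pmin(pmax(round(obsD), 0), 12)
    }
    miss <- stats::runif(h) < spec$missingness
    miss[1] <- FALSE
    obsA[miss] <- NA_real_
    obsD[miss] <- NA_real_
    cohort[[i]] <- patient_series(ids[i], traj$day, obsA, obsD,
                                  tlfb_baseline = unname(ics[i, "A0"]),
                                  n_days = h)
  }
  names(cohort) <- ids
  rownames(beta_i) <- ids
  rownames(ics) <- ids
  names(trajectories) <- ids
  attr(cohort, "ground_truth") <- list(beta_i = beta_i, ics = ics,
                                       trajectories = trajectories, spec = spec)
  cohort
}

#' Write a synthetic cohort in the diary/baseline CSV dialect
#'
#' Emits the same two CSVs [read_diary_csv()] and [read_baseline_csv()]
#' consume, plus a ground-truth JSON sidecar when requested.
#'
#' @param cohort Output of [generate_cohort()].
#' @param diary_path,baseline_path Output CSV paths.
#' @param truth_path Optional path for the ground-truth JSON sidecar.
#' @return Invisibly, the vector of written paths.
#' @export
write_cohort_csv <- function(cohort, diary_path, baseline_path,
                             truth_path = NULL) {
  diary <- do.call(rbind, lapply(cohort, function(s) {
    data.frame(patient_id = s$patient_id, day = s$records$day,
               drinks = s$records$drinks, desire = s$records$desire)
  }))
  utils::write.csv(diary, diary_path, row.names = FALSE, na = "")
  baseline <- data.frame(
    patient_id = vapply(cohort, `[[`, "", "patient_id"),
    tlfb_avg_drinks_per_day = vapply(cohort, `[[`, 0, "tlfb_baseline"))
  utils::write.csv(baseline, baseline_path, row.names = FALSE)
  paths <- c(diary_path, baseline_path)
  gt <- attr(cohort, "ground_truth")
  if (!is.null(truth_path) && !is.null(gt)) {
    jsonlite::write_json(
      list(beta_i = gt$beta_i, ics = gt$ics,
           sigma2 = gt$spec$sigma2, missingness = gt$spec$missingness,
           seed = gt$spec$seed),
      truth_path, digits = NA, matrix = "rowmajor")
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}
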