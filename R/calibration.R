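# Bayesian mixed-effects calibration of the dual-process model.
#
# Hierarchy: per patient i, effective parameters beta_i = beta + b_i with
# b_i ~ N(0, Psi) over the varying subset; observations are the full
# simulated trajectory from the patient's data-pinned initial conditions
# plus iid N(0, sigma2) noise on both outcomes. Sampling alternates
# delayed-rejection adaptive Metropolis (DRAM) updates of each beta_i block
# with conjugate Gibbs draws of beta (normal), Psi (inverse-Wishart), and
# sigma2 (inverse-gamma).

#' Parameter-count bookkeeping for the mixed-effects model
#'
#' With `m` varying quantities and `N` patients, the calibration must
#' determine `m` fixed effects, `m * N` random effects, one error variance,
#' and `m (m + 1) / 2` covariance elements.
#'
#' @param m Number of varying quantities (>= 1).
#' @param N Number of patients (>= 1).
#' @return Integer total; component counts in attribute `components`.
#' @export
count_parameters <- function(m, N) {
  if (m < 1 || N < 1) stop("m and N must be positive", call. = FALSE)
  comp <- c(fixed_effects = m, random_effects = m * N, error_variance = 1,
            covariance_elements = m * (m + 1) / 2)
  structure(sum(comp), components = comp)
}

#' Mixed-effects model specification
#'
#' Declares which coefficients receive random effects and the values at which
#' the rest are fixed. Initial conditions are taken from the data per patient
#' (`A1`/`D1` from the first recorded diary values, `A0` from the TLFB
#' baseline), not estimated.
#'
#' @param varying Parameter names receiving random effects.
#' @param fixed_values Named values for the non-varying coefficients.
#' @return List of class `mixed_effects_spec`.
#' @export
mixed_effects_spec <- function(varying = c("a2", "a3", "d2", "d3"),
                               fixed_values = c(a1 = 0.2829, d1 = 0.8144)) {
  all6 <- c("a1", "a2", "a3", "d1", "d2", "d3")
  if (length(intersect(varying, names(fixed_values))) > 0)
    stop("varying and fixed parameters must be disjoint", call. = FALSE)
  if (!setequal(c(varying, names(fixed_values)), all6))
    stop("varying + fixed must cover all six coefficients", call. = FALSE)
  structure(list(varying = varying, fixed_values = fixed_values),
            class = "mixed_effects_spec")
}

#' Prior configuration for the Bayesian calibration
#'
#' The fixed-effects prior is flat (improper): its Gibbs draw uses only the
#' random-effects structure. `sigma2 ~ Inv-Gamma` with shape `n0 / 2` and
#' scale `n0 * s0_squared / 2`; `Psi ~ Inv-Wishart` in the scale-matrix
#' parameterization with density proportional to
#' `|Psi|^-(rho0 + p + 1)/2 exp(-tr(S0 Psi^-1) / 2)`, where the scale matrix
#' is `S0 = (rho0 - p - 1) * Psi0` so that the prior *mean* equals `Psi0`.
#' A large `rho0` (default 100) then genuinely expresses confidence in the
#' preliminary frequentist covariance estimate and shortens burn-in; with the
#' raw covariance itself as the scale matrix, a large `rho0` would instead
#' shrink the prior mean toward zero by a factor `rho0 - p - 1`,
#' contradicting its stated purpose.
#'
#' @param beta0 Initial fixed-effects location (named over the varying set).
#' @param s0_squared Prior scale for the error variance.
#' @param Psi0 Prior mean of the random-effects covariance.
#' @param n0 Prior weight on `s0_squared` (default 1: nearly noninformative).
#' @param rho0 Inverse-Wishart degrees of freedom (default 100; must exceed
#'   `p + 1` for the prior mean to exist).
#' @return List of class `prior_config`.
#' @export
prior_config <- function(beta0, s0_squared, Psi0, n0 = 1, rho0 = 100) {
  Psi0 <- as.matrix(Psi0)
  if (n0 < 1) stop("n0 must be >= 1", call. = FALSE)
  if (rho0 <= nrow(Psi0) + 1)
    stop("rho0 must exceed dimension + 1", call. = FALSE)
  if (s0_squared <= 0) stop("s0_squared must be positive", call. = FALSE)
  structure(list(beta0 = beta0, s0_squared = s0_squared, Psi0 = Psi0,
                 n0 = n0, rho0 = rho0),
            class = "prior_config")
}

# Per-patient observation bundle: initial conditions per the ic policy and
# the NA-masked observation vectors the likelihood consumes.
.patient_obs <- function(series) {
  rec <- series$records
  iA <- which(!is.na(rec$drinks))[1]
  iD <- which(!is.na(rec$desire))[1]
  if (is.na(iA) || is.na(iD))
    stop("patient ", series$patient_id, " has no observed drinks or desire",
         call. = FALSE)
  list(A0 = series$tlfb_baseline,
       A1 = rec$drinks[iA], D1 = rec$desire[iD],
       obsA = rec$drinks, obsD = rec$desire,
       n_obs = sum(!is.na(rec$drinks)) + sum(!is.na(rec$desire)))
}

# Expand a varying-subset vector to the full six-coefficient vector.
.full_params <- function(theta_v, spec) {
  p <- numeric(6)
  names(p) <- c("a1", "a2", "a3", "d1", "d2", "d3")
  p[spec$varying] <- theta_v
  p[names(spec$fixed_values)] <- spec$fixed_values
  p
}

#' Mixed-effects state container
#'
#' @param beta Fixed-effects vector over the varying set.
#' @param effective Matrix of per-patient effective vectors (patients x
#'   varying).
#' @param sigma2 Error variance (> 0).
#' @param psi Random-effects covariance (symmetric positive definite).
#' @return List of class `mixed_effects_state`.
#' @export
mixed_effects_state <- function(beta, effective, sigma2, psi) {
  psi <- as.matrix(psi)
  effective <- as.matrix(effective)
  if (sigma2 <= 0) stop("sigma2 must be positive", call. = FALSE)
  if (max(abs(psi - t(psi))) > 1e-10) stop("psi must be symmetric", call. = FALSE)
  structure(list(beta = beta, effective = effective, sigma2 = sigma2,
                 psi = psi),
            class = "mixed_effects_state")
}

#' Log-likelihood kernel of the mixed-effects model
#'
#' The log of the likelihood kernel: the sum over patients of
#' `-SS_i / (2 sigma2)`, where `SS_i` is the squared-residual sum of the full
#' simulated trajectory (from the patient's data-pinned initial conditions,
#' under that patient's effective parameters) against the observed drinks and
#' desire on non-missing days, both outcomes entering the same sum. No
#' normalization constant is included (the `-(n/2) log sigma2` term belongs
#' to the sigma2 Gibbs step, which uses the normalized conditional).
#'
#' @param cohort List of `patient_series` (one per row of
#'   `state$effective`).
#' @param state A [mixed_effects_state()].
#' @param spec A [mixed_effects_spec()].
#' @param clip_nonneg Simulate with non-negativity clipping (off for
#'   calibration by default).
#' @return Scalar log-likelihood kernel.
#' @export
log_likelihood <- function(cohort, state, spec = mixed_effects_spec(),
                           clip_nonneg = FALSE) {
  tot <- 0
  for (i in seq_along(cohort)) {
    ob <- .patient_obs(cohort[[i]])
    p <- .full_params(state$effective[i, ], spec)
    tot <- tot - traj_ss(unname(p), ob$A0, ob$A1, ob$D1, ob$obsA, ob$obsD,
                         clip_nonneg) / (2 * state$sigma2)
  }
  tot
}

#' Log random-effects prior kernel
#'
#' Sum over patients of `-(beta_i - beta)' Psi^-1 (beta_i - beta) / 2`
#' (determinant terms belong to the Psi Gibbs step).
#'
#' @param state A [mixed_effects_state()].
#' @return Scalar.
#' @export
log_prior_effective <- function(state) {
  R <- tryCatch(chol(state$psi),
                error = function(e) stop("psi is numerically singular",
                                         call. = FALSE))
  dev <- sweep(state$effective, 2, state$beta)
  z <- forwardsolve(t(R), t(dev))
  -0.5 * sum(z^2)
}

#' Per-patient least-squares fit of all six coefficients
#'
#' Minimizes the squared-residual sum of the full trajectory simulation
#' against one patient's observed drinks and desire. Initialization comes
#' from one-step-ahead linear regressions of tonight's drinks and desire on
#' their lagged predictors (exact at zero noise); Nelder-Mead refines the
#' full-trajectory objective from that start plus `n_starts - 1` jittered
#' restarts. `a1, a2, d1, d2` are kept nonnegative by penalty.
#'
#' @param series A `patient_series` (should pass [inclusion_filter()]).
#' @param n_starts Number of optimizer starts (default 3).
#' @param clip_nonneg Simulate with clipping during fitting.
#' @param fix Optional named values to hold fixed during the fit (profile
#'   fit over the remaining coefficients); default `NULL` fits all six.
#' @return List with `estimate` (six named coefficients), `value` (residual
#'   sum of squares), `sigma2_hat` (residual variance, SS / (n_obs - n_free)),
#'   `n_obs`, and `converged`.
#' @export
per_patient_fit <- function(series, n_starts = 3, clip_nonneg = FALSE,
                            fix = NULL) {
  ob <- .patient_obs(series)
  rec <- series$records
  n <- nrow(rec)
  A_n <- rec$drinks[3:n]; A_l <- rec$drinks[2:(n - 1)]; A_ll <- rec$drinks[1:(n - 2)]
  D_n <- rec$desire[3:n]; D_l <- rec$desire[2:(n - 1)]
  okA <- stats::complete.cases(A_n, A_l, A_ll, D_n, D_l)
  okD <- stats::complete.cases(D_n, A_l, D_l, A_ll)
  init <- c(a1 = 0.3, a2 = 0.9, a3 = 0, d1 = 0.5, d2 = 0.5, d3 = 0)
  if (sum(okA) >= 4 && sum(okD) >= 4) {
    dD <- (D_n - D_l)[okA]; dA_A <- (A_l - A_ll)[okA]
    cfA <- tryCatch(stats::coef(stats::lm(A_n[okA] ~ 0 + dD + A_l[okA] + dA_A)),
                    error = function(e) NULL)
    dA_D <- (A_l - A_ll)[okD]
    cfD <- tryCatch(stats::coef(stats::lm(D_n[okD] ~ 0 + A_l[okD] + D_l[okD] + dA_D)),
                    error = function(e) NULL)
    if (!is.null(cfA) && !is.null(cfD) && !anyNA(c(cfA, cfD))) {
      init <- c(a1 = max(0, cfA[[1]]), a2 = max(0, cfA[[2]]), a3 = cfA[[3]],
                d1 = max(0, cfD[[1]]), d2 = max(0, cfD[[2]]), d3 = cfD[[3]])
    }
  }
  all6 <- c("a1", "a2", "a3", "d1", "d2", "d3")
  names(init) <- all6
  if (!is.null(fix)) init[names(fix)] <- fix
  free <- setdiff(all6, names(fix))
  nonneg <- intersect(free, c("a1", "a2", "d1", "d2"))
  full <- init
  obj <- function(th) {
    if (any(th[match(nonneg, free)] < 0)) return(1e12)
    full[free] <- th
    v <- traj_ss(unname(full), ob$A0, ob$A1, ob$D1, ob$obsA, ob$obsD,
                 clip_nonneg)
    if (!is.finite(v)) 1e12 else v
  }
  best <- NULL
  for (s in seq_len(n_starts)) {
    start <- if (s == 1) init[free]
             else init[free] + stats::rnorm(length(free), 0, 0.05)
    start[nonneg] <- pmax(start[nonneg], 0)
    fit <- stats::optim(start, obj, method = "Nelder-Mead",
                        control = list(maxit = 3000, reltol = 1e-12))
    fit <- stats::optim(fit$par, obj, method = "Nelder-Mead",
                        control = list(maxit = 2000, reltol = 1e-12))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  est <- full
  est[free] <- best$par
  list(estimate = est, value = best$value,
       sigma2_hat = best$value / max(ob$n_obs - length(free), 1),
       n_obs = ob$n_obs, converged = best$convergence == 0)
}

#' Preliminary frequentist calibration of the cohort
#'
#' Two-stage estimator used to seed the Bayesian run: fits each patient
#' separately with [per_patient_fit()], then takes the componentwise median
#' as the fixed-effects seed, the sample covariance of the per-patient
#' estimates (over the varying subset) as the `Psi0` scale, and the pooled
#' residual variance as the `s0_squared` seed. A singular covariance (e.g.
#' identical patients) is jittered to positive definiteness and flagged.
#'
#' @param cohort List of `patient_series` (>= 2 patients).
#' @param spec A [mixed_effects_spec()].
#' @param n_starts Optimizer starts per patient.
#' @param fix_nonvarying Hold the spec's fixed coefficients at their fixed
#'   values during the per-patient fits (default `TRUE`). This matters: a
#'   free six-parameter fit can drift along the collinearity ridge, and its
#'   varying components then pair badly with the fixed values the
#'   mixed-effects model imposes. The free fits (used as evaluation points
#'   for the identifiability screen) are a separate call.
#' @return A [prior_config()] with extra elements `estimates` (patients x 6
#'   matrix) and `jittered` (logical).
#' @export
initial_frequentist_fit <- function(cohort, spec = mixed_effects_spec(),
                                    n_starts = 3, fix_nonvarying = TRUE) {
  if (length(cohort) < 2)
    stop("need at least 2 patients to form a covariance", call. = FALSE)
  fits <- lapply(cohort, per_patient_fit, n_starts = n_starts,
                 fix = if (fix_nonvarying) spec$fixed_values)
  est <- t(vapply(fits, `[[`, numeric(6), "estimate"))
  beta0 <- apply(est[, spec$varying, drop = FALSE], 2, stats::median)
  Psi0 <- stats::cov(est[, spec$varying, drop = FALSE])
  jittered <- FALSE
  ev <- eigen(Psi0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < 1e-10) {
    Psi0 <- Psi0 + diag(1e-6, nrow(Psi0))
    jittered <- TRUE
  }
  ss <- sum(vapply(fits, `[[`, 0, "value"))
  nn <- sum(vapply(fits, `[[`, 0, "n_obs"))
  pr <- prior_config(beta0 = beta0, s0_squared = ss / nn, Psi0 = Psi0)
  pr$estimates <- est
  pr$jittered <- jittered
  pr
}

# ---- conjugate Gibbs draws (exposed so their moments can be checked against
# the closed-form conditionals) ----

#' Conjugate draw of the fixed effects given effective parameters
#'
#' With a flat prior on `beta`, the conditional is normal with mean the
#' average of the `beta_i` and covariance `Psi / N`.
#'
#' @param effective Patients x varying matrix.
#' @param psi Current random-effects covariance.
#' @return Drawn fixed-effects vector.
#' @export
draw_beta_conditional <- function(effective, psi) {
  N <- nrow(effective)
  MASS::mvrnorm(1, mu = colMeans(effective), Sigma = as.matrix(psi) / N)
}

#' Conjugate inverse-Wishart draw of the random-effects covariance
#'
#' Conditional: `Inv-Wishart(S0 + S, rho0 + N)` with
#' `S = sum_i (beta_i - beta)(beta_i - beta)'` and `S0` the prior scale
#' matrix (the sampler passes `S0 = (rho0 - p - 1) * Psi0`, centering the
#' prior mean at `Psi0`).
#'
#' @param effective Patients x varying matrix.
#' @param beta Current fixed effects.
#' @param scale0 Prior scale matrix `S0`.
#' @param rho0 Prior degrees of freedom.
#' @return Drawn covariance matrix.
#' @export
draw_psi_conditional <- function(effective, beta, scale0, rho0) {
  dev <- sweep(as.matrix(effective), 2, beta)
  scale <- as.matrix(scale0) + crossprod(dev)
  df <- rho0 + nrow(dev)
  W <- stats::rWishart(1, df, solve(scale))[, , 1]
  solve(W)
}

#' Conjugate inverse-gamma draw of the error variance
#'
#' Conditional: `Inv-Gamma(shape = (n0 + n_obs) / 2,
#' scale = (n0 s0_squared + SS) / 2)` where `SS` is the current total squared
#' residual sum over all patients and observed days.
#'
#' @param ss Total residual sum of squares.
#' @param n_obs Total number of observed residual terms.
#' @param s0_squared,n0 Prior scale and weight.
#' @return Drawn variance.
#' @export
draw_sigma2_conditional <- function(ss, n_obs, s0_squared, n0 = 1) {
  1 / stats::rgamma(1, shape = (n0 + n_obs) / 2,
                    rate = (n0 * s0_squared + ss) / 2)
}

#' Fit the mixed-effects model by DRAM Metropolis-within-Gibbs
#'
#' One sweep per iteration: (a) each patient's effective-parameter block is
#' updated by a delayed-rejection adaptive Metropolis step targeting the
#' patient's likelihood kernel times the random-effects prior; (b) `beta` by
#' its conjugate normal draw; (c) `Psi` by inverse-Wishart; (d) `sigma2` by
#' inverse-gamma. Proposal covariances adapt per patient every
#' `adapt_interval` iterations to `2.38^2 / d` times the empirical covariance
#' of that patient's chain; on a first rejection one delayed-rejection stage
#' retries with the proposal scaled down by `dr_shrink`. Disabling both
#' (`adapt = FALSE`, `delayed_rejection = FALSE`) reduces the block update to
#' plain Metropolis-Hastings.
#'
#' @param cohort List of `patient_series`.
#' @param spec A [mixed_effects_spec()].
#' @param priors A [prior_config()], typically from
#'   [initial_frequentist_fit()].
#' @param n_iter Number of sweeps.
#' @param seed Optional integer seed (identical seed, identical chain).
#' @param burn_in Fraction of sweeps discarded (default 0.5).
#' @param thin Keep every `thin`-th post-burn-in sweep.
#' @param adapt Enable proposal-covariance adaptation.
#' @param adapt_interval Sweeps between adaptations (default 100).
#' @param delayed_rejection Enable the delayed-rejection stage.
#' @param dr_shrink Scale factor of the second-stage proposal (default 1/5).
#' @param update_beta,update_psi,update_sigma2 Toggle the conjugate blocks
#'   (frozen values are held at their initial state; used for block-level
#'   testing).
#' @param init Optional initial [mixed_effects_state()]; default builds one
#'   from the priors (all patients at `beta0`).
#' @param clip_nonneg Simulate with clipping inside the likelihood.
#' @return Object of class `cravedyn_chain`: post-burn-in samples of
#'   `beta` (matrix), `sigma2` (vector), `psi` (array), `effective` (array
#'   kept x patients x varying), acceptance rates, seed and configuration.
#' @export
fit_mixed_effects <- function(cohort, spec = mixed_effects_spec(), priors,
                              n_iter = 5000, seed = NULL, burn_in = 0.5,
                              thin = 1, adapt = TRUE, adapt_interval = 100,
                              delayed_rejection = TRUE, dr_shrink = 0.2,
                              update_beta = TRUE, update_psi = TRUE,
                              update_sigma2 = TRUE, init = NULL,
                              clip_nonneg = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  m <- length(spec$varying)
  N <- length(cohort)
  obs <- lapply(cohort, .patient_obs)
  n_obs_tot <- sum(vapply(obs, `[[`, 0, "n_obs"))
  nonneg_idx <- which(spec$varying %in% c("a1", "a2", "d1", "d2"))

  if (is.null(init)) {
    init <- mixed_effects_state(
      beta = priors$beta0,
      effective = if (!is.null(priors$estimates))
        priors$estimates[, spec$varying, drop = FALSE]
      else matrix(rep(priors$beta0, each = N), nrow = N,
                  dimnames = list(NULL, spec$varying)),
      sigma2 = priors$s0_squared, psi = priors$Psi0)
  }
  beta <- init$beta
  eff <- init$effective
  sigma2 <- init$sigma2
  psi <- init$psi

  ss_fun <- function(theta_v, ob) {
    p <- .full_params(theta_v, spec)
    traj_ss(unname(p), ob$A0, ob$A1, ob$D1, ob$obsA, ob$obsD, clip_nonneg)
  }
  ss_i <- vapply(seq_len(N), function(i) ss_fun(eff[i, ], obs[[i]]), 0)

  # per-patient proposal state: cholesky of the proposal covariance plus
  # Welford running moments for adaptation. The initial covariance is the
  # Gauss-Newton approximation sigma2 * (J'J)^-1 of each patient's
  # conditional posterior at its starting point (the per-patient conditional
  # is orders of magnitude tighter than the population spread, so seeding
  # from Psi0 would stall the chain until adaptation caught up).
  sd_opt <- 2.38^2 / m
  gn_cov <- function(theta_v, ob) {
    h_len <- length(ob$obsA)
    J <- matrix(0, 2 * h_len, m)
    for (k in seq_len(m)) {
      h <- max(1e-4, 1e-3 * abs(theta_v[k]))
      up <- theta_v; up[k] <- up[k] + h
      dn <- theta_v; dn[k] <- dn[k] - h
      pu <- .full_params(up, spec); pd <- .full_params(dn, spec)
      tu <- sim_core(unname(pu), ob$A0, ob$A1, ob$D1, h_len, clip_nonneg)
      td <- sim_core(unname(pd), ob$A0, ob$A1, ob$D1, h_len, clip_nonneg)
      J[, k] <- c(tu[, 1] - td[, 1], tu[, 2] - td[, 2]) / (2 * h)
    }
    J <- J[c(!is.na(ob$obsA), !is.na(ob$obsD)), , drop = FALSE]
    # conditional-posterior covariance: likelihood information plus the
    # random-effects prior precision (bounds the proposal above by Psi even
    # when J'J is near-singular along the collinearity ridge)
    prior_prec <- tryCatch(solve(as.matrix(priors$Psi0) + diag(1e-10, m)),
                           error = function(e) diag(1e4, m))
    G <- crossprod(J) / sigma2 + prior_prec
    V <- tryCatch(solve(G), error = function(e) NULL)
    if (is.null(V) || any(!is.finite(V))) diag(1e-4, m)
    else (V + t(V)) / 2
  }
  prop_R <- vector("list", N)
  gn_base <- vector("list", N)           # Gauss-Newton covariances
  for (i in seq_len(N)) {
    gn_base[[i]] <- gn_cov(eff[i, ], obs[[i]])
    prop_R[[i]] <- tryCatch(chol(sd_opt * gn_base[[i]]),
                            error = function(e) {
                              gn_base[[i]] <<- diag(1e-4, m)
                              chol(sd_opt * diag(1e-4, m))
                            })
  }
  w_n <- integer(N)
  w_mu <- matrix(0, N, m)
  w_M2 <- array(0, c(N, m, m))
  log_scale <- numeric(N)                # per-patient proposal log-scale
  win_acc <- integer(N)                  # acceptances in current window
  acc_target <- 0.234

  psi_scale0 <- (priors$rho0 - m - 1) * as.matrix(priors$Psi0)
  psi_R <- chol(psi)
  quad <- function(th) {
    z <- forwardsolve(t(psi_R), th - beta)
    0.5 * sum(z^2)
  }
  n_keep <- floor((n_iter - floor(n_iter * burn_in)) / thin)
  keep_beta <- matrix(NA_real_, n_keep, m, dimnames = list(NULL, spec$varying))
  keep_sigma2 <- numeric(n_keep)
  keep_psi <- array(NA_real_, c(m, m, n_keep))
  keep_eff <- array(NA_real_, c(n_keep, N, m))
  acc1 <- integer(N)
  acc2 <- integer(N)
  n_dr <- integer(N)
  kept <- 0L
  burn <- floor(n_iter * burn_in)

  for (it in seq_len(n_iter)) {
    inv2s <- 1 / (2 * sigma2)
    for (i in seq_len(N)) {
      x <- eff[i, ]
      lp_x <- -ss_i[i] * inv2s - quad(x)
      R <- prop_R[[i]]
      y1 <- x + drop(stats::rnorm(m) %*% R)
      ok1 <- all(y1[nonneg_idx] >= 0)
      if (ok1) {
        ss_y1 <- ss_fun(y1, obs[[i]])
        lp_y1 <- -ss_y1 * inv2s - quad(y1)
      } else lp_y1 <- -Inf
      la1 <- min(0, lp_y1 - lp_x)
      if (is.nan(la1)) la1 <- -Inf
      if (is.finite(lp_y1) && log(stats::runif(1)) < la1) {
        eff[i, ] <- y1
        ss_i[i] <- ss_y1
        acc1[i] <- acc1[i] + 1L
        win_acc[i] <- win_acc[i] + 1L
      } else if (delayed_rejection) {
        n_dr[i] <- n_dr[i] + 1L
        y2 <- x + dr_shrink * drop(stats::rnorm(m) %*% R)
        ok2 <- all(y2[nonneg_idx] >= 0)
        if (ok2) {
          ss_y2 <- ss_fun(y2, obs[[i]])
          lp_y2 <- -ss_y2 * inv2s - quad(y2)
          if (is.finite(lp_y2)) {
            # stage-2 acceptance: density ratio times the ratio of stage-1
            # proposal densities to y1 and of the stage-1 rejection odds
            q1 <- function(a, b) { # log N(b; a, R'R) up to constant
              z <- forwardsolve(t(R), b - a)
              -0.5 * sum(z^2)
            }
            la1_rev <- min(0, if (is.finite(lp_y1)) lp_y1 - lp_y2 else -Inf)
            num <- lp_y2 + q1(y2, y1) + log1mexp(la1_rev)
            den <- lp_x + q1(x, y1) + log1mexp(la1)
            if (is.finite(num - den) && log(stats::runif(1)) < num - den) {
              eff[i, ] <- y2
              ss_i[i] <- ss_y2
              acc2[i] <- acc2[i] + 1L
              win_acc[i] <- win_acc[i] + 1L
            }
          }
        }
      }
      # adaptation bookkeeping (Welford update with the post-update value)
      if (adapt) {
        w_n[i] <- w_n[i] + 1L
        delta <- eff[i, ] - w_mu[i, ]
        w_mu[i, ] <- w_mu[i, ] + delta / w_n[i]
        w_M2[i, , ] <- w_M2[i, , ] + tcrossprod(delta, eff[i, ] - w_mu[i, ])
        if (it %% adapt_interval == 0) {
          # acceptance-targeted scale correction (keeps anisotropic or
          # strongly curved patient posteriors from stalling the chain)
          rate <- win_acc[i] / adapt_interval
          log_scale[i] <- max(-10, min(4, log_scale[i] + (rate - acc_target)))
          win_acc[i] <- 0L
          C <- if (w_n[i] > 4 * m) {
            Ce <- matrix(w_M2[i, , ], m, m) / (w_n[i] - 1)
            (Ce + t(Ce)) / 2 + 1e-6 * gn_base[[i]] + diag(1e-12, m)
          } else gn_base[[i]]
          prop_R[[i]] <- tryCatch(
            chol(exp(log_scale[i]) * sd_opt * C),
            error = function(e) prop_R[[i]])
        }
      }
    }
    if (update_beta) beta <- draw_beta_conditional(eff, psi)
    if (update_psi) {
      psi <- draw_psi_conditional(eff, beta, psi_scale0, priors$rho0)
      psi_R <- chol(psi)
    }
    if (update_sigma2)
      sigma2 <- draw_sigma2_conditional(sum(ss_i), n_obs_tot,
                                        priors$s0_squared, priors$n0)
    if (it > burn && (it - burn) %% thin == 0 && kept < n_keep) {
      kept <- kept + 1L
      keep_beta[kept, ] <- beta
      keep_sigma2[kept] <- sigma2
      keep_psi[, , kept] <- psi
      keep_eff[kept, , ] <- eff
    }
  }
  structure(list(
    beta = keep_beta[seq_len(kept), , drop = FALSE],
    sigma2 = keep_sigma2[seq_len(kept)],
    psi = keep_psi[, , seq_len(kept), drop = FALSE],
    effective = keep_eff[seq_len(kept), , , drop = FALSE],
    accept = list(stage1 = acc1 / n_iter,
                  dr = ifelse(n_dr > 0, acc2 / pmax(n_dr, 1), 0),
                  overall = (acc1 + acc2) / n_iter),
    n_iter = n_iter, burn_in = burn_in, thin = thin, seed = seed,
    spec = spec, priors = priors[c("beta0", "s0_squared", "n0", "rho0")],
    patient_ids = vapply(cohort, `[[`, "", "patient_id")),
    class = "cravedyn_chain")
}

# numerically stable log(1 - exp(x)) for x <= 0
log1mexp <- function(x) {
  if (x >= 0) return(-Inf)
  if (x > -log(2)) log(-expm1(x)) else log1p(-exp(x))
}

#' Posterior summary tables
#'
#' Population value = posterior mean of the fixed effects; individual-level
#' spread statistics (min, max, mean, median, sd) are computed over the
#' per-patient posterior means of the effective parameters. Fixed
#' coefficients are echoed with zero spread.
#'
#' @param chain A `cravedyn_chain`.
#' @return List with `population` (data frame mirroring the reference layout)
#'   and `effective_means` (patients x varying matrix).
#' @export
summarize_posterior <- function(chain) {
  if (nrow(chain$beta) == 0) stop("empty chain", call. = FALSE)
  spec <- chain$spec
  beta_hat <- colMeans(chain$beta)
  eff_mean <- apply(chain$effective, c(2, 3), mean)
  colnames(eff_mean) <- spec$varying
  rownames(eff_mean) <- chain$patient_ids
  all6 <- c("a1", "a2", "a3", "d1", "d2", "d3")
  pop <- data.frame(parameter = all6, value = NA_real_, min = NA_real_,
                    max = NA_real_, mean = NA_real_, median = NA_real_,
                    sd = NA_real_, fixed = all6 %in% names(spec$fixed_values))
  for (k in all6) {
    r <- pop$parameter == k
    if (k %in% names(spec$fixed_values)) {
      v <- spec$fixed_values[[k]]
      pop[r, c("value", "min", "max", "mean", "median")] <- v
      pop[r, "sd"] <- 0
    } else {
      e <- eff_mean[, k]
      pop[r, "value"] <- beta_hat[[k]]
      pop[r, c("min", "max", "mean", "median", "sd")] <-
        c(min(e), max(e), mean(e), stats::median(e), stats::sd(e))
    }
  }
  list(population = pop, effective_means = eff_mean,
       sigma2 = mean(chain$sigma2))
}

#' Convergence diagnostics for a chain
#'
#' Geweke z-scores (first 10% vs last 50%, spectral variance estimates) and
#' effective sample sizes for each fixed-effect scalar and the error
#' variance, plus the per-patient acceptance rates. `|z| > 2` is flagged.
#' A constant scalar gets `NA` diagnostics and a flag.
#'
#' @param chain A `cravedyn_chain` with at least 200 kept samples.
#' @return Data frame with columns `scalar, geweke_z, ess, flagged`, plus
#'   attribute `acceptance`.
#' @export
convergence_diagnostics <- function(chain) {
  draws <- cbind(chain$beta, sigma2 = chain$sigma2)
  if (nrow(draws) < 200)
    stop("need at least 200 kept samples for diagnostics", call. = FALSE)
  out <- data.frame(scalar = colnames(draws), geweke_z = NA_real_,
                    ess = NA_real_, flagged = FALSE)
  for (j in seq_len(ncol(draws))) {
    v <- draws[, j]
    if (stats::var(v) == 0) {
      out$flagged[j] <- TRUE
      next
    }
    z <- tryCatch(coda::geweke.diag(coda::mcmc(v),
                                    frac1 = 0.1, frac2 = 0.5)$z,
                  error = function(e) NA_real_)
    out$geweke_z[j] <- unname(z)
    out$ess[j] <- unname(coda::effectiveSize(coda::mcmc(v)))
    out$flagged[j] <- is.na(z) || abs(z) > 2
  }
  attr(out, "acceptance") <- chain$accept
  out
}

#' Write chain samples and metadata
#'
#' Samples to CSV (one row per kept sweep: fixed effects and error variance)
#' and metadata (seed, configuration, acceptance rates) to JSON.
#'
#' @param chain A `cravedyn_chain`.
#' @param csv_path,json_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_chain <- function(chain, csv_path, json_path) {
  utils::write.csv(cbind(as.data.frame(chain$beta), sigma2 = chain$sigma2),
                   csv_path, row.names = FALSE)
  jsonlite::write_json(list(seed = chain$seed, n_iter = chain$n_iter,
                            burn_in = chain$burn_in, thin = chain$thin,
                            acceptance = chain$accept, priors = chain$priors),
                       json_path, digits = NA, auto_unbox = TRUE)
  invisible(c(csv_path, json_path))
}
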