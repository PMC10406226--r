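test_that("parameter counting follows the mixed-effects bookkeeping", {
  expect_equal(as.integer(count_parameters(1, 1)), 4L)
  cmp <- attr(count_parameters(3, 10), "components")
  expect_equal(unname(cmp), c(3, 30, 1, 6))
  expect_error(count_parameters(0, 5), "positive")
})

test_that("the likelihood kernel is the scaled residual sum over observed days", {
  # zero residuals: log kernel exactly 0
  sp <- cohort_spec(n_patients = 3, sigma2 = 0, missingness = 0, seed = 7)
  co <- generate_cohort(sp)
  gt <- attr(co, "ground_truth")
  spec <- mixed_effects_spec()
  st <- mixed_effects_state(beta = population_params()[varying4],
                            effective = gt$beta_i[, varying4],
                            sigma2 = 2, psi = psi_fixture())
  expect_equal(log_likelihood(co, st, spec), 0)

  # a single observed post-baseline day contributes -r^2 / (2 sigma2)
  p <- population_params()
  tr <- simulate_trajectory(p, median_ics, 84)
  r <- 1.7
  drinks <- c(tr$A[1], tr$A[2] + r)
  s <- series_from(c(1, 2), drinks, c(tr$D[1], NA), tlfb = 8.4)
  st1 <- mixed_effects_state(beta = p[varying4],
                             effective = matrix(p[varying4], 1,
                                                dimnames = list(NULL, varying4)),
                             sigma2 = 0.5, psi = psi_fixture())
  expect_equal(log_likelihood(list(s), st1, spec), -r^2 / (2 * 0.5),
               tolerance = 1e-10)

  # masking one day removes exactly its squared residual
  co2 <- small_cohort(n = 2, sigma2 = 0.25, missingness = 0, seed = 9)
  gt2 <- attr(co2, "ground_truth")
  st2 <- mixed_effects_state(beta = population_params()[varying4],
                             effective = gt2$beta_i[, varying4],
                             sigma2 = 0.3, psi = psi_fixture())
  ll_full <- log_likelihood(co2, st2, spec)
  day <- 40
  r_day <- co2[[1]]$records$drinks[day] - gt2$trajectories[[1]]$A[day]
  co2[[1]]$records$drinks[day] <- NA
  ll_masked <- log_likelihood(co2, st2, spec)
  expect_equal(ll_masked - ll_full, r_day^2 / (2 * 0.3), tolerance = 1e-10)
})

test_that("the random-effects prior kernel is the Mahalanobis sum", {
  b <- c(a2 = 1, a3 = 0, d2 = 0.4, d3 = 0)
  eff <- matrix(rep(b, 3), 3, byrow = TRUE, dimnames = list(NULL, names(b)))
  st <- mixed_effects_state(b, eff, sigma2 = 1, psi = diag(4))
  expect_equal(log_prior_effective(st), 0)

  eff[1, ] <- b + c(1, 0, 0, 0)
  st <- mixed_effects_state(b, eff, sigma2 = 1, psi = diag(4))
  expect_equal(log_prior_effective(st), -0.5)

  # invariance under joint translation
  shift <- c(0.1, -0.2, 0.05, 0.3)
  st2 <- mixed_effects_state(b + shift, sweep(eff, 2, -shift), sigma2 = 1,
                             psi = diag(4))
  expect_equal(log_prior_effective(st2), log_prior_effective(st))
})

test_that("per-patient least squares recovers noiseless generating parameters", {
  sp <- cohort_spec(n_patients = 2, sigma2 = 0, missingness = 0, seed = 19)
  co <- generate_cohort(sp)
  gt <- attr(co, "ground_truth")
  f <- per_patient_fit(co[[1]])
  expect_equal(unname(f$estimate), unname(gt$beta_i[1, ]), tolerance = 1e-3)
  expect_lt(f$value, 1e-10)
  expect_true(f$converged)

  # profile fit holds the fixed coefficients and matches the varying truth
  fx <- mixed_effects_spec()$fixed_values
  fp <- per_patient_fit(co[[1]], fix = fx)
  expect_equal(fp$estimate[names(fx)], fx)
  expect_equal(unname(fp$estimate[varying4]), unname(gt$beta_i[1, varying4]),
               tolerance = 1e-3)

  # with noise, the residual-variance estimate tracks the generating sigma2
  spn <- cohort_spec(n_patients = 3, sigma2 = 0.25, missingness = 0, seed = 23)
  con <- generate_cohort(spn)
  s2 <- vapply(con, function(s) per_patient_fit(s, fix = fx)$sigma2_hat, 0)
  expect_equal(mean(s2), 0.25, tolerance = 0.35)
})

test_that("the frequentist two-stage seed reflects the cohort", {
  co <- small_cohort(n = 6, sigma2 = 0.25, seed = 29)
  gt <- attr(co, "ground_truth")
  pr <- initial_frequentist_fit(co)
  expect_s3_class(pr, "prior_config")
  # medians over six patients land near the cohort's own medians
  expect_equal(unname(pr$beta0),
               unname(apply(gt$beta_i[, varying4], 2, median)),
               tolerance = 0.25)
  expect_equal(pr$s0_squared, 0.25, tolerance = 0.2)
  expect_false(pr$jittered)

  # identical patients: singular covariance is jittered and flagged
  co2 <- co[c(1, 1, 1)]
  names(co2) <- c("A", "B", "C")
  pr2 <- initial_frequentist_fit(co2)
  expect_true(pr2$jittered)
  expect_gt(min(eigen(pr2$Psi0)$values), 0)
  expect_error(initial_frequentist_fit(co[1]), "at least 2")
})

test_that("DRAM on a linear-in-parameter model matches the conjugate posterior", {
  # with only d1 varying and every alcohol coefficient zero, the desire
  # trajectory is affine in d1: f = c + d1 * g with g_n = A1 * d2^(n-2).
  # Gaussian likelihood x Gaussian prior then has a closed-form posterior.
  spec1 <- mixed_effects_spec(varying = "d1",
                              fixed_values = c(a1 = 0, a2 = 0, a3 = 0,
                                               d2 = 0.5, d3 = 0))
  h <- 30; A1 <- 5; D1 <- 6; sig2 <- 0.25; psi1 <- 0.04
  d1_true <- 0.8
  set.seed(61)
  p_true <- c(a1 = 0, a2 = 0, a3 = 0, d1 = d1_true, d2 = 0.5, d3 = 0)
  tr <- simulate_trajectory(p_true, c(A0 = 5, A1 = A1, D1 = D1), h)
  obsD <- tr$D + c(0, rnorm(h - 1, 0, sqrt(sig2)))
  s <- series_from(1:h, c(tr$A[1], rep(NA, h - 1)), obsD, tlfb = 5,
                   n_days = h)
  # closed form: design over observed days 2..h
  p0 <- p_true; p0[["d1"]] <- 0
  c0 <- simulate_trajectory(p0, c(A0 = 5, A1 = A1, D1 = D1), h)$D
  g <- (tr$D - c0) / d1_true
  prior_mean <- 0.7
  prec <- sum(g[-1]^2) / sig2 + 1 / psi1
  post_mean <- (sum(g[-1] * (obsD[-1] - c0[-1])) / sig2 + prior_mean / psi1) /
    prec
  post_sd <- sqrt(1 / prec)

  pr <- prior_config(beta0 = c(d1 = prior_mean), s0_squared = sig2,
                     Psi0 = matrix(psi1, 1, 1), rho0 = 100)
  init <- mixed_effects_state(beta = c(d1 = prior_mean),
                              effective = matrix(prior_mean, 1,
                                                 dimnames = list(NULL, "d1")),
                              sigma2 = sig2, psi = matrix(psi1, 1, 1))
  ch <- fit_mixed_effects(list(s), spec1, pr, n_iter = 6000, seed = 62,
                          update_beta = FALSE, update_psi = FALSE,
                          update_sigma2 = FALSE, init = init)
  draws <- ch$effective[, 1, 1]
  expect_equal(mean(draws), post_mean, tolerance = 4 * post_sd / sqrt(200))
  expect_equal(sd(draws), post_sd, tolerance = 0.2 * post_sd)
})

test_that("chains are reproducible under a fixed seed and run in plain-MH mode", {
  co <- small_cohort(n = 3, sigma2 = 0.25, seed = 71, horizon = 42)
  pr <- initial_frequentist_fit(co)
  ch1 <- fit_mixed_effects(co, priors = pr, n_iter = 300, seed = 72)
  ch2 <- fit_mixed_effects(co, priors = pr, n_iter = 300, seed = 72)
  expect_identical(ch1$beta, ch2$beta)
  expect_identical(ch1$sigma2, ch2$sigma2)
  expect_identical(ch1$effective, ch2$effective)

  # with adaptation and delayed rejection off the sweep is plain MH and
  # still produces a valid chain
  ch3 <- fit_mixed_effects(co, priors = pr, n_iter = 300, seed = 73,
                           adapt = FALSE, delayed_rejection = FALSE)
  expect_true(all(is.finite(ch3$beta)))
  expect_true(all(ch3$accept$dr == 0))
  expect_true(all(ch3$accept$stage1 >= 0 & ch3$accept$stage1 <= 1))
})

test_that("posterior summaries mirror the reference table layout", {
  co <- small_cohort(n = 3, sigma2 = 0.25, seed = 81, horizon = 42)
  pr <- initial_frequentist_fit(co)
  ch <- fit_mixed_effects(co, priors = pr, n_iter = 400, seed = 82)
  s <- summarize_posterior(ch)
  pop_tab <- s$population
  expect_equal(pop_tab$parameter, c("a1", "a2", "a3", "d1", "d2", "d3"))
  # fixed coefficients echoed with zero spread
  expect_equal(pop_tab$value[pop_tab$parameter == "a1"], 0.2829)
  expect_equal(pop_tab$sd[pop_tab$parameter %in% c("a1", "d1")], c(0, 0))
  # population value is the posterior mean of the fixed effects
  expect_equal(pop_tab$value[pop_tab$parameter == "a2"],
               mean(ch$beta[, "a2"]))
  # spread statistics are over per-patient posterior means
  em <- s$effective_means
  expect_equal(pop_tab$min[pop_tab$parameter == "d2"], min(em[, "d2"]))
  expect_equal(dim(em), c(3L, 4L))
})

test_that("convergence diagnostics flag trends and constants, pass white noise", {
  mk_chain <- function(draws) {
    structure(list(beta = draws, sigma2 = rexp(nrow(draws)) + 1,
                   psi = array(1, c(1, 1, nrow(draws))),
                   effective = array(0, c(nrow(draws), 1, 1)),
                   accept = list(stage1 = 0.3, dr = 0.1, overall = 0.35),
                   spec = mixed_effects_spec(), patient_ids = "P1"),
              class = "cravedyn_chain")
  }
  set.seed(91)
  white <- matrix(rnorm(1000), ncol = 1, dimnames = list(NULL, "a2"))
  d <- convergence_diagnostics(mk_chain(white))
  expect_lt(abs(d$geweke_z[d$scalar == "a2"]), 3)
  expect_gt(d$ess[d$scalar == "a2"], 400)

  trend <- matrix(seq(0, 5, length.out = 1000) + rnorm(1000, 0, 0.1),
                  ncol = 1, dimnames = list(NULL, "a2"))
  d <- convergence_diagnostics(mk_chain(trend))
  expect_true(d$flagged[d$scalar == "a2"])

  const <- matrix(1, 500, 1, dimnames = list(NULL, "a2"))
  d <- convergence_diagnostics(mk_chain(const))
  expect_true(d$flagged[d$scalar == "a2"])
  expect_error(convergence_diagnostics(mk_chain(white[1:50, , drop = FALSE])),
               "200")
})
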