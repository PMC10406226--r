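# Shared fixtures: small synthetic cohorts and hand-rolled series built in
# code at test time.

pop <- population_params()
median_ics <- initial_conditions(A0 = 8.4, A1 = 4, D1 = 7)
varying4 <- c("a2", "a3", "d2", "d3")

# direct two-line oracle for one day of the coupled system (independent of
# the package's step/simulate path)
oracle_step <- function(p, A_prev, A_prev2, D_prev) {
  D_n <- p[["d1"]] * A_prev + p[["d2"]] * D_prev + p[["d3"]] * (A_prev - A_prev2)
  A_n <- p[["a1"]] * (D_n - D_prev) + p[["a2"]] * A_prev + p[["a3"]] * (A_prev - A_prev2)
  c(A = A_n, D = D_n)
}

# oracle trajectory by iterating the two-line update in plain R; with
# clipping on, tonight's desire is floored before it enters the same-day
# alcohol update (trajectory entries are max(0, raw value))
oracle_traj <- function(p, ics, horizon, clip = FALSE) {
  A <- numeric(horizon); D <- numeric(horizon)
  A[1] <- ics[["A1"]]; D[1] <- ics[["D1"]]
  Ap2 <- ics[["A0"]]
  for (n in 2:horizon) {
    D_n <- p[["d1"]] * A[n - 1] + p[["d2"]] * D[n - 1] +
      p[["d3"]] * (A[n - 1] - Ap2)
    if (clip) D_n <- max(0, D_n)
    A_n <- p[["a1"]] * (D_n - D[n - 1]) + p[["a2"]] * A[n - 1] +
      p[["a3"]] * (A[n - 1] - Ap2)
    if (clip) A_n <- max(0, A_n)
    Ap2 <- A[n - 1]
    A[n] <- A_n; D[n] <- D_n
  }
  data.frame(day = seq_len(horizon), A = A, D = D)
}

# small calibration-ready cohort (noise consistent with the likelihood)
small_cohort <- function(n = 4, sigma2 = 0.25, missingness = 0.2, seed = 42,
                         horizon = 84) {
  generate_cohort(cohort_spec(n_patients = n, horizon = horizon,
                              sigma2 = sigma2, missingness = missingness,
                              seed = seed))
}

# one patient_series built directly from vectors (NA-padded to n_days)
series_from <- function(day, drinks, desire, tlfb = 8, n_days = 84,
                        id = "P1") {
  patient_series(id, day, drinks, desire, tlfb_baseline = tlfb,
                 n_days = n_days)
}
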