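#' Reference population-level parameter estimates
#'
#' Packaged reference values from the population-level mixed-effects
#' calibration of a 37-patient moderation-goal AUD daily-diary cohort. The
#' coefficients `a1` and `d1` were fixed prior to that calibration (medians of
#' preliminary per-patient fits); the remaining four were estimated with
#' patient-level random effects. These values serve as defaults for the
#' synthetic-cohort generator and as the baseline point for sensitivity
#' analysis; they are fixtures, not quantities this package re-estimates.
#'
#' @return Named numeric vector with elements `a1, a2, a3, d1, d2, d3`.
#' @seealso [param_spread()], [ic_stats()], [subject_params()]
#' @export
population_params <- function() {
  c(a1 = 0.2829, a2 = 0.9944, a3 = -0.4539,
    d1 = 0.8144, d2 = 0.4110, d3 = -0.0561)
}

#' Individual-level spread of the effective parameters
#'
#' Reference summary statistics (min, max, mean, median, sd) of the per-patient
#' effective parameters from the same calibration as [population_params()].
#' The fixed coefficients `a1` and `d1` have zero spread by construction.
#'
#' @return Data frame with one row per parameter and columns
#'   `parameter, min, max, mean, median, sd`.
#' @export
param_spread <- function() {
  data.frame(
    parameter = c("a1", "a2", "a3", "d1", "d2", "d3"),
    min    = c(0.2829,  0.9688, -1.1274, 0.8144, 0.0069, -0.7469),
    max    = c(0.2829,  1.0052,  0.3316, 0.8144, 0.7530,  0.7719),
    mean   = c(0.2829,  0.9944, -0.4541, 0.8144, 0.4111, -0.0561),
    median = c(0.2829,  0.9988, -0.4974, 0.8144, 0.4552, -0.1165),
    sd     = c(0,       0.0088,  0.4475, 0,      0.2168,  0.3426),
    stringsAsFactors = FALSE
  )
}

#' Initial-condition summary statistics across the reference cohort
#'
#' Distributional summaries of the three initial conditions across the
#' 37 reference patients: `A0` (baseline average drinks/day from a 30-day
#' Timeline Followback), `A1` (drinks on the first diary day), and `D1`
#' (desire composite on the first diary day).
#'
#' @return Data frame with columns `condition, min, max, mean, median, sd`.
#' @export
ic_stats <- function() {
  data.frame(
    condition = c("A0", "A1", "D1"),
    min    = c(3.5,     0,      0),
    max    = c(32,      16,     12),
    mean   = c(9.4622,  4.7297, 6.2162),
    median = c(8.4,     4,      7),
    sd     = c(5.9181,  4.0665, 3.5444),
    stringsAsFactors = FALSE
  )
}

#' Reference per-patient parameter sets for three sample subjects
#'
#' Effective parameter estimates for three illustrative subjects of the
#' reference cohort (ids "1274", "1677", "1848"), alongside the population
#' set (`id = "population"`).
#'
#' @param id One of `"population"`, `"1274"`, `"1677"`, `"1848"`.
#' @return Named numeric vector as in [population_params()].
#' @export
subject_params <- function(id = "population") {
  id <- as.character(id)
  tabs <- list(
    population = population_params(),
    `1274` = c(a1 = 0.2829, a2 = 0.9989, a3 = -0.1489,
               d1 = 0.8144, d2 = 0.5095, d3 = -0.1173),
    `1677` = c(a1 = 0.2829, a2 = 1.0013, a3 = -0.0484,
               d1 = 0.8144, d2 = 0.7055, d3 = -0.4816),
    `1848` = c(a1 = 0.2829, a2 = 0.9994, a3 = -0.9963,
               d1 = 0.8144, d2 = 0.3024, d3 = 0.4477)
  )
  if (!id %in% names(tabs))
    stop("unknown subject id: ", id, call. = FALSE)
  tabs[[id]]
}

#' Default random-effects covariance fixture
#'
#' Diagonal covariance over the varying parameter subset `{a2, a3, d2, d3}`,
#' with standard deviations taken from the individual-level spread of the
#' reference calibration ([param_spread()]). Off-diagonal covariances were
#' estimated in that calibration but not reported, so the fixture is diagonal.
#'
#' @param varying Character vector of varying parameter names.
#' @return Symmetric positive-definite matrix with dimnames `varying`.
#' @export
psi_fixture <- function(varying = c("a2", "a3", "d2", "d3")) {
  sp <- param_spread()
  sds <- sp$sd[match(varying, sp$parameter)]
  if (anyNA(sds)) stop("unknown parameter in 'varying'", call. = FALSE)
  psi <- diag(sds^2, nrow = length(varying))
  dimnames(psi) <- list(varying, varying)
  psi
}
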