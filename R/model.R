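#' Construct and validate a model parameter vector
#'
#' The dual-process model couples nightly alcohol consumption `A_n` and desire
#' to drink `D_n` through a pair of delayed difference equations:
#' \deqn{D_n = d_1 A_{n-1} + d_2 D_{n-1} + d_3 (A_{n-1} - A_{n-2})}
#' \deqn{A_n = a_1 (D_n - D_{n-1}) + a_2 A_{n-1} + a_3 (A_{n-1} - A_{n-2})}
#' `a1, a2, d1, d2` are nonnegative rate coefficients; `a3` and `d3` may take
#' either sign (a recent run-up in drinking can either sustain or suppress
#' tonight's drinking and desire).
#'
#' @param a1 Drinks tonight per unit change in desire over the past day.
#' @param a2 Drinks tonight per drink last night.
#' @param a3 Drinks tonight per unit change in drinks over two nights (any sign).
#' @param d1 Desire units tonight per drink last night.
#' @param d2 Desire units tonight per desire unit last night.
#' @param d3 Desire units tonight per unit change in drinks over two nights.
#' @return Named numeric vector of length 6.
#' @export
model_params <- function(a1, a2, a3, d1, d2, d3) {
  p <- c(a1 = a1, a2 = a2, a3 = a3, d1 = d1, d2 = d2, d3 = d3)
  if (!all(is.finite(p))) stop("model parameters must be finite", call. = FALSE)
  if (any(p[c("a1", "a2", "d1", "d2")] < 0))
    stop("a1, a2, d1, d2 must be nonnegative", call. = FALSE)
  p
}

.as_params <- function(p) {
  nm <- c("a1", "a2", "a3", "d1", "d2", "d3")
  if (is.null(names(p))) {
    if (length(p) != 6) stop("expected 6 parameters", call. = FALSE)
    names(p) <- nm
  }
  if (!all(nm %in% names(p))) stop("missing parameter names", call. = FALSE)
  p <- p[nm]
  if (!all(is.finite(p))) stop("model parameters must be finite", call. = FALSE)
  p
}

#' Initial conditions for a trajectory
#'
#' The delays require two preceding days of alcohol and one of desire, so a
#' solution is pinned down by three values: `A0`, the pre-study baseline
#' drinking level (average drinks/day from the Timeline Followback); `A1`,
#' drinks reported on the first diary day; and `D1`, the desire composite on
#' the first diary day.
#'
#' @param A0,A1 Nonnegative drink counts (real-valued).
#' @param D1 Desire composite in \[0, 12\].
#' @return Named numeric vector `c(A0, A1, D1)`.
#' @export
initial_conditions <- function(A0, A1, D1) {
  ics <- c(A0 = A0, A1 = A1, D1 = D1)
  if (!all(is.finite(ics))) stop("initial conditions must be finite", call. = FALSE)
  if (A0 < 0 || A1 < 0) stop("A0 and A1 must be nonnegative", call. = FALSE)
  if (D1 < 0 || D1 > 12) stop("D1 must lie in [0, 12]", call. = FALSE)
  ics
}

#' One-day update of the dual-process system
#'
#' Computes tonight's desire first (it depends only on yesterday's states) and
#' then tonight's alcohol, which uses the same-day desire change. This order is
#' the only one that makes the same-day coupling well-defined without solving a
#' simultaneous system.
#'
#' @param params Parameter vector (see [model_params()]).
#' @param A_prev Drinks last night.
#' @param A_prev2 Drinks two nights ago.
#' @param D_prev Desire last night.
#' @return Named numeric vector `c(A, D)` for tonight.
#' @export
step_day <- function(params, A_prev, A_prev2, D_prev) {
  p <- .as_params(params)
  x <- c(A_prev, A_prev2, D_prev)
  if (!all(is.finite(x))) stop("states must be finite", call. = FALSE)
  D_n <- p[["d1"]] * A_prev + p[["d2"]] * D_prev + p[["d3"]] * (A_prev - A_prev2)
  A_n <- p[["a1"]] * (D_n - D_prev) + p[["a2"]] * A_prev + p[["a3"]] * (A_prev - A_prev2)
  c(A = A_n, D = D_n)
}

#' Simulate a trajectory of nightly alcohol and desire
#'
#' Day 1 carries the initial values `(A1, D1)`; `A0` seeds the two-night delay
#' for the day-2 update; days 2..horizon iterate the system. With
#' `clip_nonneg = TRUE` every computed value is floored at zero before being
#' used in subsequent updates (the convention used in sensitivity sweeps,
#' where solutions are bounded to be biologically plausible); the raw linear
#' system (default) is what the calibration likelihood uses.
#'
#' @param params Parameter vector.
#' @param ics Initial conditions (see [initial_conditions()]) or any named
#'   vector with elements `A0, A1, D1`.
#' @param horizon Number of days to simulate (>= 2).
#' @param clip_nonneg Floor states at zero as they are generated.
#' @return Data frame with columns `day`, `A`, `D` and `horizon` rows.
#' @export
simulate_trajectory <- function(params, ics, horizon, clip_nonneg = FALSE) {
  p <- .as_params(params)
  if (!is.numeric(horizon) || length(horizon) != 1 || horizon < 2)
    stop("horizon must be a single integer >= 2", call. = FALSE)
  ics <- ics[c("A0", "A1", "D1")]
  if (anyNA(ics)) stop("ics must contain A0, A1, D1", call. = FALSE)
  m <- sim_core(unname(p), ics[["A0"]], ics[["A1"]], ics[["D1"]],
                as.integer(horizon), isTRUE(clip_nonneg))
  data.frame(day = seq_len(nrow(m)), A = m[, 1], D = m[, 2])
}

#' Companion matrix of the linearized system
#'
#' The system is linear in the state `(A_n, A_{n-1}, D_n)`; substituting the
#' desire update into the alcohol update gives a 3x3 one-step transition
#' matrix whose spectrum governs long-run behavior (dominant eigenvalue
#' modulus below one: damped; above one: growing).
#'
#' @param params Parameter vector.
#' @return 3x3 numeric matrix acting on `(A_{n-1}, A_{n-2}, D_{n-1})`.
#' @export
companion_matrix <- function(params) {
  p <- .as_params(params)
  a1 <- p[["a1"]]; a2 <- p[["a2"]]; a3 <- p[["a3"]]
  d1 <- p[["d1"]]; d2 <- p[["d2"]]; d3 <- p[["d3"]]
  matrix(c(
    a1 * (d1 + d3) + a2 + a3, -(a1 * d3 + a3), a1 * (d2 - 1),
    1,                         0,               0,
    d1 + d3,                  -d3,              d2
  ), nrow = 3, byrow = TRUE,
  dimnames = list(c("A_n", "A_nm1", "D_n"), c("A_nm1", "A_nm2", "D_nm1")))
}

#' Dominant eigenvalue modulus of the companion matrix
#' @param params Parameter vector.
#' @return Nonnegative real number.
#' @export
spectral_radius <- function(params) {
  max(Mod(eigen(companion_matrix(params), only.values = TRUE)$values))
}

#' Classify the steady states admitted by a parameter set
#'
#' Three special steady states exist. `E0 = (0, 0)` (abstinence with no
#' desire) always. When `d2 = 1` a line of equilibria `E1 = (0, D*)` appears:
#' abstinence with a constant positive desire. When `a2 = 1` and `d2 != 1`,
#' a line `E2 = (A*, d1 A* / (1 - d2))` appears: sustained moderated drinking
#' with constant desire; which `A*` is reached depends on the initial
#' conditions.
#'
#' @param params Parameter vector.
#' @param Astar Optional drinking level at which to evaluate the E2 desire
#'   constraint.
#' @param tol Tolerance for the `a2 = 1` / `d2 = 1` special cases.
#' @return List with elements `kind` (one of `"E0"`, `"E1-line"`, `"E2-line"`,
#'   `"none-of-special-cases"`), `Astar`, `Dstar`, and `note`.
#' @export
classify_equilibrium <- function(params, Astar = NULL, tol = 1e-9) {
  p <- .as_params(params)
  if (abs(p[["d2"]] - 1) < tol) {
    return(list(kind = "E1-line", Astar = 0, Dstar = NA_real_,
                note = "d2 = 1: abstinence with constant positive desire (any D*)"))
  }
  if (abs(p[["a2"]] - 1) < tol) {
    Dstar <- if (is.null(Astar)) NA_real_ else p[["d1"]] * Astar / (1 - p[["d2"]])
    return(list(kind = "E2-line", Astar = if (is.null(Astar)) NA_real_ else Astar,
                Dstar = Dstar,
                note = sprintf(
                  "a2 = 1, d2 != 1: sustained drinking with D* = d1*A*/(1-d2) = %.4f*A*",
                  p[["d1"]] / (1 - p[["d2"]]))))
  }
  list(kind = "none-of-special-cases", Astar = 0, Dstar = 0,
       note = "only the abstinence equilibrium E0 = (0, 0)")
}

#' Classify the qualitative behavior of a simulated solution
#'
#' Labels the alcohol trajectory as constant, monotone (increasing or
#' decreasing), damped-oscillatory, or growing, from the sign pattern of
#' successive differences and the trend of the oscillation envelope; the
#' dominant eigenvalue modulus of the companion matrix is reported as a
#' cross-check. Oscillation means at least two sign changes in the successive
#' differences of `A` over the horizon.
#'
#' @param params Parameter vector.
#' @param ics Initial conditions.
#' @param horizon Days to simulate (>= 10).
#' @param tol Differences below `tol` (relative to the trajectory scale) are
#'   treated as zero.
#' @return List with `label`, `rho` (dominant eigenvalue modulus), and
#'   `n_sign_changes`.
#' @export
classify_behavior <- function(params, ics, horizon = 100, tol = 1e-8) {
  if (horizon < 10) stop("horizon must be >= 10", call. = FALSE)
  traj <- simulate_trajectory(params, ics, horizon, clip_nonneg = FALSE)
  # classify from day 2 onward: day 1 is a data-pinned value, and the jump
  # into the dynamics would otherwise masquerade as a trend
  A <- traj$A[-1]
  horizon <- length(A)
  rho <- spectral_radius(params)
  scale <- max(abs(A), 1)
  d <- diff(A)
  d[abs(d) < tol * scale] <- 0
  s <- sign(d[d != 0])
  nsc <- if (length(s) > 1) sum(diff(s) != 0) else 0L
  grow <- rho > 1 + 1e-9 &&
    max(abs(A[seq(ceiling(horizon / 2) + 1, horizon)])) >
      max(abs(A[seq_len(ceiling(horizon / 2))]))
  label <-
    if (all(d == 0)) "constant"
    else if (grow) "growing"
    else if (nsc >= 2) "damped-oscillatory"
    else if (all(d >= 0)) "monotone-increasing"
    else if (all(d <= 0)) "monotone-decreasing"
    else "damped-oscillatory"
  list(label = label, rho = rho, n_sign_changes = nsc)
}

#' Write a trajectory to CSV
#' @param traj Data frame from [simulate_trajectory()].
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(traj, path, row.names = FALSE)
  invisible(path)
}
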