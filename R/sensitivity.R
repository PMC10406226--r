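# Global sensitivity analysis: Latin hypercube designs over the nine inputs
# (six coefficients + three initial conditions), four scalar output measures
# at 84-day and 1-year horizons, PRCC with z-test significance, and
# single-input monotonicity sweeps.

.lhs_inputs <- c("a1", "a2", "a3", "d1", "d2", "d3", "A0", "A1", "D1")

#' Default LHS sampling ranges
#'
#' Baselines are the population parameter means with ranges of plus/minus two
#' individual-level standard deviations, overridden by: a floor of 0.001 on
#' the initial conditions and `d2` (to keep them positive); `a1` sampled on
#' \[0.001, 1.0015\] and `d1` on \[0.001, 2.2742\] — maxima chosen so that
#' solutions with all other inputs at baseline never exceed 17 drinks on any
#' day, minima matching values observed during the per-patient calibrations.
#'
#' @param spread Parameter summary table with columns `parameter, mean, sd`,
#'   where `mean` is the population-level value (e.g. the `value`/`sd`
#'   columns of [summarize_posterior()]'s population table). Default: the
#'   packaged population values and individual-level standard deviations.
#' @param ics IC summary table as [ic_stats()].
#' @return Data frame with columns `input, lower, upper`.
#' @export
default_ranges <- function(spread = NULL, ics = ic_stats()) {
  if (is.null(spread)) {
    spread <- data.frame(parameter = names(population_params()),
                         mean = unname(population_params()),
                         sd = param_spread()$sd)
  }
  rng <- data.frame(input = .lhs_inputs, lower = NA_real_, upper = NA_real_)
  for (k in c("a2", "a3", "d2", "d3")) {
    r <- spread[spread$parameter == k, ]
    rng[rng$input == k, c("lower", "upper")] <-
      c(r$mean - 2 * r$sd, r$mean + 2 * r$sd)
  }
  for (k in c("A0", "A1", "D1")) {
    r <- ics[ics$condition == k, ]
    rng[rng$input == k, c("lower", "upper")] <-
      c(r$mean - 2 * r$sd, r$mean + 2 * r$sd)
  }
  floor_in <- c("A0", "A1", "D1", "d2")
  rng$lower[rng$input %in% floor_in] <-
    pmax(rng$lower[rng$input %in% floor_in], 0.001)
  rng[rng$input == "a1", c("lower", "upper")] <- c(0.001, 1.0015)
  rng[rng$input == "d1", c("lower", "upper")] <- c(0.001, 2.2742)
  if (any(rng$lower >= rng$upper))
    stop("degenerate sampling range (lower >= upper): ",
         paste(rng$input[rng$lower >= rng$upper], collapse = ", "),
         call. = FALSE)
  rng
}

#' Latin hypercube design over the sampling ranges
#'
#' Each input's interval is split into `n_samples` equal strata with exactly
#' one uniform draw per stratum, stratum order permuted independently per
#' input (stratified sampling without replacement).
#'
#' @param ranges Data frame from [default_ranges()].
#' @param n_samples Number of design points (>= 2).
#' @param seed Optional integer seed.
#' @return Matrix `n_samples` x `nrow(ranges)` with named columns.
#' @export
lhs_design <- function(ranges, n_samples, seed = NULL) {
  if (n_samples < 2) stop("n_samples must be >= 2", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  u <- lhs::randomLHS(n_samples, nrow(ranges))
  design <- sweep(u, 2, ranges$upper - ranges$lower, "*")
  design <- sweep(design, 2, ranges$lower, "+")
  colnames(design) <- ranges$input
  design
}

#' Evaluate the four output measures over a design
#'
#' Simulates the system with non-negativity clipping on (solutions bounded to
#' be biologically plausible during sweeps) and records total and maximum
#' daily alcohol and desire over the horizon.
#'
#' @param design Matrix with the nine named input columns.
#' @param horizon Days (84 for the observation window, 365 for one year).
#' @return Data frame with columns `sumA, sumD, maxA, maxD`.
#' @export
evaluate_outputs <- function(design, horizon = 84) {
  n <- nrow(design)
  out <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, c("sumA", "sumD", "maxA", "maxD")))
  for (i in seq_len(n)) {
    x <- design[i, ]
    m <- sim_core(unname(x[c("a1", "a2", "a3", "d1", "d2", "d3")]),
                  x[["A0"]], x[["A1"]], x[["D1"]], as.integer(horizon), TRUE)
    out[i, ] <- c(sum(m[, 1]), sum(m[, 2]), max(m[, 1]), max(m[, 2]))
  }
  as.data.frame(out)
}

#' Partial rank correlation coefficients
#'
#' Rank-transforms every input column and the output (ties get average
#' ranks), removes the rank-linear effect of all other inputs from both the
#' input of interest and the output by linear regression, and correlates the
#' two residual vectors. Rank-based, so invariant under strictly monotone
#' transforms of any column.
#'
#' @param design Input matrix (samples x inputs, named columns).
#' @param y Output vector (one measure).
#' @return Named numeric vector of PRCCs in \[-1, 1\] (NA for a constant
#'   input column, with a warning).
#' @export
prcc <- function(design, y) {
  n <- nrow(design)
  k <- ncol(design)
  if (n <= k + 2) stop("need n_samples > n_inputs + 2", call. = FALSE)
  Rx <- apply(design, 2, rank)
  Ry <- rank(y)
  out <- stats::setNames(rep(NA_real_, k), colnames(design))
  for (j in seq_len(k)) {
    if (stats::var(Rx[, j]) == 0) {
      warning("constant input column: ", colnames(design)[j], call. = FALSE)
      next
    }
    Z <- cbind(1, Rx[, -j, drop = FALSE])
    qz <- qr(Z)
    rx <- stats::resid(stats::lm.fit(Z, Rx[, j]))
    ry <- stats::resid(stats::lm.fit(Z, Ry))
    out[j] <- stats::cor(rx, ry)
  }
  out
}

#' z-test significance of PRCC values
#'
#' For each PRCC `g`, the statistic `g * sqrt((n - 2 - k) / (1 - g^2))` is
#' referred to a t distribution with `n - 2 - k` degrees of freedom (`k` =
#' number of conditioned inputs); two-sided p-values. `|PRCC| = 1` returns
#' p = 0 with a degeneracy flag.
#'
#' @param gamma PRCC values.
#' @param n_samples Number of design points.
#' @param n_conditioned Number of inputs conditioned on (inputs - 1).
#' @return Data frame with `prcc, statistic, p_value, degenerate`.
#' @export
prcc_significance <- function(gamma, n_samples, n_conditioned) {
  df <- n_samples - 2 - n_conditioned
  degen <- !is.na(gamma) & abs(gamma) >= 1
  stat <- ifelse(degen, Inf * sign(gamma),
                 gamma * sqrt(df / (1 - gamma^2)))
  p <- ifelse(degen, 0, 2 * stats::pt(-abs(stat), df = df))
  data.frame(input = names(gamma), prcc = as.numeric(gamma),
             statistic = as.numeric(stat), p_value = as.numeric(p),
             degenerate = degen, row.names = NULL)
}

#' Full LHS/PRCC sensitivity analysis
#'
#' Convenience wrapper: design, outputs at the requested horizon, PRCC per
#' input per measure, and two-sided p-values.
#'
#' @param ranges Data frame from [default_ranges()].
#' @param n_samples LHS size (default 1000).
#' @param horizon Days.
#' @param seed Optional integer seed.
#' @return List with `design`, `outputs`, `prcc` (inputs x measures matrix),
#'   `significance` (long data frame).
#' @export
sensitivity_analysis <- function(ranges = default_ranges(), n_samples = 1000,
                                 horizon = 84, seed = NULL) {
  design <- lhs_design(ranges, n_samples, seed)
  outputs <- evaluate_outputs(design, horizon)
  pr <- sapply(outputs, function(y) prcc(design, y))
  sig <- do.call(rbind, lapply(colnames(pr), function(msr) {
    s <- prcc_significance(stats::setNames(pr[, msr], rownames(pr)),
                           n_samples, ncol(design) - 1)
    cbind(measure = msr, s)
  }))
  list(design = design, outputs = outputs, prcc = pr, significance = sig)
}

#' Single-input monotonicity sweep
#'
#' Freezes all inputs at a base point, varies one over its range on an even
#' grid, and reports the four output measures plus a monotone/non-monotone
#' verdict per measure (from sign changes of successive differences, with a
#' relative tolerance for flat segments). Used to check that the
#' input-output relationships are monotone enough for PRCC to be meaningful.
#'
#' @param base Named vector of the nine inputs (e.g. population parameters
#'   plus median initial conditions).
#' @param input Name of the input to sweep.
#' @param range Length-2 vector (default: the input's row of
#'   [default_ranges()]).
#' @param n_grid Grid size (>= 3, default 25).
#' @param horizon Days.
#' @return List with `curve` (data frame: input value + four measures) and
#'   `monotone` (named logical per measure).
#' @export
monotonicity_sweep <- function(base, input, range = NULL, n_grid = 25,
                               horizon = 84) {
  if (n_grid < 3) stop("n_grid must be >= 3", call. = FALSE)
  if (is.null(range)) {
    rr <- default_ranges()
    range <- unlist(rr[rr$input == input, c("lower", "upper")])
  }
  grid <- seq(range[1], range[2], length.out = n_grid)
  design <- matrix(rep(base[.lhs_inputs], each = n_grid), nrow = n_grid,
                   dimnames = list(NULL, .lhs_inputs))
  design[, input] <- grid
  outs <- evaluate_outputs(design, horizon)
  monotone <- vapply(outs, function(y) {
    d <- diff(y)
    tol <- 1e-9 * max(abs(y), 1)
    d[abs(d) < tol] <- 0
    s <- sign(d[d != 0])
    length(s) == 0 || all(s == s[1])
  }, logical(1))
  list(curve = cbind(stats::setNames(data.frame(grid), input), outs),
       monotone = monotone)
}
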