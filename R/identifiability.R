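# Practical (local) identifiability screening via collinearity indices of the
# scaled local sensitivity matrix, evaluated per patient at that patient's own
# least-squares estimate.

#' Scaled local sensitivity matrix of the trajectory
#'
#' Central finite differences of [simulate_trajectory()] with respect to each
#' of the six model coefficients, restricted to the observed days, stacked as
#' all observed alcohol days followed by all observed desire days. Each entry
#' is non-dimensionalized as `(df_j/dtheta_k) * theta_k / sc_j`, where `sc_j`
#' is a per-output scale (the mean observed value of that output by default);
#' a parameter sitting exactly at zero gets weight 1 and an absolute
#' difference step instead of a relative one. The collinearity index is
#' invariant to this scaling up to the column normalization it applies anyway;
#' it is exposed for inspection.
#'
#' @param params Evaluation point (six coefficients).
#' @param ics Initial conditions.
#' @param horizon Days to simulate.
#' @param obs_A,obs_D Logical masks (length `horizon`) of observed alcohol /
#'   desire days; default all observed.
#' @param rel_step Relative finite-difference step (default 0.01).
#' @param abs_step Absolute step used when a parameter is zero.
#' @param scales Optional named vector `c(A = , D = )` of per-output scales;
#'   default mean simulated value of each output over its observed days.
#' @param clip_nonneg Simulate with non-negativity clipping.
#' @return Matrix with `sum(obs_A) + sum(obs_D)` rows and six named columns.
#' @export
sensitivity_matrix <- function(params, ics, horizon = 84,
                               obs_A = NULL, obs_D = NULL,
                               rel_step = 0.01, abs_step = 1e-4,
                               scales = NULL, clip_nonneg = FALSE) {
  p <- .as_params(params)
  if (is.null(obs_A)) obs_A <- rep(TRUE, horizon)
  if (is.null(obs_D)) obs_D <- rep(TRUE, horizon)
  base <- simulate_trajectory(p, ics, horizon, clip_nonneg)
  if (is.null(scales)) {
    scales <- c(A = mean(abs(base$A[obs_A])), D = mean(abs(base$D[obs_D])))
  }
  if (any(!is.finite(scales)) || any(scales <= 0))
    stop("degenerate output scaling (all-zero trajectory?)", call. = FALSE)
  S <- matrix(0, nrow = sum(obs_A) + sum(obs_D), ncol = 6,
              dimnames = list(NULL, names(p)))
  for (k in names(p)) {
    h <- if (p[[k]] == 0) abs_step else rel_step * abs(p[[k]])
    up <- p; up[[k]] <- up[[k]] + h
    dn <- p; dn[[k]] <- dn[[k]] - h
    tu <- simulate_trajectory(up, ics, horizon, clip_nonneg)
    td <- simulate_trajectory(dn, ics, horizon, clip_nonneg)
    dA <- (tu$A - td$A)[obs_A] / (2 * h)
    dD <- (tu$D - td$D)[obs_D] / (2 * h)
    w <- if (p[[k]] == 0) 1 else p[[k]]
    S[, k] <- c(dA * w / scales[["A"]], dD * w / scales[["D"]])
  }
  S
}

#' Collinearity index of a parameter subset
#'
#' Columns of the sensitivity matrix belonging to the subset are normalized
#' to unit Euclidean norm; the index is `1 / sqrt(lambda_min)` where
#' `lambda_min` is the smallest eigenvalue of the normalized Gram matrix.
#' Orthogonal columns give 1; nearly linearly dependent columns give large
#' values; an exactly dependent (or all-zero) subset gives `Inf`.
#'
#' @param S Sensitivity matrix with named columns.
#' @param subset Column names (or indices) of the subset.
#' @return Nonnegative real (>= 1), possibly `Inf`.
#' @export
collinearity_index <- function(S, subset) {
  X <- S[, subset, drop = FALSE]
  norms <- sqrt(colSums(X^2))
  if (any(norms == 0)) return(Inf)
  Xn <- sweep(X, 2, norms, "/")
  lam <- eigen(crossprod(Xn), symmetric = TRUE, only.values = TRUE)$values
  lmin <- min(lam)
  if (lmin <= .Machine$double.eps) return(Inf)
  1 / sqrt(lmin)
}

#' Screen every parameter subset for identifiability
#'
#' Evaluates the collinearity index of every subset of the matrix columns
#' (singletons are trivially identifiable: their normalized index is 1) and
#' flags a subset identifiable when its index falls below the threshold.
#' Indices in `[threshold, 1.5 * threshold)` get a near-threshold annotation
#' (still non-identifiable) since the cutoff is conventional rather than
#' principled.
#'
#' @param S Sensitivity matrix with named columns.
#' @param threshold Identifiability cutoff (default 20).
#' @return Data frame of class `collinearity_report` with columns
#'   `subset, size, index, identifiable, near_threshold`.
#' @export
subset_screen <- function(S, threshold = 20) {
  pnames <- colnames(S)
  p <- length(pnames)
  rows <- list()
  for (size in seq_len(p)) {
    combs <- utils::combn(pnames, size, simplify = FALSE)
    for (cc in combs) {
      idx <- collinearity_index(S, cc)
      rows[[length(rows) + 1L]] <- data.frame(
        subset = paste(cc, collapse = "+"), size = size, index = idx,
        identifiable = is.finite(idx) && idx < threshold,
        near_threshold = is.finite(idx) &&
          idx >= threshold && idx < 1.5 * threshold)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  class(out) <- c("collinearity_report", class(out))
  out
}

#' Select the largest commonly identifiable parameter subset
#'
#' Given per-patient screening reports, chooses the subset identifiable in
#' the largest number of patients; among those, prefers larger subsets; ties
#' are broken by the smaller maximum index across patients. The full
#' per-subset tally is returned so that a judgment call trading coverage for
#' subset size (as done when a large subset is identifiable in most but not
#' all patients) can be made by inspection.
#'
#' @param reports List of [subset_screen()] outputs, one per patient.
#' @return List with `subset` (character vector of parameter names),
#'   `n_patients_identifiable`, `max_index`, and `tally` (per-subset data
#'   frame sorted by the selection order).
#' @export
select_common_subset <- function(reports) {
  if (length(reports) == 0) stop("need at least one report", call. = FALSE)
  keys <- reports[[1]]$subset
  counts <- rowSums(vapply(reports, function(r)
    r$identifiable[match(keys, r$subset)], logical(length(keys))))
  maxidx <- apply(vapply(reports, function(r)
    r$index[match(keys, r$subset)], numeric(length(keys))), 1, max)
  tally <- data.frame(subset = keys, size = reports[[1]]$size,
                      n_patients = counts, max_index = maxidx)
  ord <- order(-tally$n_patients, -tally$size, tally$max_index)
  tally <- tally[ord, ]
  rownames(tally) <- NULL
  best <- tally[1, ]
  list(subset = strsplit(best$subset, "+", fixed = TRUE)[[1]],
       n_patients_identifiable = best$n_patients,
       max_index = best$max_index,
       tally = tally)
}

#' Write a collinearity report (or several) to CSV
#' @param reports List of `collinearity_report`s named by patient id, or one
#'   report.
#' @param path Output CSV path.
#' @return The path, invisibly.
#' @export
write_collinearity_csv <- function(reports, path) {
  if (inherits(reports, "collinearity_report")) reports <- list(all = reports)
  tab <- do.call(rbind, lapply(names(reports), function(id) {
    r <- as.data.frame(reports[[id]])
    cbind(patient_id = id, r)
  }))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
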