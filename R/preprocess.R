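#' Desire composite from three Likert items
#'
#' Daily desire (craving) is measured with three 0-4 Likert items; the first
#' ("I really don't feel like drinking") is reverse-coded and the three are
#' summed, giving a composite in 0-12. Vectorized over days.
#'
#' @param item1,item2,item3 Integer vectors with values in 0..4 (NA allowed;
#'   any missing item yields a missing composite).
#' @return Integer vector of composites in 0..12.
#' @export
desire_composite <- function(item1, item2, item3) {
  items <- cbind(item1, item2, item3)
  obs <- items[!is.na(items)]
  if (any(obs != round(obs) | obs < 0 | obs > 4))
    stop("Likert items must be integers in 0..4", call. = FALSE)
  as.integer((4 - item1) + item2 + item3)
}

#' Winsorize drink counts at a data-driven or fixed cap
#'
#' Caps extreme drink counts to limit outlier influence on model building.
#' The default cap is `round(mean + k * sd)` of the pooled values (sample sd,
#' n-1 denominator); a known cap (e.g. the reference cohort's 17) can be
#' supplied instead.
#'
#' @param values Nonnegative, non-missing drink counts (pooled across the
#'   cohort).
#' @param k Number of standard deviations above the mean (default 2).
#' @param fixed_cap Optional fixed cap overriding the data-driven rule.
#' @return List with `values` (capped), `cap`, and `n_affected`.
#' @export
winsorize_drinks <- function(values, k = 2, fixed_cap = NULL) {
  if (length(values) == 0) stop("empty value sequence", call. = FALSE)
  if (anyNA(values) || any(values < 0))
    stop("values must be nonnegative and non-missing", call. = FALSE)
  cap <- if (!is.null(fixed_cap)) fixed_cap
         else round(mean(values) + k * stats::sd(values))
  n_affected <- sum(values > cap)
  values[values > cap] <- cap
  list(values = values, cap = cap, n_affected = n_affected)
}

#' Build a patient series
#'
#' The unit of observation: one subject's daily diary over the study window
#' plus the Timeline Followback baseline. Records are completed to the full
#' day grid (missing days get NA) and sorted by day.
#'
#' @param patient_id Identifier (coerced to character).
#' @param day Integer day indices in 1..n_days.
#' @param drinks Nonnegative drink counts (NA = missing).
#' @param desire Desire composites in 0..12 (NA = missing).
#' @param tlfb_baseline Baseline average drinks/day (finite, >= 0).
#' @param n_days Length of the study window (default 84).
#' @return Object of class `patient_series`: list with `patient_id`,
#'   `records` (data frame `day, drinks, desire`), `tlfb_baseline`, `n_days`.
#' @export
patient_series <- function(patient_id, day, drinks, desire, tlfb_baseline,
                           n_days = 84) {
  if (!is.finite(tlfb_baseline) || tlfb_baseline < 0)
    stop("tlfb_baseline must be finite and nonnegative", call. = FALSE)
  if (anyDuplicated(day)) stop("duplicate day within patient", call. = FALSE)
  rec <- data.frame(day = seq_len(n_days), drinks = NA_real_, desire = NA_real_)
  idx <- match(day, rec$day)
  if (anyNA(idx)) stop("day indices must lie in 1..n_days", call. = FALSE)
  rec$drinks[idx] <- drinks
  rec$desire[idx] <- desire
  structure(list(patient_id = as.character(patient_id), records = rec,
                 tlfb_baseline = tlfb_baseline, n_days = n_days),
            class = "patient_series")
}

#' @export
print.patient_series <- function(x, ...) {
  n_obs <- sum(!is.na(x$records$drinks) & !is.na(x$records$desire))
  cat(sprintf("<patient_series %s: %d/%d complete days, TLFB baseline %.2f>\n",
              x$patient_id, n_obs, x$n_days, x$tlfb_baseline))
  invisible(x)
}

#' Apply the cohort inclusion criteria
#'
#' A patient enters the analysis only with at least `min_completeness` of the
#' possible diary days complete (both drinks and desire reported; denominator
#' is the full study window) and with data extending beyond the window's
#' midpoint.
#'
#' @param series A `patient_series`.
#' @param min_completeness Minimum fraction of complete days (default 0.30).
#' @param min_last_day Last observed day must exceed this (default 42).
#' @return Logical scalar.
#' @export
inclusion_filter <- function(series, min_completeness = 0.30, min_last_day = 42) {
  rec <- series$records
  complete <- !is.na(rec$drinks) & !is.na(rec$desire)
  any_obs <- !is.na(rec$drinks) | !is.na(rec$desire)
  if (!any(any_obs)) return(FALSE)
  (sum(complete) / series$n_days >= min_completeness) &&
    (max(rec$day[any_obs]) > min_last_day)
}

#' Weekly averages of drinks and desire
#'
#' Non-overlapping 7-day windows (days 1-7, 8-14, ...); each week's mean is
#' taken over the non-missing values; a week with no observations is NA.
#'
#' @param series A `patient_series`.
#' @return Data frame with columns `week, mean_drinks, mean_desire`.
#' @export
weekly_average <- function(series) {
  rec <- series$records
  week <- (rec$day - 1) %/% 7 + 1
  wk_mean <- function(v) {
    out <- tapply(v, week, function(x) mean(x, na.rm = TRUE))
    out[is.nan(out)] <- NA_real_
    as.numeric(out)
  }
  data.frame(week = sort(unique(week)),
             mean_drinks = wk_mean(rec$drinks),
             mean_desire = wk_mean(rec$desire))
}

# The six lag panels that motivated the linear model terms: response,
# predictor, and the (lagged) fields each needs.
.lag_panels <- list(
  A_vs_dD    = list(response = "A_n", predictor = "D_n - D_nm1"),
  A_vs_Alag  = list(response = "A_n", predictor = "A_nm1"),
  A_vs_dA    = list(response = "A_n", predictor = "A_nm1 - A_nm2"),
  D_vs_Alag  = list(response = "D_n", predictor = "A_nm1"),
  D_vs_Dlag  = list(response = "D_n", predictor = "D_nm1"),
  D_vs_dA    = list(response = "D_n", predictor = "A_nm1 - A_nm2")
)

#' Binned lag relationships pooled across a cohort
#'
#' For each of the six panels relating tonight's drinks or desire to lagged
#' quantities (the empirical relationships that justify the model's linear
#' terms), pools all patients' valid consecutive-day tuples, bins the
#' predictor at integer values (rounding to the nearest integer), and returns
#' the mean response, support, and a low-support flag per bin. A tuple is used
#' only when every field the panel needs is non-missing on the consecutive
#' calendar days involved; no imputation.
#'
#' @param cohort List of `patient_series`.
#' @param low_support Bins with fewer than this many tuples are flagged
#'   (default 10).
#' @return Named list of six data frames with columns
#'   `bin, mean_response, n, low_support`, each carrying attributes
#'   `response` and `predictor`.
#' @export
binned_lag_relationships <- function(cohort, low_support = 10) {
  pull <- function(s) {
    r <- s$records
    n <- nrow(r)
    data.frame(
      A_n = r$drinks[3:n], A_nm1 = r$drinks[2:(n - 1)], A_nm2 = r$drinks[1:(n - 2)],
      D_n = r$desire[3:n], D_nm1 = r$desire[2:(n - 1)]
    )
  }
  pooled <- do.call(rbind, lapply(cohort, pull))
  lapply(.lag_panels, function(panel) {
    resp <- with(pooled, eval(parse(text = panel$response)))
    pred <- with(pooled, eval(parse(text = panel$predictor)))
    ok <- !is.na(resp) & !is.na(pred)
    if (!any(ok)) {
      out <- data.frame(bin = numeric(0), mean_response = numeric(0),
                        n = integer(0), low_support = logical(0))
    } else {
      bin <- round(pred[ok])
      mr <- tapply(resp[ok], bin, mean)
      cnt <- tapply(resp[ok], bin, length)
      out <- data.frame(bin = as.numeric(names(mr)),
                        mean_response = as.numeric(mr),
                        n = as.integer(cnt),
                        low_support = as.integer(cnt) < low_support)
      out <- out[order(out$bin), ]
      rownames(out) <- NULL
    }
    attr(out, "response") <- panel$response
    attr(out, "predictor") <- panel$predictor
    out
  })
}

#' Read a daily-diary CSV
#'
#' Expected columns: `patient_id, day, drinks` and either `desire` or the
#' three items `item1, item2, item3` (composite computed with
#' [desire_composite()]). Missing entries are empty fields.
#'
#' @param path CSV file path.
#' @return Data frame with columns `patient_id, day, drinks, desire`.
#' @export
read_diary_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "day", "drinks")
  if (!all(need %in% names(d)))
    stop("diary CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  if (!"desire" %in% names(d)) {
    if (!all(c("item1", "item2", "item3") %in% names(d)))
      stop("diary CSV needs 'desire' or 'item1','item2','item3'", call. = FALSE)
    d$desire <- desire_composite(d$item1, d$item2, d$item3)
  }
  d$patient_id <- as.character(d$patient_id)
  d[c("patient_id", "day", "drinks", "desire")]
}

#' Read a baseline (TLFB) CSV
#' @param path CSV with columns `patient_id, tlfb_avg_drinks_per_day`.
#' @return Data frame.
#' @export
read_baseline_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "tlfb_avg_drinks_per_day")
  if (!all(need %in% names(d)))
    stop("baseline CSV must contain columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  d$patient_id <- as.character(d$patient_id)
  d
}

#' Assemble a cohort from diary and baseline tables
#'
#' Joins the two CSV dialects into a list of [patient_series()], optionally
#' winsorizing the pooled drink counts first (cap shared across the cohort).
#'
#' @param diary Data frame from [read_diary_csv()].
#' @param baseline Data frame from [read_baseline_csv()].
#' @param winsorize Apply [winsorize_drinks()] to the pooled drinks.
#' @param fixed_cap Optional fixed winsorization cap (e.g. 17).
#' @param n_days Study window length.
#' @return List of `patient_series` (one per patient present in both tables),
#'   with attribute `winsorization` recording cap and count when applied.
#' @export
build_cohort <- function(diary, baseline, winsorize = TRUE, fixed_cap = NULL,
                         n_days = 84) {
  wins <- NULL
  if (winsorize) {
    obs <- !is.na(diary$drinks)
    w <- winsorize_drinks(diary$drinks[obs], fixed_cap = fixed_cap)
    diary$drinks[obs] <- w$values
    wins <- list(cap = w$cap, n_affected = w$n_affected)
  }
  ids <- intersect(unique(diary$patient_id), baseline$patient_id)
  cohort <- lapply(ids, function(id) {
    di <- diary[diary$patient_id == id, ]
    patient_series(id, di$day, di$drinks, di$desire,
                   baseline$tlfb_avg_drinks_per_day[
                     match(id, baseline$patient_id)],
                   n_days = n_days)
  })
  names(cohort) <- ids
  attr(cohort, "winsorization") <- wins
  cohort
}
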