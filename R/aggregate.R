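# Weekly (visit-level) digital markers: windowing, validity rules,
# transformation and standardization.

#' Collapse one participant's daily values into a weekly marker
#'
#' The observation window is the `window_days` days strictly after the
#' baseline visit (the baseline day itself is excluded). For every measure
#' except `mode_intertap_dist` the marker is the mean of the non-null daily
#' values, provided at least `min_valid` are non-null. `mode_intertap_dist`
#' is already a trailing 7-day statistic, so its marker is the last valid
#' value in the window, guarded by `intertap_min_valid` instead of the 4-day
#' rule (set `intertap_min_valid = min_valid` to re-impose it).
#'
#' @param dates local dates of the daily observations
#' @param values daily values (may contain `NA`)
#' @param baseline_date baseline visit date
#' @param measure_name one of [measure_sources()] names
#' @param window_days window length, days (default 7)
#' @param min_valid minimum non-null daily observations (default 4)
#' @param intertap_min_valid validity floor for the last-valid rule
#' @return list: `value` (NA when the validity rule fails), `n_valid_days`,
#'   `rule` (`"mean_of_week"` or `"last_valid"`)
#' @examples
#' b <- as.Date("2021-03-01")
#' weekly_marker(b + 1:7, c(7, 8, 9, 8, NA, NA, NA), b, "total_sleep_hrs")
#' @export
weekly_marker <- function(dates, values, baseline_date, measure_name,
                          window_days = 7, min_valid = 4,
                          intertap_min_valid = 1) {
  dates <- as.Date(dates)
  baseline_date <- as.Date(baseline_date)
  lo <- baseline_date + 1
  hi <- baseline_date + window_days
  if (any(dates < lo | dates > hi))
    stop(sprintf(
      "daily rows outside the observation window (%s .. %s): %s",
      format(lo), format(hi),
      paste(format(dates[dates < lo | dates > hi]), collapse = ", ")))
  ord <- order(dates)
  dates <- dates[ord]; values <- values[ord]
  ok <- !is.na(values)
  n_valid <- sum(ok)
  if (identical(measure_name, "mode_intertap_dist")) {
    value <- if (n_valid >= max(1, intertap_min_valid))
      values[ok][n_valid] else NA_real_
    rule <- "last_valid"
  } else {
    value <- if (n_valid >= min_valid) mean(values[ok]) else NA_real_
    rule <- "mean_of_week"
  }
  list(value = value, n_valid_days = n_valid, rule = rule)
}

#' Weekly markers for a whole cohort
#'
#' @param daily stacked daily-measures data.frame from [extract_features()]
#' @param intertap stacked intertap data.frame from [extract_features()]
#' @param baseline_dates data.frame (participant_id, baseline_date)
#' @inheritParams weekly_marker
#' @return wide data.frame: participant_id plus one column per digital
#'   measure (NA where the validity rule failed)
#' @export
aggregate_markers <- function(daily, intertap, baseline_dates,
                              window_days = 7, min_valid = 4,
                              intertap_min_valid = 1) {
  ids <- baseline_dates$participant_id
  meas <- names(measure_sources())
  out <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  for (m in meas) out[[m]] <- NA_real_
  for (i in seq_along(ids)) {
    pid <- ids[i]
    b <- as.Date(baseline_dates$baseline_date[i])
    drows <- daily[daily$participant_id == pid, , drop = FALSE]
    irows <- intertap[intertap$participant_id == pid, , drop = FALSE]
    for (m in meas) {
      src <- if (m == "mode_intertap_dist") irows else drows
      if (!nrow(src)) next
      wm <- weekly_marker(src$local_date, src[[m]], b, m, window_days,
                          min_valid, intertap_min_valid)
      out[[m]][i] <- wm$value
    }
  }
  out
}

standardize_columns <- function(df, vars, transform = character(0)) {
  center <- scale_ <- setNames(numeric(length(vars)), vars)
  trans <- setNames(rep("none", length(vars)), vars)
  z <- df
  for (v in vars) {
    x <- df[[v]]
    if (v %in% transform) {
      if (any(x < 0, na.rm = TRUE))
        stop(sprintf("log1p transform requires non-negative values in '%s'", v))
      x <- log1p(x)
      trans[v] <- "log1p"
    }
    ok <- !is.na(x)
    if (sum(ok) < 2)
      stop(sprintf("fewer than 2 non-null values in '%s'", v))
    m <- mean(x[ok])
    s <- sd(x[ok])                # sample SD, ddof = 1
    if (s == 0)
      stop(sprintf("zero standard deviation in '%s': cannot standardize", v))
    center[v] <- m; scale_[v] <- s
    z[[v]] <- (x - m) / s
  }
  structure(list(data = z, vars = vars, center = center, scale = scale_,
                 transform_applied = trans),
            class = "standardized_matrix")
}

#' @export
print.standardized_matrix <- function(x, ...) {
  cat(sprintf("<standardized_matrix> %d rows x %d variables (%d log1p-transformed)\n",
              nrow(x$data), length(x$vars),
              sum(x$transform_applied == "log1p")))
  invisible(x)
}

#' Transform and standardize the cohort marker table
#'
#' Applies `log(1 + x)` to the particularly skewed markers (by default
#' distance travelled and messages sent), then z-scores every measure column
#' across the population on its non-null support (sample SD, ddof = 1). The
#' null mask is preserved: standardization is complete-case per column.
#'
#' @param markers wide marker data.frame from [aggregate_markers()]
#' @param log1p_vars character vector of variables to log1p-transform first
#' @return a `standardized_matrix`: `data` (participant_id + z-scored
#'   columns), `center`, `scale`, `transform_applied`
#' @export
transform_and_standardize <- function(markers,
                                      log1p_vars = c("dist_travelled",
                                                     "total_msg_sent")) {
  vars <- intersect(names(measure_sources()), names(markers))
  standardize_columns(markers, vars, transform = log1p_vars)
}

#' Prepare and standardize the clinical table
#'
#' Derives the analysis orientation of the two reversed instruments —
#' `inv_sofas_rating = 100 - SOFAS` and `neg_bacs_comp = -BACS` so that
#' higher always means worse — then z-scores all clinical measures and age
#' across the population. Age standardized means an age term of zero is
#' exactly the cohort mean age, making the digital coefficient directly
#' interpretable at mean age. The study-phone indicator is carried through
#' unstandardized (own = 0, study = 1).
#'
#' @param profiles clinical profiles data.frame from [generate_cohort()]
#' @return a `standardized_matrix` over [clinical_measures()] plus `age`;
#'   `data` also carries `uses_study_phone`
#' @export
prepare_clinical <- function(profiles) {
  df <- profiles
  df$inv_sofas_rating <- 100 - df$sofas
  df$neg_bacs_comp <- -df$bacs_composite
  vars <- c(intersect(clinical_measures(), names(df)), "age")
  keep <- c("participant_id", "uses_study_phone", vars)
  standardize_columns(df[, keep, drop = FALSE], vars)
}
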