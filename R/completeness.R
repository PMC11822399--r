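# Successful data-collection rates over hourly windows, and the
# study-phone vs own-phone group comparison.

#' Successful data-collection rate for one participant
#'
#' Fraction of the `24 * n_days` hour-long windows following the first local
#' midnight after baseline that contain at least one sample from the
#' reference sensor: the heart-rate stream for the wearable, the
#' ambient-light presence stream for the phone. Sample density beyond the
#' first sample does not matter — one sample saturates a window.
#'
#' @param bundle a `sensor_bundle`
#' @param source `"wearable"` or `"phone"`
#' @return fraction in `[0, 1]`
#' @export
completeness_rate <- function(bundle, source = c("wearable", "phone")) {
  source <- match.arg(source)
  n_windows <- 24L * bundle$n_days
  first <- 24L                       # windows 24 .. 24 + n_windows - 1
  idx <- if (source == "wearable") {
    if (!nrow(bundle$hr)) integer(0) else
      hour_index(bundle$hr$ts, bundle$baseline_date, bundle$tz_offset_hrs)
  } else {
    bundle$light_hours
  }
  idx <- idx[idx >= first & idx < first + n_windows]
  length(unique(idx)) / n_windows
}

#' Completeness report for a cohort
#'
#' @param bundles list of `sensor_bundle` objects
#' @return data.frame: participant_id, wearable_rate, phone_rate, n_windows
#' @export
completeness_table <- function(bundles) {
  data.frame(
    participant_id = vapply(bundles, `[[`, "", "participant_id"),
    wearable_rate = vapply(bundles, completeness_rate, 0, source = "wearable"),
    phone_rate = vapply(bundles, completeness_rate, 0, source = "phone"),
    n_windows = vapply(bundles, function(b) as.integer(24 * b$n_days), 0L),
    stringsAsFactors = FALSE)
}

#' Mann-Whitney U comparison of two groups
#'
#' Rank-sum statistic with midranks for ties. The two-sided p-value uses the
#' exact null distribution when `n1 * n2 <= 400` and the pooled sample has no
#' ties, otherwise the normal approximation with tie-corrected variance and a
#' 0.5 continuity correction. The exact two-sided p is
#' `min(1, 2 * min(P(U <= u), P(U >= u)))`.
#'
#' @param x,y numeric vectors (e.g. completeness rates per group)
#' @return list: `U` (statistic for `x`), `p_two_sided`, `group_means`,
#'   `method`
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))  # U = 0, exact p = 0.1
#' @export
mann_whitney_u <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  n1 <- length(x); n2 <- length(y)
  pooled <- c(x, y)
  r <- rank(pooled)                      # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(pooled))
  if (all(pooled == pooled[1])) {
    return(list(U = U, p_two_sided = 1,
                group_means = c(x = mean(x), y = mean(y)),
                method = "degenerate"))
  }
  if (!ties && n1 * n2 <= 400) {
    lowtail <- stats::pwilcox(U, n1, n2)
    hightail <- 1 - if (U >= 1) stats::pwilcox(U - 1, n1, n2) else 0
    p <- min(1, 2 * min(lowtail, hightail))
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    nt <- table(pooled)
    n <- n1 + n2
    tiecorr <- sum(nt^3 - nt) / (n * (n - 1))
    sigma2 <- n1 * n2 / 12 * ((n + 1) - tiecorr)
    zstat <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
    p <- min(1, 2 * pnorm(-abs(zstat)))
    method <- "normal"
  }
  list(U = U, p_two_sided = p,
       group_means = c(x = mean(x), y = mean(y)), method = method)
}

#' Cohort completeness summary with the phone-group comparison
#'
#' @param bundles list of `sensor_bundle` objects
#' @param profiles clinical profiles (for the study-phone indicator)
#' @return list: `per_participant` table, `cohort` means/SDs, `group_means`
#'   (phone rate by study/own phone) and the Mann-Whitney comparison
#' @export
completeness_summary <- function(bundles, profiles) {
  tab <- completeness_table(bundles)
  m <- match(tab$participant_id, profiles$participant_id)
  study <- profiles$uses_study_phone[m]
  cmp <- mann_whitney_u(tab$phone_rate[study], tab$phone_rate[!study])
  list(per_participant = tab,
       cohort = list(
         wearable_mean = mean(tab$wearable_rate),
         wearable_sd = sd(tab$wearable_rate),
         phone_mean = mean(tab$phone_rate),
         phone_sd = sd(tab$phone_rate)),
       group_means = c(study_phone = mean(tab$phone_rate[study]),
                       own_phone = mean(tab$phone_rate[!study])),
       comparison = cmp)
}
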