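# Time conventions used throughout:
#  - raw timestamps are numeric seconds since the Unix epoch, UTC
#  - the cohort lives at a single fixed UTC offset (default +8); "local"
#    dates and hour windows are defined against that offset, never against
#    the R session time zone

SECS_PER_DAY <- 86400
SECS_PER_HOUR <- 3600

#' Local calendar date of a UTC timestamp
#'
#' @param ts numeric vector, seconds since epoch (UTC)
#' @param tz_offset_hrs fixed UTC offset of the cohort, hours
#' @return `Date` vector
#' @keywords internal
local_date <- function(ts, tz_offset_hrs) {
  as.Date(floor((ts + tz_offset_hrs * SECS_PER_HOUR) / SECS_PER_DAY),
          origin = "1970-01-01")
}

# UTC timestamp of local midnight starting `date`
local_midnight_utc <- function(date, tz_offset_hrs) {
  as.numeric(as.Date(date)) * SECS_PER_DAY - tz_offset_hrs * SECS_PER_HOUR
}

# Absolute hour-window index of a timestamp, counted from local midnight of
# the baseline date (window 0 = baseline day 00:00-01:00 local). The
# completeness window of study spans indices 24 .. 24 + 24*n_days - 1.
hour_index <- function(ts, baseline_date, tz_offset_hrs) {
  as.integer(floor((ts - local_midnight_utc(baseline_date, tz_offset_hrs)) /
                     SECS_PER_HOUR))
}

# total length (seconds) of the intersection of intervals [s1,e1) with a
# single interval [s2,e2); vectorised over s1/e1
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}
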