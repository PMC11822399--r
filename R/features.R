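# Daily digital measures extracted from one participant's raw streams.
# A sleep segment belongs to the local date of its END (wake-up date),
# matching the wearable vendor's reporting convention.

EARTH_RADIUS_KM <- 6371.0088

#' Haversine great-circle distance
#'
#' @param lat1,lon1,lat2,lon2 coordinates in degrees; vectorised
#' @return distance in km
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad / 2
  dlon <- (lon2 - lon1) * to_rad / 2
  a <- sin(dlat)^2 + cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon)^2
  2 * EARTH_RADIUS_KM * asin(pmin(1, sqrt(a)))
}

segments_for_date <- function(sleep, date, tz_offset_hrs) {
  if (!nrow(sleep)) return(sleep)
  sleep[local_date(sleep$end, tz_offset_hrs) == as.Date(date), , drop = FALSE]
}

#' Sleep measures for one local date
#'
#' Every sleep segment (main night or nap) is assigned to the local date on
#' which it ends. Total sleep sums the light, deep and REM stage hours over
#' all assigned segments (naps included); wake hours are tallied separately;
#' efficiency is taken from the assigned main segment only (`NA` if the date
#' has none; if several, the longest main segment wins).
#'
#' @param sleep data.frame of segments (seg_id, start, end, is_main,
#'   efficiency)
#' @param stages data.frame of stage bouts (seg_id, stage, start, end)
#' @param date local calendar date
#' @param tz_offset_hrs cohort UTC offset
#' @return named list: total_sleep_hrs, sleep_hrs_wake, sleep_hrs_light,
#'   sleep_hrs_deep, sleep_hrs_rem, sleep_efficiency (all `NA` when no
#'   segment is assigned to the date)
#' @export
sleep_measures_for_day <- function(sleep, stages, date, tz_offset_hrs = 8) {
  out <- list(total_sleep_hrs = NA_real_, sleep_hrs_wake = NA_real_,
              sleep_hrs_light = NA_real_, sleep_hrs_deep = NA_real_,
              sleep_hrs_rem = NA_real_, sleep_efficiency = NA_real_)
  segs <- segments_for_date(sleep, date, tz_offset_hrs)
  if (!nrow(segs)) return(out)
  segs <- segs[order(segs$start), , drop = FALSE]
  if (nrow(segs) > 1) {
    lap <- which(segs$start[-1] < segs$end[-nrow(segs)])
    if (length(lap))
      stop(sprintf(
        "overlapping sleep segments assigned to %s: segment %s [%s, %s) overlaps segment %s [%s, %s)",
        format(as.Date(date)),
        segs$seg_id[lap[1]], segs$start[lap[1]], segs$end[lap[1]],
        segs$seg_id[lap[1] + 1], segs$start[lap[1] + 1], segs$end[lap[1] + 1]))
  }
  st <- stages[stages$seg_id %in% segs$seg_id, , drop = FALSE]
  hrs <- tapply((st$end - st$start) / SECS_PER_HOUR, st$stage, sum)
  g <- function(s) if (s %in% names(hrs)) unname(hrs[[s]]) else 0
  out$sleep_hrs_wake <- g("wake")
  out$sleep_hrs_light <- g("light")
  out$sleep_hrs_deep <- g("deep")
  out$sleep_hrs_rem <- g("rem")
  out$total_sleep_hrs <- out$sleep_hrs_light + out$sleep_hrs_deep +
    out$sleep_hrs_rem
  mains <- segs[segs$is_main, , drop = FALSE]
  if (nrow(mains)) {
    mains <- mains[order(mains$end - mains$start, decreasing = TRUE), ,
                   drop = FALSE]
    out$sleep_efficiency <- mains$efficiency[1]
  }
  out
}

#' Mean sleeping heart rate for one local date
#'
#' Unweighted mean of heart-rate samples whose timestamps fall inside the
#' date's assigned sleep segments but outside wake-stage sub-intervals (main
#' segment and naps alike). `NA` when no sample qualifies.
#'
#' @param hr data.frame (ts, bpm), time-ordered
#' @inheritParams sleep_measures_for_day
#' @return bpm, or `NA`
#' @export
hr_asleep <- function(hr, sleep, stages, date, tz_offset_hrs = 8) {
  segs <- segments_for_date(sleep, date, tz_offset_hrs)
  if (!nrow(segs) || !nrow(hr)) return(NA_real_)
  st <- stages[stages$seg_id %in% segs$seg_id & stages$stage != "wake", ,
               drop = FALSE]
  if (!nrow(st)) return(NA_real_)
  st <- st[order(st$start), , drop = FALSE]
  j <- findInterval(hr$ts, st$start)
  inside <- j > 0 & hr$ts < st$end[pmax(j, 1)]
  if (!any(inside)) return(NA_real_)
  mean(hr$bpm[inside])
}

#' Distance travelled on one local date
#'
#' Drops fixes with accuracy worse than `max_accuracy_m`, then sums haversine
#' hop distances between consecutive retained fixes. Hops implying a speed
#' above `max_speed_kmh` (teleports) or displacing less than
#' `min_displacement_m` (GPS jitter) contribute zero. `NA` with fewer than
#' two retained fixes.
#'
#' @param gps data.frame (ts, lat, lon, accuracy), time-ordered
#' @param date local calendar date
#' @param tz_offset_hrs cohort UTC offset
#' @param max_accuracy_m accuracy filter, metres
#' @param min_displacement_m jitter floor, metres
#' @param max_speed_kmh teleport filter, km/h
#' @return km, or `NA`
#' @export
distance_travelled <- function(gps, date, tz_offset_hrs = 8,
                               max_accuracy_m = 100, min_displacement_m = 30,
                               max_speed_kmh = 150) {
  if (!nrow(gps)) return(NA_real_)
  day <- gps[local_date(gps$ts, tz_offset_hrs) == as.Date(date), ,
             drop = FALSE]
  if (!nrow(day)) return(NA_real_)
  if (any(!is.finite(day$lat)) || any(!is.finite(day$lon)))
    stop("non-finite GPS coordinates")
  day <- day[day$accuracy <= max_accuracy_m, , drop = FALSE]
  if (nrow(day) < 2) return(NA_real_)
  n <- nrow(day)
  hop <- haversine_km(day$lat[-n], day$lon[-n], day$lat[-1], day$lon[-1])
  dt_h <- diff(day$ts) / SECS_PER_HOUR
  speed <- ifelse(dt_h > 0, hop / dt_h, Inf)
  hop[speed > max_speed_kmh | hop * 1000 < min_displacement_m] <- 0
  sum(hop)
}

#' Modal intertap interval over a trailing window
#'
#' Intertap durations are gaps between consecutive non-game taps belonging to
#' the same typing session (gap at most `session_gap_ms`). Durations from the
#' trailing `window_days` local days ending at `window_end_date` are binned
#' with width `bin_ms`; the statistic is the midpoint of the modal bin
#' (lowest bin wins ties). `NA` with fewer than `min_taps` durations.
#'
#' @param taps data.frame (ts, in_game), time-ordered
#' @param window_end_date last local date of the window
#' @param tz_offset_hrs cohort UTC offset
#' @param window_days trailing window length, days
#' @param session_gap_ms gap splitting typing sessions, milliseconds
#' @param bin_ms histogram bin width, milliseconds
#' @param min_taps minimum number of durations for a non-null statistic
#' @return list: `mode_intertap_dist` (ms, or `NA`), `n_taps_in_window`
#' @export
mode_intertap <- function(taps, window_end_date, tz_offset_hrs = 8,
                          window_days = 7, session_gap_ms = 5000,
                          bin_ms = 50, min_taps = 30) {
  end <- as.Date(window_end_date)
  lo <- end - (window_days - 1)
  if (nrow(taps)) {
    d <- local_date(taps$ts, tz_offset_hrs)
    tt <- taps[!taps$in_game & d >= lo & d <= end, , drop = FALSE]
  } else tt <- taps
  if (nrow(tt) < 2)
    return(list(mode_intertap_dist = NA_real_, n_taps_in_window = 0L))
  gaps <- diff(sort(tt$ts)) * 1000
  # epoch-scale doubles resolve to ~4e-4 ms; round to 1 microsecond so an
  # exact-millisecond gap cannot straddle a bin edge
  gaps <- round(gaps, 3)
  gaps <- gaps[gaps > 0 & gaps <= session_gap_ms]
  if (length(gaps) < min_taps)
    return(list(mode_intertap_dist = NA_real_,
                n_taps_in_window = length(gaps)))
  bin <- floor(gaps / bin_ms)
  counts <- tabulate(bin + 1L)
  modal <- which.max(counts) - 1L
  list(mode_intertap_dist = (modal + 0.5) * bin_ms,
       n_taps_in_window = length(gaps))
}

#' Messages sent on one local date
#'
#' Counts `direction == "sent"` events, both channels pooled. Returns 0 when
#' the phone reported that day (any event, or `phone_present`), but `NA` when
#' the phone was entirely absent — the zero-vs-missing distinction that keeps
#' non-compliance from masquerading as social withdrawal.
#'
#' @param msgs data.frame (ts, channel, direction)
#' @param date local calendar date
#' @param tz_offset_hrs cohort UTC offset
#' @param phone_present did the ambient-light stream report this day?
#' @return count, or `NA`
#' @export
messages_sent <- function(msgs, date, tz_offset_hrs = 8,
                          phone_present = TRUE) {
  if (nrow(msgs)) {
    day <- msgs[local_date(msgs$ts, tz_offset_hrs) == as.Date(date), ,
                drop = FALSE]
  } else day <- msgs
  if (!nrow(day)) {
    return(if (phone_present) 0L else NA_integer_)
  }
  sum(day$direction == "sent")
}

# sessionize a full power-state log into [on, off) intervals; consecutive
# screen_on events restart the session (the earlier one is capped), and an
# unterminated trailing session is capped at max_session_hrs
power_sessions <- function(power, max_session_hrs = 4) {
  cap <- max_session_hrs * SECS_PER_HOUR
  on <- NA_real_
  starts <- numeric(0); ends <- numeric(0)
  for (i in seq_len(nrow(power))) {
    ts <- power$ts[i]; state <- power$state[i]
    if (state == "screen_on") {
      if (!is.na(on)) {            # restart: cap the dangling session
        starts <- c(starts, on); ends <- c(ends, min(on + cap, ts))
      }
      on <- ts
    } else if (state == "screen_off" && !is.na(on)) {
      starts <- c(starts, on); ends <- c(ends, max(ts, on))
      on <- NA_real_
    }
  }
  if (!is.na(on)) {
    starts <- c(starts, on); ends <- c(ends, on + cap)
  }
  data.frame(start = starts, end = ends)
}

#' Screen time on one local date
#'
#' Matches screen_on/screen_off pairs into sessions over the whole log, then
#' sums the portion of each session intersecting the local date, so a session
#' crossing midnight is split between the adjacent dates. Unterminated
#' sessions are capped at `max_session_hrs`.
#'
#' @param power data.frame (ts, state), time-ordered
#' @param date local calendar date
#' @param tz_offset_hrs cohort UTC offset
#' @param max_session_hrs cap for unterminated sessions, hours
#' @param phone_present did the ambient-light stream report this day?
#' @return hours, or `NA` when the day has no sessions, no events and no
#'   phone presence
#' @export
screen_time <- function(power, date, tz_offset_hrs = 8, max_session_hrs = 4,
                        phone_present = TRUE) {
  date <- as.Date(date)
  day_start <- local_midnight_utc(date, tz_offset_hrs)
  day_end <- day_start + SECS_PER_DAY
  total <- 0
  if (nrow(power)) {
    ses <- power_sessions(power, max_session_hrs)
    if (nrow(ses))
      total <- sum(interval_overlap(ses$start, ses$end, day_start, day_end)) /
        SECS_PER_HOUR
  }
  if (total == 0) {
    ev_today <- nrow(power) &&
      any(local_date(power$ts, tz_offset_hrs) == date)
    if (!ev_today && !phone_present) return(NA_real_)
  }
  total
}

#' All daily digital measures for one participant
#'
#' Runs every extractor per post-baseline local date. Wearable fields are
#' naturally `NA` on days the device was not worn (no segments / samples /
#' step record); phone count features distinguish 0 (phone present, nothing
#' sent) from `NA` (phone absent, proxied by the ambient-light stream).
#'
#' @param bundle a `sensor_bundle`
#' @param max_accuracy_m,min_displacement_m,max_speed_kmh GPS filter, see
#'   [distance_travelled()]
#' @param session_gap_ms,bin_ms,min_taps,window_days intertap parameters, see
#'   [mode_intertap()]
#' @param max_session_hrs screen-session cap, see [screen_time()]
#' @return list with `daily` (one row per local date: participant_id,
#'   local_date and the eleven per-day measures) and `intertap` (one row per
#'   date: mode_intertap_dist, n_taps_in_window)
#' @export
daily_measures <- function(bundle,
                           max_accuracy_m = 100, min_displacement_m = 30,
                           max_speed_kmh = 150,
                           session_gap_ms = 5000, bin_ms = 50, min_taps = 30,
                           window_days = 7, max_session_hrs = 4) {
  stopifnot(inherits(bundle, "sensor_bundle"))
  off <- bundle$tz_offset_hrs
  dates <- bundle$baseline_date + seq_len(bundle$n_days)
  day_hours <- function(d) 24L * d + 0:23
  rows <- vector("list", length(dates))
  itaps <- vector("list", length(dates))
  for (d in seq_along(dates)) {
    date <- dates[d]
    phone_present <- any(bundle$light_hours %in% day_hours(d))
    sl <- sleep_measures_for_day(bundle$sleep, bundle$stages, date, off)
    hrv <- hr_asleep(bundle$hr, bundle$sleep, bundle$stages, date, off)
    stp <- if (nrow(bundle$steps)) {
      m <- bundle$steps$steps[bundle$steps$date == date]
      if (length(m)) m[1] else NA_integer_
    } else NA_integer_
    dist <- distance_travelled(bundle$gps, date, off, max_accuracy_m,
                               min_displacement_m, max_speed_kmh)
    msg <- messages_sent(bundle$msgs, date, off, phone_present)
    scr <- screen_time(bundle$power, date, off, max_session_hrs,
                       phone_present)
    it <- mode_intertap(bundle$taps, date, off, window_days, session_gap_ms,
                        bin_ms, min_taps)
    rows[[d]] <- data.frame(
      participant_id = bundle$participant_id, local_date = date,
      total_sleep_hrs = sl$total_sleep_hrs,
      sleep_hrs_wake = sl$sleep_hrs_wake,
      sleep_hrs_light = sl$sleep_hrs_light,
      sleep_hrs_deep = sl$sleep_hrs_deep,
      sleep_hrs_rem = sl$sleep_hrs_rem,
      sleep_efficiency = sl$sleep_efficiency,
      hr_asleep = hrv, total_steps = stp, dist_travelled = dist,
      total_msg_sent = msg, screen_time = scr,
      stringsAsFactors = FALSE)
    itaps[[d]] <- data.frame(
      participant_id = bundle$participant_id, local_date = date,
      mode_intertap_dist = it$mode_intertap_dist,
      n_taps_in_window = it$n_taps_in_window,
      stringsAsFactors = FALSE)
  }
  list(daily = do.call(rbind, rows), intertap = do.call(rbind, itaps))
}

#' Daily measures for a whole cohort
#'
#' @param bundles list of `sensor_bundle` objects
#' @param ... passed to [daily_measures()]
#' @return list with stacked `daily` and `intertap` data.frames
#' @export
extract_features <- function(bundles, ...) {
  out <- lapply(bundles, daily_measures, ...)
  list(daily = do.call(rbind, lapply(out, `[[`, "daily")),
       intertap = do.call(rbind, lapply(out, `[[`, "intertap")))
}
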