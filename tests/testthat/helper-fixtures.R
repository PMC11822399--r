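# Shared fixtures: everything is built in code at test time.

TZ_OFF <- 8
BASE <- as.Date("2021-03-01")

# UTC seconds of local midnight starting `date` (cohort offset +8)
lmid <- function(date, off = TZ_OFF) as.numeric(as.Date(date)) * 86400 - off * 3600

# UTC seconds of local clock time `hh` (fractional hours) on `date`
lts <- function(date, hh, off = TZ_OFF) lmid(date, off) + hh * 3600

# one sleep segment with a single bout per stage, in the given order
make_segment <- function(start, stage_hours, seg_id = 1L, is_main = TRUE,
                         efficiency = NA_real_) {
  durs <- stage_hours[stage_hours > 0]
  bounds <- start + cumsum(c(0, durs)) * 3600
  list(
    sleep = data.frame(seg_id = seg_id, start = start,
                       end = start + sum(stage_hours) * 3600,
                       is_main = is_main, efficiency = efficiency),
    stages = data.frame(seg_id = seg_id, stage = names(durs),
                        start = bounds[-length(bounds)], end = bounds[-1],
                        stringsAsFactors = FALSE)
  )
}

bind_segments <- function(...) {
  segs <- list(...)
  list(sleep = do.call(rbind, lapply(segs, `[[`, "sleep")),
       stages = do.call(rbind, lapply(segs, `[[`, "stages")))
}

# minimal bundle; override individual streams as needed
make_bundle <- function(..., participant_id = "T001", baseline_date = BASE,
                        n_days = 7, tz_offset_hrs = TZ_OFF) {
  streams <- digiphen:::empty_streams()
  over <- list(...)
  for (nm in names(over)) streams[[nm]] <- over[[nm]]
  digiphen:::new_sensor_bundle(participant_id, baseline_date, n_days,
                               tz_offset_hrs, streams)
}

# small cohort memoised across test files (generation is the expensive part)
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- generate_cohort(cohort_config(n_participants = 8, seed = 202))
    cache
  }
})
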