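# Synthetic cohort generator: raw sensor streams + baseline clinical scales
# with known ground truth. All randomness flows from the config seed through
# per-participant substreams.

# truncated-normal draw via inverse CDF; sd == 0 degenerates to the mean
rtnorm <- function(n, mean, sd, lo = -Inf, hi = Inf) {
  if (sd == 0) return(pmin(pmax(rep(mean, n), lo), hi))
  plo <- pnorm(lo, mean, sd)
  phi <- pnorm(hi, mean, sd)
  u <- pmin(pmax(runif(n, plo, phi), 1e-15), 1 - 1e-15)
  # the probability clamp can step just outside [lo, hi] under extreme
  # truncation; snap back so the support contract always holds
  pmin(pmax(qnorm(u, mean, sd), lo), hi)
}

# zero-truncated normal whose *post-truncation* mean equals target_mean:
# the latent location is solved so that truncation does not inflate the
# calibrated moments (the config states the moments of the generated data)
rtnorm_target <- function(n, target_mean, sd, lo = 0) {
  if (sd == 0) return(rep(max(target_mean, lo), n))
  target <- max(target_mean, lo + 1e-3 * sd)
  tn_mean <- function(m) {
    a <- (lo - m) / sd
    # Mills ratio on the log scale to stay stable for strongly negative m
    m + sd * exp(stats::dnorm(a, log = TRUE) -
                   pnorm(a, lower.tail = FALSE, log.p = TRUE))
  }
  m <- stats::uniroot(function(m) tn_mean(m) - target,
                      lower = target - 10 * sd, upper = target,
                      extendInt = "upX", tol = 1e-8)$root
  rtnorm(n, m, sd, lo = lo)
}

rdirichlet1 <- function(alpha) {
  g <- vapply(alpha, function(a) if (a <= 0) 0 else stats::rgamma(1, a), 0)
  g / sum(g)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

STAGES <- c("wake", "light", "deep", "rem")

# Lay out stage bouts over [start, start + sum(hours)): half the wake time at
# the start, half at the end, and the asleep time as four light/deep/rem
# cycles. Boundaries are cumulative, so the tiling is exact.
tile_stages <- function(start, stage_hours) {
  stage_hours <- stage_hours[STAGES]
  w <- stage_hours[["wake"]]
  cyc <- unlist(lapply(seq_len(4), function(i)
    c(light = stage_hours[["light"]] / 4,
      deep  = stage_hours[["deep"]] / 4,
      rem   = stage_hours[["rem"]] / 4)))
  durs <- c(wake = w / 2, cyc, wake = w / 2)
  stage <- sub("[0-9]*$", "", names(durs))
  bounds <- start + cumsum(c(0, durs)) * SECS_PER_HOUR
  keep <- durs > 0
  data.frame(stage = unname(stage[keep]),
             start = unname(bounds[-length(bounds)][keep]),
             end = unname(bounds[-1][keep]),
             stringsAsFactors = FALSE)
}

#' Generate one staged sleep segment
#'
#' Draws per-night stage proportions from a Dirichlet distribution centred on
#' `stage_fractions` and tiles the time in bed with stage bouts (wake split
#' between sleep onset and final waking, the asleep time as four
#' light/deep/REM cycles). The expected hours spent in each stage equal
#' `stage_fractions * time_in_bed_hrs`.
#'
#' @param time_in_bed_hrs segment duration, hours
#' @param start segment start, seconds since epoch UTC
#' @param stage_fractions named proportions (wake, light, deep, rem) of time
#'   in bed; must sum to 1 within 1e-9
#' @param concentration Dirichlet concentration; `Inf` gives deterministic
#'   fractions
#' @param is_main main sleep segment (carries an efficiency score)?
#' @param efficiency efficiency in `[0, 1]` for the main segment, `NA`
#'   otherwise
#' @return list with `segment` (one-row data.frame: start, end, is_main,
#'   efficiency) and `stages` (data.frame stage/start/end tiling the segment)
#' @examples
#' set.seed(1)
#' night <- generate_sleep_night(8, 0, c(wake = .1, light = .6, deep = .15, rem = .15))
#' sum(night$stages$end - night$stages$start) / 3600  # == 8
#' @export
generate_sleep_night <- function(time_in_bed_hrs, start, stage_fractions,
                                 concentration = 60, is_main = TRUE,
                                 efficiency = NA_real_) {
  if (length(stage_fractions) != 4 ||
      abs(sum(stage_fractions) - 1) > 1e-9 || any(stage_fractions < 0))
    stop("stage_fractions must be 4 non-negative proportions summing to 1")
  if (is.null(names(stage_fractions)))
    names(stage_fractions) <- STAGES
  p <- if (is.infinite(concentration)) stage_fractions[STAGES] else
    setNames(rdirichlet1(concentration * stage_fractions[STAGES]), STAGES)
  stage_hours <- p * time_in_bed_hrs
  stages <- tile_stages(start, stage_hours)
  seg <- data.frame(start = start,
                    end = start + time_in_bed_hrs * SECS_PER_HOUR,
                    is_main = is_main,
                    efficiency = if (is_main) efficiency else NA_real_)
  list(segment = seg, stages = stages)
}

# asleep-hours-first variant used by the cohort generator: fixes the total
# asleep (non-wake) time and lets time in bed follow from the drawn wake share
tile_night_asleep <- function(asleep_hrs, start, stage_fractions,
                              concentration, allow_wake = TRUE) {
  p <- setNames(rdirichlet1(concentration * stage_fractions[STAGES]), STAGES)
  if (!allow_wake) {
    p[["wake"]] <- 0
    p <- p / sum(p)
  }
  asleep_share <- 1 - p[["wake"]]
  t_bed <- asleep_hrs / asleep_share
  tile_stages(start, p * t_bed)
}

empty_streams <- function() {
  list(
    hr = data.frame(ts = numeric(0), bpm = numeric(0)),
    sleep = data.frame(seg_id = integer(0), start = numeric(0),
                       end = numeric(0), is_main = logical(0),
                       efficiency = numeric(0)),
    stages = data.frame(seg_id = integer(0), stage = character(0),
                        start = numeric(0), end = numeric(0),
                        stringsAsFactors = FALSE),
    steps = data.frame(date = as.Date(character(0)), steps = integer(0)),
    gps = data.frame(ts = numeric(0), lat = numeric(0), lon = numeric(0),
                     accuracy = numeric(0)),
    taps = data.frame(ts = numeric(0), in_game = logical(0)),
    msgs = data.frame(ts = numeric(0), channel = character(0),
                      direction = character(0), stringsAsFactors = FALSE),
    power = data.frame(ts = numeric(0), state = character(0),
                       stringsAsFactors = FALSE),
    light_hours = integer(0)
  )
}

new_sensor_bundle <- function(participant_id, baseline_date, n_days,
                              tz_offset_hrs, streams) {
  structure(c(list(participant_id = participant_id,
                   baseline_date = as.Date(baseline_date),
                   n_days = n_days,
                   tz_offset_hrs = tz_offset_hrs),
              streams),
            class = "sensor_bundle")
}

#' @export
print.sensor_bundle <- function(x, ...) {
  cat(sprintf("<sensor_bundle> %s, baseline %s (+%d days, UTC%+d)\n",
              x$participant_id, format(x$baseline_date), x$n_days,
              x$tz_offset_hrs))
  cat(sprintf("  hr %d | sleep segs %d | step days %d | gps %d | taps %d | msgs %d | power %d | light hrs %d\n",
              nrow(x$hr), nrow(x$sleep), nrow(x$steps), nrow(x$gps),
              nrow(x$taps), nrow(x$msgs), nrow(x$power),
              length(x$light_hours)))
  invisible(x)
}

#' Generate a synthetic passive-sensing cohort
#'
#' Produces raw sensor streams and a baseline clinical-scales table for
#' `config$n_participants` participants over `config$n_days` post-baseline
#' days, together with the ground truth (per-participant latent traits and
#' stream parameters) needed to verify the downstream pipeline.
#'
#' Each participant carries one standard-normal latent trait per digital
#' measure. The trait shifts the participant-level mean of that measure
#' (between/within variance split `config$between_var_frac`), and, for every
#' entry of `config$latent_effects`, also drives the linked clinical scale
#' with the planted standardized effect via a bivariate-normal construction,
#' so the population correlation between scale and participant-level digital
#' mean equals the planted effect.
#'
#' Wearable wear and smartphone presence are decided independently per
#' hour-window (the granularity of the completeness statistic); heart rate is
#' sampled once per minute during sleep and every `hr_wake_cadence_min`
#' minutes otherwise, only while worn. Sleep nights are staged segments whose
#' asleep total keeps the configured moments even when a nap splits off part
#' of it. Phone streams (GPS, taps, messages, screen power) are emitted only
#' during phone-present hours/days, mirroring how real compliance gaps
#' produce missing daily values.
#'
#' @param config a [cohort_config()]
#' @return list with components `bundles` (list of `sensor_bundle`),
#'   `profiles` (data.frame of `ClinicalProfile` rows: participant_id, age,
#'   uses_study_phone and the fifteen scale scores) and `truth` (list:
#'   `participants` data.frame of planted per-participant parameters,
#'   `effects`, `config`)
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 3, seed = 7))
#' names(cohort)
#' cohort$bundles[[1]]
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_config(config)
  cfg <- config
  n <- cfg$n_participants
  baseline <- as.Date("2021-03-01")  # arbitrary fixed anchor; dates are relative

  set.seed(cfg$seed)
  n_study <- round(n * cfg$study_phone_fraction)
  study <- sample(rep(c(TRUE, FALSE), c(n_study, n - n_study)))
  pseeds <- sample.int(.Machine$integer.max - 1L, n, replace = TRUE)

  bundles <- vector("list", n)
  profiles <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    out <- generate_participant(sprintf("P%03d", i), baseline, cfg,
                                pseeds[i], study[i])
    bundles[[i]] <- out$bundle
    profiles[[i]] <- out$profile
    truth[[i]] <- out$truth
  }
  effects <- if (length(cfg$latent_effects)) {
    data.frame(scale = names(cfg$latent_effects),
               measure = vapply(cfg$latent_effects, `[[`, "", "measure"),
               effect = vapply(cfg$latent_effects, function(e)
                 as.numeric(e$effect), 0),
               row.names = NULL, stringsAsFactors = FALSE)
  } else {
    data.frame(scale = character(0), measure = character(0),
               effect = numeric(0), stringsAsFactors = FALSE)
  }
  list(bundles = bundles,
       profiles = do.call(rbind, profiles),
       truth = list(participants = do.call(rbind, truth),
                    effects = effects,
                    config = cfg))
}

generate_participant <- function(pid, baseline, cfg, pseed, uses_study_phone) {
  set.seed(pseed)
  nd <- cfg$n_days
  off <- cfg$tz_offset_hrs
  H <- 24L * (nd + 1L)          # hour windows covering baseline day .. day nd
  base_mid <- local_midnight_utc(baseline, off)
  bf <- cfg$between_var_frac
  sb <- sqrt(bf); sw <- sqrt(1 - bf)

  measures <- names(measure_sources())
  z <- setNames(rnorm(length(measures)), measures)

  ## ---- clinical profile ------------------------------------------------
  scales <- cfg$clinical_scales
  linked <- cfg$latent_effects
  score <- numeric(nrow(scales))
  for (k in seq_len(nrow(scales))) {
    s <- scales$scale[k]
    zs <- if (s %in% names(linked)) {
      e <- linked[[s]]
      e$effect * z[[e$measure]] + sqrt(1 - e$effect^2) * rnorm(1)
    } else rnorm(1)
    score[k] <- clamp(scales$mean[k] + scales$sd[k] * zs,
                      scales$lo[k], scales$hi[k])
  }
  age <- clamp(rnorm(1, cfg$age_mean, cfg$age_sd), 21, 65)
  profile <- data.frame(participant_id = pid, age = age,
                        uses_study_phone = uses_study_phone,
                        as.list(setNames(score, scales$scale)),
                        stringsAsFactors = FALSE)

  ## ---- presence --------------------------------------------------------
  wear <- rbinom(H, 1, cfg$wearable_presence_prob)
  p_phone <- if (uses_study_phone) cfg$phone_presence_prob_study else
    cfg$phone_presence_prob_own
  light <- rbinom(H, 1, p_phone)
  light_hours <- which(light == 1L) - 1L

  worn_hour <- function(ts) {
    h <- floor((ts - base_mid) / SECS_PER_HOUR)
    ok <- h >= 0 & h < H
    ok & wear[pmin(pmax(h, 0), H - 1) + 1] == 1L
  }
  present_hours_of_day <- function(d, from = 0, to = 24) {
    h <- 24L * d + seq.int(from, to - 1L)
    h <- h[h < H]
    h[light[h + 1] == 1L]
  }

  ## ---- sleep -----------------------------------------------------------
  p_sleep <- clamp(cfg$sleep_mean_hrs + cfg$sleep_sd_hrs * sb *
                     z[["total_sleep_hrs"]], 1, 15)
  p_eff <- clamp(cfg$efficiency_mean + cfg$efficiency_sd * sb *
                   z[["sleep_efficiency"]], 0.5, 0.999)
  p_hr <- cfg$hr_asleep_mean + cfg$hr_asleep_sd * z[["hr_asleep"]]

  seg_rows <- list(); stage_rows <- list(); seg_id <- 0L
  hr_chunks <- list()
  for (d in seq_len(nd)) {
    asleep <- rtnorm(1, p_sleep, cfg$sleep_sd_hrs * sw, lo = 0.5, hi = 16)
    nap_asleep <- 0
    if (runif(1) < cfg$nap_prob) {
      nap_asleep <- asleep * runif(1, 0.05, 0.15)
    }
    main_asleep <- asleep - nap_asleep

    bed_local <- clamp(rnorm(1, 23.5, 0.75), 21.5, 25.5)
    start_main <- local_midnight_utc(baseline + d - 1, off) +
      bed_local * SECS_PER_HOUR
    stages_main <- tile_night_asleep(main_asleep, start_main,
                                     cfg$stage_fractions,
                                     cfg$stage_concentration)
    end_main <- max(stages_main$end)
    eff <- if (cfg$efficiency_sd == 0) cfg$efficiency_mean else
      rtnorm(1, p_eff, cfg$efficiency_sd * sw, lo = 0, hi = 1)

    segs_today <- list(list(stages = stages_main, is_main = TRUE, eff = eff))

    if (nap_asleep > 0) {
      end_main_local <- (end_main - local_midnight_utc(baseline + d, off)) /
        SECS_PER_HOUR
      nap_start_local <- max(13.5, end_main_local + 0.5) + runif(1, 0, 2)
      if (nap_start_local < 21) {
        start_nap <- local_midnight_utc(baseline + d, off) +
          nap_start_local * SECS_PER_HOUR
        stages_nap <- tile_night_asleep(nap_asleep, start_nap,
                                        cfg$stage_fractions,
                                        cfg$stage_concentration,
                                        allow_wake = FALSE)
        segs_today <- c(segs_today,
                        list(list(stages = stages_nap, is_main = FALSE,
                                  eff = NA_real_)))
      }
    }

    for (sg in segs_today) {
      st <- min(sg$stages$start); en <- max(sg$stages$end)
      hrs <- seq.int(floor((st - base_mid) / SECS_PER_HOUR),
                     floor((en - 1 - base_mid) / SECS_PER_HOUR))
      hrs <- hrs[hrs >= 0 & hrs < H]
      recorded <- length(hrs) > 0 && mean(wear[hrs + 1]) >= 0.5
      if (!recorded) next
      seg_id <- seg_id + 1L
      seg_rows[[seg_id]] <- data.frame(seg_id = seg_id, start = st, end = en,
                                       is_main = sg$is_main,
                                       efficiency = sg$eff)
      stage_rows[[seg_id]] <- cbind(seg_id = seg_id, sg$stages)

      # minute-level HR inside the segment, worn hours only
      tmin <- seq(ceiling(st / 60) * 60, en - 1, by = 60)
      if (length(tmin)) {
        idx <- findInterval(tmin, sg$stages$start)
        stage <- sg$stages$stage[pmax(idx, 1)]
        night_hr <- p_hr + rnorm(1, 0, cfg$hr_night_sd)
        bpm <- night_hr + ifelse(stage == "wake", 8, 0) +
          rnorm(length(tmin), 0, cfg$hr_within_sd)
        keep <- worn_hour(tmin)
        if (any(keep))
          hr_chunks[[length(hr_chunks) + 1L]] <-
            list(ts = tmin[keep], bpm = clamp(bpm[keep], 25, 250))
      }
    }
  }
  sleep <- if (seg_id) do.call(rbind, seg_rows) else empty_streams()$sleep
  stages <- if (seg_id) do.call(rbind, stage_rows) else empty_streams()$stages

  ## ---- daytime HR (completeness driver) --------------------------------
  worn_idx <- which(wear == 1L) - 1L
  if (length(worn_idx)) {
    cad <- cfg$hr_wake_cadence_min * 60
    tday <- as.vector(outer(seq(30, SECS_PER_HOUR - 1, by = cad),
                            base_mid + worn_idx * SECS_PER_HOUR, `+`))
    tday <- sort(tday)
    if (seg_id) {
      ord <- order(sleep$start)
      sst <- sleep$start[ord]; sen <- sleep$end[ord]
      j <- findInterval(tday, sst)
      inseg <- j > 0 & tday < sen[pmax(j, 1)]
      tday <- tday[!inseg]
    }
    if (length(tday)) {
      hloc <- ((tday + off * SECS_PER_HOUR) %% SECS_PER_DAY) / SECS_PER_HOUR
      bpm <- p_hr + 12 + 5 * sin(2 * pi * (hloc - 15) / 24) +
        rnorm(length(tday), 0, 4)
      hr_chunks[[length(hr_chunks) + 1L]] <-
        list(ts = tday, bpm = clamp(bpm, 25, 250))
    }
  }
  hr <- if (length(hr_chunks)) {
    out <- data.frame(ts = unlist(lapply(hr_chunks, `[[`, "ts")),
                      bpm = unlist(lapply(hr_chunks, `[[`, "bpm")))
    out[order(out$ts), , drop = FALSE]
  } else empty_streams()$hr

  ## ---- steps -----------------------------------------------------------
  p_steps <- cfg$steps_mean + cfg$steps_sd * sb * z[["total_steps"]]
  step_rows <- list()
  for (d in seq_len(nd)) {
    hrs <- 24L * d + 0:23
    if (!any(wear[hrs + 1] == 1L)) next   # wearable absent all day
    v <- rtnorm_target(1, p_steps, cfg$steps_sd * sw, lo = 0)
    step_rows[[length(step_rows) + 1L]] <-
      data.frame(date = baseline + d, steps = as.integer(round(v)))
  }
  steps <- if (length(step_rows)) do.call(rbind, step_rows) else
    empty_streams()$steps

  ## ---- GPS mobility ----------------------------------------------------
  dl <- cfg$distance_lognormal_params
  mu_i <- dl[[1]] + dl[[2]] * sb * z[["dist_travelled"]]
  lat0 <- 1.35; lon0 <- 103.80
  gps_rows <- list()
  for (d in seq_len(nd)) {
    ph <- present_hours_of_day(d, 9, 21)
    if (!length(ph)) next
    D <- min(exp(mu_i + dl[[2]] * sw * rnorm(1)), 300)   # km over 12 h
    bearing <- runif(1, 0, 2 * pi)
    speed <- D / 12                                       # km/h
    t0 <- base_mid + 24 * d * SECS_PER_HOUR + 9 * SECS_PER_HOUR
    ts <- as.vector(outer(seq(0, SECS_PER_HOUR - 1, by = cfg$gps_cadence_min * 60),
                          base_mid + ph * SECS_PER_HOUR, `+`))
    ts <- sort(ts)
    s_km <- speed * (ts - t0) / SECS_PER_HOUR
    lat <- lat0 + s_km * cos(bearing) / 110.574
    lon <- lon0 + s_km * sin(bearing) / (111.320 * cos(lat0 * pi / 180))
    acc <- runif(length(ts), 5, 60)
    bad <- runif(length(ts)) < 0.05
    acc[bad] <- runif(sum(bad), 150, 400)
    gps_rows[[length(gps_rows) + 1L]] <-
      list(ts = ts, lat = lat, lon = lon, accuracy = acc)
  }
  gps <- if (length(gps_rows)) {
    data.frame(ts = unlist(lapply(gps_rows, `[[`, "ts")),
               lat = unlist(lapply(gps_rows, `[[`, "lat")),
               lon = unlist(lapply(gps_rows, `[[`, "lon")),
               accuracy = unlist(lapply(gps_rows, `[[`, "accuracy")))
  } else empty_streams()$gps

  ## ---- touchscreen taps ------------------------------------------------
  s_t <- cfg$intertap_sigma
  mode_i <- cfg$intertap_mode_ms * exp(0.6 * z[["mode_intertap_dist"]] - 0.18)
  mu_tap <- log(mode_i) + s_t^2    # lognormal mode = exp(mu - sigma^2)
  tap_rows <- list()
  for (d in seq_len(nd)) {
    ph <- present_hours_of_day(d, 8, 23)
    if (!length(ph)) next
    nsess <- rpois(1, cfg$tap_sessions_per_day)
    if (nsess == 0) next
    for (ss in seq_len(nsess)) {
      h <- ph[sample.int(length(ph), 1)]
      t0 <- base_mid + h * SECS_PER_HOUR + runif(1, 0, 3000)
      ntap <- 8 + rpois(1, 12)
      gaps <- pmin(stats::rlnorm(ntap - 1, mu_tap, s_t), 4000) / 1000
      ts <- t0 + cumsum(c(0, gaps))
      tap_rows[[length(tap_rows) + 1L]] <-
        list(ts = ts, in_game = rep(runif(1) < 0.1, ntap))
    }
  }
  taps <- if (length(tap_rows)) {
    out <- data.frame(ts = unlist(lapply(tap_rows, `[[`, "ts")),
                      in_game = unlist(lapply(tap_rows, `[[`, "in_game")))
    out[order(out$ts), , drop = FALSE]
  } else empty_streams()$taps

  ## ---- messages --------------------------------------------------------
  lam <- cfg$msgs_mean * exp(cfg$msgs_sigma * z[["total_msg_sent"]] -
                               cfg$msgs_sigma^2 / 2)
  msg_rows <- list()
  for (d in seq_len(nd)) {
    ph <- present_hours_of_day(d, 8, 23)
    if (!length(ph)) next
    n_sent <- rpois(1, lam)
    n_recv <- rpois(1, lam * 1.3)
    ntot <- n_sent + n_recv
    if (ntot == 0) next
    ts <- base_mid + ph[sample.int(length(ph), ntot, replace = TRUE)] *
      SECS_PER_HOUR + runif(ntot, 0, SECS_PER_HOUR)
    msg_rows[[length(msg_rows) + 1L]] <- list(
      ts = ts,
      channel = sample(c("carrier", "whatsapp"), ntot, replace = TRUE,
                       prob = c(0.3, 0.7)),
      direction = rep(c("sent", "received"), c(n_sent, n_recv)))
  }
  msgs <- if (length(msg_rows)) {
    out <- data.frame(
      ts = unlist(lapply(msg_rows, `[[`, "ts")),
      channel = unlist(lapply(msg_rows, `[[`, "channel")),
      direction = unlist(lapply(msg_rows, `[[`, "direction")),
      stringsAsFactors = FALSE)
    out[order(out$ts), , drop = FALSE]
  } else empty_streams()$msgs

  ## ---- screen power events ---------------------------------------------
  p_scr <- cfg$screen_hrs_mean + cfg$screen_hrs_sd * sb * z[["screen_time"]]
  pow_rows <- list()
  for (d in seq_len(nd)) {
    hrs <- 24L * d + 0:23
    hrs <- hrs[hrs < H]
    if (!any(light[hrs + 1] == 1L)) next   # phone absent all day
    S <- min(rtnorm_target(1, p_scr, cfg$screen_hrs_sd * sw, lo = 0), 20)
    k <- max(1L, rpois(1, cfg$screen_sessions_per_day))
    durs <- S * rdirichlet1(rep(1, k))
    gapsh <- (23 - S) * rdirichlet1(rep(1, k + 1))
    day0 <- base_mid + 24 * d * SECS_PER_HOUR + 0.5 * SECS_PER_HOUR
    t <- day0
    for (j in seq_len(k)) {
      t <- t + gapsh[j] * SECS_PER_HOUR
      if (durs[j] > 0) {
        pow_rows[[length(pow_rows) + 1L]] <-
          list(ts = c(t, t + durs[j] * SECS_PER_HOUR),
               state = c("screen_on", "screen_off"))
      }
      t <- t + durs[j] * SECS_PER_HOUR
    }
  }
  power <- if (length(pow_rows)) {
    out <- data.frame(ts = unlist(lapply(pow_rows, `[[`, "ts")),
                      state = unlist(lapply(pow_rows, `[[`, "state")),
                      stringsAsFactors = FALSE)
    out[order(out$ts), , drop = FALSE]
  } else empty_streams()$power

  streams <- list(hr = hr, sleep = sleep, stages = stages, steps = steps,
                  gps = gps, taps = taps, msgs = msgs, power = power,
                  light_hours = light_hours)
  bundle <- new_sensor_bundle(pid, baseline, nd, off, streams)

  truth <- data.frame(participant_id = pid,
                      uses_study_phone = uses_study_phone,
                      p_sleep_mean = p_sleep, p_eff_mean = p_eff,
                      p_hr_mean = p_hr, p_steps_mean = p_steps,
                      p_screen_mean = p_scr, msg_rate = lam,
                      dist_log_mu = mu_i, intertap_mode = mode_i,
                      as.list(setNames(z, paste0("z_", measures))),
                      stringsAsFactors = FALSE)
  list(bundle = bundle, profile = profile, truth = truth)
}
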