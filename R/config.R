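#' Default clinical-scale specification
#'
#' Population mean, SD and admissible instrument range for each baseline
#' clinical scale carried by a [ClinicalProfile][generate_cohort]. Scores are
#' drawn from a Gaussian with these moments and truncated to the instrument
#' range; the defaults emulate a community sample of recently discharged,
#' mildly ill outpatients with schizophrenia spectrum disorders.
#'
#' Ranges follow the instruments: PANSS items score 1-7 (total 30-210; the
#' five factors use the consensus factor structure), BNSS items 0-6,
#' CDSS items 0-3 (total 0-27), SOFAS 0-100. The BACS composite is an
#' unbounded z score.
#'
#' @return data.frame with columns `scale`, `mean`, `sd`, `lo`, `hi`
#' @export
clinical_scale_defaults <- function() {
  df <- data.frame(
    scale = c("panss_total", "panss_pos", "panss_neg", "panss_cogdis",
              "panss_depanx", "panss_hos",
              "bnss_total", "bnss_anhedonia", "bnss_asociality",
              "bnss_avolition", "bnss_blunted", "bnss_alogia",
              "cdss_total", "sofas", "bacs_composite"),
    mean = c(51.11, 8.49, 13.20, 10.55, 8.85, 5.40,
             20.90, 5.51, 3.34, 3.30, 5.77, 2.82,
             12.31, 53.96, -1.31),
    sd   = c(9.97, 3.82, 4.08, 2.50, 3.43, 1.89,
             9.30, 2.76, 1.55, 1.89, 3.89, 2.61,
             3.55, 11.85, 1.36),
    lo   = c(30, 4, 6, 3, 4, 4,
             0, 0, 0, 0, 0, 0,
             0, 0, -Inf),
    hi   = c(210, 28, 42, 21, 28, 28,
             78, 18, 12, 12, 18, 12,
             27, 100, Inf),
    stringsAsFactors = FALSE
  )
  df
}

#' Measure names and sources
#'
#' The twelve daily digital measures, in canonical column order, and which
#' device each comes from. Phone-derived markers receive the study-phone
#' covariate terms in the association screen.
#'
#' @return named character vector: names are measure names, values are
#'   `"wearable"` or `"phone"`
#' @export
measure_sources <- function() {
  c(total_sleep_hrs = "wearable", sleep_hrs_wake = "wearable",
    sleep_hrs_light = "wearable", sleep_hrs_deep = "wearable",
    sleep_hrs_rem = "wearable", sleep_efficiency = "wearable",
    hr_asleep = "wearable", total_steps = "wearable",
    dist_travelled = "phone", mode_intertap_dist = "phone",
    total_msg_sent = "phone", screen_time = "phone")
}

#' Clinical measures entering the association screen, in heat-map row order
#'
#' SOFAS enters inverted (`inv_sofas_rating` = 100 - SOFAS) and the BACS
#' composite negated (`neg_bacs_comp`), so that higher always means worse.
#'
#' @return character vector of analysis-variable names
#' @export
clinical_measures <- function() {
  c("panss_total", "panss_pos", "panss_neg", "panss_cogdis",
    "panss_depanx", "panss_hos",
    "bnss_total", "bnss_anhedonia", "bnss_asociality",
    "bnss_avolition", "bnss_blunted", "bnss_alogia",
    "cdss_total", "inv_sofas_rating", "neg_bacs_comp")
}

#' Build (and validate) a cohort simulation configuration
#'
#' Returns a `cohort_config` object holding every tunable parameter of the
#' synthetic cohort. Defaults are calibrated so that the full pipeline
#' reproduces the cohort summary statistics of a 99-participant, one-week
#' psychosis passive-sensing deployment: hourly wearable presence 0.91,
#' smartphone presence 0.91 (study phone) / 0.77 (own phone), nightly sleep
#' 8.76 (SD 2.13) h, main-segment efficiency 0.93 (SD 0.03), sleeping heart
#' rate 69.94 (SD 10.06) bpm, daily steps 9186.91 (SD 5413.21), and daily
#' screen time 4.74 (SD 3.64) h.
#'
#' @param n_participants number of participants
#' @param n_days post-baseline days simulated and analysed (default 7)
#' @param seed integer master seed; all randomness flows from it through
#'   per-participant substreams
#' @param wearable_presence_prob probability that any given hour-window has
#'   the wearable worn (and hence >= 1 heart-rate sample)
#' @param phone_presence_prob_own,phone_presence_prob_study hourly smartphone
#'   presence probability (ambient-light samples) for own-phone and
#'   study-phone participants
#' @param study_phone_fraction fraction of the cohort using a study-provided
#'   phone; assignment is exact (`round(n * fraction)` participants)
#' @param sleep_mean_hrs,sleep_sd_hrs moments of total daily asleep hours
#'   (naps included, wake stage excluded)
#' @param stage_fractions named numeric (wake, light, deep, rem), expected
#'   fractions of time in bed per sleep stage; must sum to 1
#' @param stage_concentration Dirichlet concentration controlling night-to-
#'   night jitter of stage fractions (larger = less jitter)
#' @param efficiency_mean,efficiency_sd moments of main-segment sleep
#'   efficiency (truncated to `[0, 1]`)
#' @param nap_prob probability a given day includes a nap; the nap's asleep
#'   time is carved out of that day's total so daily asleep hours keep their
#'   configured moments
#' @param hr_asleep_mean,hr_asleep_sd participant-level moments of sleeping
#'   heart rate (bpm); `hr_within_sd` is the sample-level SD around the
#'   nightly mean
#' @param hr_night_sd night-to-night SD of the nightly mean heart rate
#' @param hr_within_sd minute-sample SD around the nightly mean (bpm)
#' @param hr_wake_cadence_min daytime heart-rate sampling cadence, minutes
#'   (sleep is always sampled at 1/min)
#' @param steps_mean,steps_sd moments of daily step totals (zero-truncated)
#' @param distance_lognormal_params numeric `(mu, sigma)` of log daily
#'   distance travelled in km
#' @param gps_cadence_min GPS fix cadence while the phone is present, minutes
#' @param intertap_mode_ms modal intertap interval, milliseconds
#' @param intertap_sigma lognormal shape of intertap intervals
#' @param tap_sessions_per_day mean number of typing sessions per day
#' @param msgs_mean mean daily messages sent (lognormal-Poisson mixture, so
#'   the marginal distribution is right-skewed)
#' @param msgs_sigma lognormal shape of the participant-level message rate
#' @param screen_hrs_mean,screen_hrs_sd moments of daily screen-on hours
#'   (zero-truncated)
#' @param screen_sessions_per_day mean number of screen sessions per day
#' @param age_mean,age_sd cohort age moments, years
#' @param between_var_frac fraction of each daily quantity's total variance
#'   attributed to stable between-participant differences (the rest is
#'   day-to-day); the weekly markers average over days, so a high value keeps
#'   marker SDs close to the configured daily SDs
#' @param tz_offset_hrs fixed UTC offset defining local days (default +8)
#' @param clinical_scales data.frame as [clinical_scale_defaults()]
#' @param latent_effects named list mapping a clinical-scale name to
#'   `list(measure = <digital measure>, effect = <standardized effect>)`;
#'   the participant-level trait driving that measure's mean also drives the
#'   scale, with correlation `effect`
#'
#' @return object of class `cohort_config` (a validated named list)
#' @examples
#' cfg <- cohort_config(n_participants = 5, seed = 1)
#' cfg$n_days
#' @export
cohort_config <- function(n_participants = 99,
                          n_days = 7,
                          seed = 42,
                          wearable_presence_prob = 0.91,
                          phone_presence_prob_own = 0.77,
                          phone_presence_prob_study = 0.91,
                          study_phone_fraction = 39 / 99,
                          sleep_mean_hrs = 8.76,
                          sleep_sd_hrs = 2.13,
                          stage_fractions = c(wake = 0.0916, light = 0.5871,
                                              deep = 0.1358, rem = 0.1855),
                          stage_concentration = 60,
                          efficiency_mean = 0.93,
                          efficiency_sd = 0.03,
                          nap_prob = 0.15,
                          hr_asleep_mean = 69.94,
                          hr_asleep_sd = 10.06,
                          hr_night_sd = 1.0,
                          hr_within_sd = 3.0,
                          hr_wake_cadence_min = 5,
                          steps_mean = 9186.91,
                          steps_sd = 5413.21,
                          distance_lognormal_params = c(mu = 2.848, sigma = 0.971),
                          gps_cadence_min = 5,
                          intertap_mode_ms = 596.06,
                          intertap_sigma = 0.35,
                          tap_sessions_per_day = 12,
                          msgs_mean = 38.02,
                          msgs_sigma = 1.1,
                          screen_hrs_mean = 4.74,
                          screen_hrs_sd = 3.64,
                          screen_sessions_per_day = 10,
                          age_mean = 29.88,
                          age_sd = 6.72,
                          between_var_frac = 0.8,
                          tz_offset_hrs = 8,
                          clinical_scales = clinical_scale_defaults(),
                          latent_effects = list()) {
  cfg <- mget(names(formals(cohort_config)))
  class(cfg) <- "cohort_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  stop_cfg <- function(field, msg) {
    stop(sprintf("invalid cohort_config field '%s': %s", field, msg),
         call. = FALSE)
  }
  chk_prob <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop_cfg(field, "must be a probability in [0, 1]")
  }
  chk_pos <- function(field, strict = FALSE) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) ||
        (if (strict) v <= 0 else v < 0))
      stop_cfg(field, if (strict) "must be > 0" else "must be >= 0")
  }
  for (f in c("wearable_presence_prob", "phone_presence_prob_own",
              "phone_presence_prob_study", "study_phone_fraction",
              "nap_prob", "between_var_frac", "efficiency_mean"))
    chk_prob(f)
  if (!is.numeric(cfg$n_participants) || cfg$n_participants < 1)
    stop_cfg("n_participants", "must be >= 1")
  if (!is.numeric(cfg$n_days) || cfg$n_days < 1)
    stop_cfg("n_days", "must be >= 1")
  for (f in c("sleep_sd_hrs", "efficiency_sd", "hr_within_sd", "steps_sd",
              "screen_hrs_sd", "age_sd", "msgs_sigma", "intertap_sigma"))
    chk_pos(f)
  for (f in c("sleep_mean_hrs", "hr_asleep_mean", "steps_mean",
              "intertap_mode_ms", "msgs_mean", "screen_hrs_mean",
              "age_mean", "stage_concentration"))
    chk_pos(f, strict = TRUE)
  sf <- cfg$stage_fractions
  if (length(sf) != 4 || any(sf < 0) || abs(sum(sf) - 1) > 1e-9)
    stop_cfg("stage_fractions",
             "must be 4 non-negative proportions (wake, light, deep, rem) summing to 1")
  if (is.null(names(sf)) ||
      !identical(sort(names(sf)), sort(c("wake", "light", "deep", "rem"))))
    stop_cfg("stage_fractions", "must be named wake/light/deep/rem")
  le <- cfg$latent_effects
  if (length(le)) {
    if (is.null(names(le)) || any(!nzchar(names(le))))
      stop_cfg("latent_effects", "must be a named list (names = clinical scales)")
    for (nm in names(le)) {
      e <- le[[nm]]
      if (!is.list(e) || is.null(e$measure) || is.null(e$effect))
        stop_cfg("latent_effects",
                 sprintf("entry '%s' needs $measure and $effect", nm))
      if (!e$measure %in% names(measure_sources()))
        stop_cfg("latent_effects",
                 sprintf("unknown digital measure '%s'", e$measure))
      if (!nm %in% cfg$clinical_scales$scale)
        stop_cfg("latent_effects", sprintf("unknown clinical scale '%s'", nm))
      if (abs(e$effect) > 1)
        stop_cfg("latent_effects", "planted effect must lie in [-1, 1]")
    }
  }
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf(
    "<cohort_config> %d participants x %d days, seed %s\n",
    x$n_participants, x$n_days, format(x$seed)))
  cat(sprintf("  wearable presence %.2f | phone presence own %.2f / study %.2f (study frac %.2f)\n",
              x$wearable_presence_prob, x$phone_presence_prob_own,
              x$phone_presence_prob_study, x$study_phone_fraction))
  cat(sprintf("  sleep %.2f (SD %.2f) h, efficiency %.2f (SD %.2f), HR asleep %.1f bpm\n",
              x$sleep_mean_hrs, x$sleep_sd_hrs, x$efficiency_mean,
              x$efficiency_sd, x$hr_asleep_mean))
  cat(sprintf("  %d planted clinical-digital effect(s)\n", length(x$latent_effects)))
  invisible(x)
}
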