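test_that("config validation rejects bad fields by name", {
  expect_error(cohort_config(wearable_presence_prob = 1.5),
               "wearable_presence_prob")
  expect_error(cohort_config(n_days = 0), "n_days")
  expect_error(cohort_config(sleep_sd_hrs = -1), "sleep_sd_hrs")
  expect_error(cohort_config(stage_fractions = c(wake = .5, light = .5,
                                                 deep = .5, rem = .5)),
               "stage_fractions")
  expect_error(
    cohort_config(latent_effects = list(panss_neg = list(measure = "nope",
                                                         effect = 0.3))),
    "latent_effects")
  expect_error(
    cohort_config(latent_effects = list(not_a_scale = list(
      measure = "total_steps", effect = 0.3))),
    "latent_effects")
})

test_that("same config and seed reproduce the cohort exactly; seeds differ", {
  cfg <- cohort_config(n_participants = 3, seed = 77)
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a$profiles, b$profiles)
  for (i in 1:3) {
    expect_identical(a$bundles[[i]]$hr, b$bundles[[i]]$hr)
    expect_identical(a$bundles[[i]]$stages, b$bundles[[i]]$stages)
    expect_identical(a$bundles[[i]]$taps, b$bundles[[i]]$taps)
    expect_identical(a$bundles[[i]]$light_hours, b$bundles[[i]]$light_hours)
  }
  c_ <- generate_cohort(cohort_config(n_participants = 3, seed = 78))
  expect_false(identical(a$bundles[[1]]$hr, c_$bundles[[1]]$hr))
})

test_that("degenerate presence probabilities saturate the hour windows", {
  cfg <- cohort_config(n_participants = 3, seed = 5,
                       wearable_presence_prob = 1,
                       phone_presence_prob_own = 1,
                       phone_presence_prob_study = 1)
  co <- generate_cohort(cfg)
  for (b in co$bundles) {
    expect_equal(completeness_rate(b, "wearable"), 1)
    expect_equal(completeness_rate(b, "phone"), 1)
  }
})

test_that("generate_sleep_night validates fractions and honours degenerate ones", {
  expect_error(generate_sleep_night(8, 0, c(wake = .2, light = .2,
                                            deep = .2, rem = .2)),
               "summing to 1")
  set.seed(1)
  n <- generate_sleep_night(6, 0, c(wake = 0, light = 1, deep = 0, rem = 0))
  expect_true(all(n$stages$stage == "light"))
  expect_equal(sum(n$stages$end - n$stages$start), 6 * 3600)
})

test_that("expected stage hours match fractions times time in bed (Monte Carlo)", {
  fr <- c(wake = 0.1, light = 0.6, deep = 0.15, rem = 0.15)
  expected <- fr * 10
  set.seed(42)
  draws <- matrix(0, 10000, 4, dimnames = list(NULL, names(fr)))
  for (i in seq_len(nrow(draws))) {
    n <- generate_sleep_night(10, 0, fr)
    h <- tapply((n$stages$end - n$stages$start) / 3600, n$stages$stage, sum)
    draws[i, names(h)] <- h
  }
  for (s in names(fr)) {
    se <- sd(draws[, s]) / sqrt(nrow(draws))
    expect_lt(abs(mean(draws[, s]) - expected[[s]]), 2 * se + 1e-12)
  }
})

test_that("stage bouts tile every generated segment to within 1 ms", {
  set.seed(3)
  for (i in 1:200) {
    tib <- runif(1, 4, 11)
    n <- generate_sleep_night(tib, runif(1, 0, 1e9),
                              c(wake = .09, light = .59, deep = .14, rem = .18))
    expect_lt(abs(sum(n$stages$end - n$stages$start) -
                    (n$segment$end - n$segment$start)), 1e-3)
    expect_true(all(n$stages$start[-1] == n$stages$end[-nrow(n$stages)]))
  }
  co <- small_cohort()
  for (b in co$bundles) {
    by_seg <- split(b$stages, b$stages$seg_id)
    for (sid in names(by_seg)) {
      st <- by_seg[[sid]]
      seg <- b$sleep[b$sleep$seg_id == as.integer(sid), ]
      expect_lt(abs(sum(st$end - st$start) - (seg$end - seg$start)), 1e-3)
    }
  }
})

test_that("zero efficiency spread gives every main segment the configured score", {
  co <- generate_cohort(cohort_config(n_participants = 4, seed = 10,
                                      efficiency_sd = 0))
  effs <- unlist(lapply(co$bundles, function(b)
    b$sleep$efficiency[b$sleep$is_main]))
  expect_true(length(effs) > 0)
  expect_true(all(effs == 0.93))
})

test_that("all stream timestamps stay inside the bundle window", {
  co <- small_cohort()
  for (b in co$bundles) {
    lo <- lmid(b$baseline_date)
    hi <- lmid(b$baseline_date + b$n_days + 1)
    for (s in c("hr", "gps", "taps", "msgs", "power")) {
      if (nrow(b[[s]]))
        expect_true(all(b[[s]]$ts >= lo & b[[s]]$ts < hi), label = s)
    }
    if (nrow(b$sleep))
      expect_true(all(b$sleep$start >= lo & b$sleep$end < hi))
    expect_true(all(b$light_hours >= 0 &
                      b$light_hours < 24 * (b$n_days + 1)))
  }
})

test_that("clinical scores respect instrument ranges and profile schema", {
  co <- small_cohort()
  sc <- clinical_scale_defaults()
  for (k in seq_len(nrow(sc))) {
    v <- co$profiles[[sc$scale[k]]]
    expect_true(all(v >= sc$lo[k] & v <= sc$hi[k]), label = sc$scale[k])
  }
  expect_setequal(
    names(co$profiles),
    c("participant_id", "age", "uses_study_phone", sc$scale))
})
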