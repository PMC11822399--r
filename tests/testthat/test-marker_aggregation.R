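test_that("weekly_marker applies the mean rule with the 4-valid-day floor", {
  b <- BASE
  w <- weekly_marker(b + 1:7, rep(8, 7), b, "total_sleep_hrs")
  expect_equal(w$value, 8)
  expect_equal(w$n_valid_days, 7L)
  expect_equal(w$rule, "mean_of_week")

  w3 <- weekly_marker(b + 1:7, c(8, 8, 8, NA, NA, NA, NA), b,
                      "total_sleep_hrs")
  expect_true(is.na(w3$value))
  expect_equal(w3$n_valid_days, 3L)

  w4 <- weekly_marker(b + 1:4, c(7, 8, 9, 8), b, "total_sleep_hrs")
  expect_equal(w4$value, 8)
})

test_that("weekly_marker rejects rows outside the window", {
  expect_error(weekly_marker(BASE + 0:6, rep(1, 7), BASE, "total_steps"),
               "outside the observation window")
  expect_error(weekly_marker(BASE + 2:8, rep(1, 7), BASE, "total_steps"),
               "outside")
})

test_that("intertap uses last-valid with its own guard", {
  b <- BASE
  w <- weekly_marker(b + 1:7, c(500, 550, NA, 600, NA, NA, NA), b,
                     "mode_intertap_dist")
  expect_equal(w$value, 600)       # last valid, not the mean
  expect_equal(w$rule, "last_valid")
  # with the 4-day rule re-imposed, 3 valid days fail
  w2 <- weekly_marker(b + 1:7, c(500, 550, NA, 600, NA, NA, NA), b,
                      "mode_intertap_dist", intertap_min_valid = 4)
  expect_true(is.na(w2$value))
})

test_that("shifting baseline by one day swaps exactly the two boundary days", {
  all_dates <- BASE + 1:8
  win <- function(b) all_dates[all_dates > b & all_dates <= b + 7]
  w0 <- win(BASE); w1 <- win(BASE + 1)
  expect_equal(setdiff(w0, w1), as.numeric(BASE + 1))
  expect_equal(setdiff(w1, w0), as.numeric(BASE + 8))
  expect_equal(length(intersect(w0, w1)), 6L)
})

test_that("standardization is exact on the toy column and preserves nulls", {
  mk <- data.frame(participant_id = c("a", "b", "c"),
                   total_sleep_hrs = c(2, 4, 6),
                   total_steps = c(1000, NA, 3000),
                   dist_travelled = c(0, 10, 20),
                   stringsAsFactors = FALSE)
  z <- transform_and_standardize(mk, log1p_vars = "dist_travelled")
  expect_equal(z$data$total_sleep_hrs, c(-1, 0, 1))
  expect_true(is.na(z$data$total_steps[2]))
  expect_equal(mean(z$data$total_steps, na.rm = TRUE), 0)
  expect_equal(sd(z$data$total_steps, na.rm = TRUE), 1)
  # log1p applied only to the named variable, before centering
  expect_equal(z$transform_applied[["dist_travelled"]], "log1p")
  expect_equal(z$transform_applied[["total_sleep_hrs"]], "none")
  expect_equal(z$center[["dist_travelled"]], mean(log1p(c(0, 10, 20))))
  # rank preservation under log1p
  expect_equal(cor(mk$dist_travelled, log1p(mk$dist_travelled),
                   method = "spearman"), 1)
})

test_that("standardization is idempotent and rejects zero spread", {
  set.seed(2)
  mk <- data.frame(participant_id = sprintf("p%02d", 1:30),
                   total_sleep_hrs = rnorm(30, 8, 2),
                   screen_time = rexp(30), stringsAsFactors = FALSE)
  z1 <- transform_and_standardize(mk, log1p_vars = character(0))
  z2 <- transform_and_standardize(z1$data, log1p_vars = character(0))
  expect_equal(z2$data$total_sleep_hrs, z1$data$total_sleep_hrs,
               tolerance = 1e-12)
  mk$screen_time <- 5
  expect_error(transform_and_standardize(mk, log1p_vars = character(0)),
               "screen_time")
})

test_that("prepare_clinical inverts SOFAS and BACS and standardizes age", {
  set.seed(11)
  n <- 40
  prof <- data.frame(participant_id = sprintf("p%02d", 1:n),
                     age = rnorm(n, 30, 7),
                     uses_study_phone = rep(c(TRUE, FALSE), n / 2),
                     stringsAsFactors = FALSE)
  for (s in clinical_scale_defaults()$scale) prof[[s]] <- rnorm(n, 10, 3)
  prof$sofas <- rnorm(n, 54, 12)
  prof$bacs_composite <- rnorm(n, -1.3, 1.4)

  cz <- prepare_clinical(prof)
  expect_equal(cz$center[["inv_sofas_rating"]], 100 - mean(prof$sofas))
  expect_equal(cz$center[["neg_bacs_comp"]], -mean(prof$bacs_composite))
  for (v in c(clinical_measures(), "age")) {
    expect_equal(mean(cz$data[[v]]), 0, tolerance = 1e-9)
    expect_equal(sd(cz$data[[v]]), 1, tolerance = 1e-9)
  }
  # 100 - 54 = 46 before standardization
  i <- which.min(abs(prof$sofas - 54))
  expect_equal(cz$data$inv_sofas_rating[i] * cz$scale[["inv_sofas_rating"]] +
                 cz$center[["inv_sofas_rating"]], 100 - prof$sofas[i])

  prof$sofas <- 54
  expect_error(prepare_clinical(prof), "inv_sofas_rating")
})

test_that("aggregate_markers wires daily rows to the wide marker table", {
  co <- small_cohort()
  f <- extract_features(co$bundles)
  bd <- data.frame(
    participant_id = vapply(co$bundles, `[[`, "", "participant_id"),
    baseline_date = as.Date(vapply(co$bundles,
                                   function(b) format(b$baseline_date), "")),
    stringsAsFactors = FALSE)
  mk <- aggregate_markers(f$daily, f$intertap, bd)
  expect_equal(nrow(mk), length(co$bundles))
  expect_true(all(names(measure_sources()) %in% names(mk)))
  # spot-check one participant against a direct mean
  p <- mk$participant_id[1]
  dd <- f$daily[f$daily$participant_id == p, ]
  v <- dd$total_sleep_hrs[!is.na(dd$total_sleep_hrs)]
  if (length(v) >= 4)
    expect_equal(mk$total_sleep_hrs[1], mean(v))
})
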