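date1 <- BASE + 1

test_that("sleep measures follow the wake-up-date assignment and stage sums", {
  # 8 h in bed: wake .8, light 4.5, deep 1.2, rem 1.5
  seg <- make_segment(lts(BASE, 23), c(wake = 0.4, light = 4.5, deep = 1.2,
                                       rem = 1.5, wake = 0.4),
                      efficiency = 0.9)
  m <- sleep_measures_for_day(seg$sleep, seg$stages, date1)
  expect_equal(m$total_sleep_hrs, 7.2)
  expect_equal(m$sleep_hrs_wake, 0.8)
  expect_equal(m$sleep_hrs_light, 4.5)
  expect_equal(m$sleep_efficiency, 0.9)

  # no segments that date -> all NA
  m0 <- sleep_measures_for_day(seg$sleep, seg$stages, date1 + 1)
  expect_true(all(is.na(unlist(m0))))

  # main (7 h light) + 1 h fully-light nap: naps count toward total,
  # efficiency comes from the main segment only
  two <- bind_segments(
    make_segment(lts(BASE, 23.5), c(light = 7), seg_id = 1L,
                 efficiency = 0.88),
    make_segment(lts(date1, 14), c(light = 1), seg_id = 2L, is_main = FALSE))
  m2 <- sleep_measures_for_day(two$sleep, two$stages, date1)
  expect_equal(m2$total_sleep_hrs, 8)
  expect_equal(m2$sleep_efficiency, 0.88)
})

test_that("overlapping segments assigned to one date raise a descriptive error", {
  two <- bind_segments(
    make_segment(lts(BASE, 23), c(light = 8), seg_id = 1L),
    make_segment(lts(BASE, 26), c(light = 6), seg_id = 2L, is_main = FALSE))
  expect_error(sleep_measures_for_day(two$sleep, two$stages, date1),
               "overlapping")
})

test_that("hr_asleep averages non-wake samples only", {
  seg <- make_segment(lts(BASE, 23), c(wake = 1, light = 2), efficiency = .9)
  inside_light <- lts(BASE, 24.5) + (0:59) * 60   # within the light bout
  hr <- data.frame(ts = inside_light, bpm = rep(60, 60))
  expect_equal(hr_asleep(hr, seg$sleep, seg$stages, date1), 60)

  # samples only during the wake bout -> NA
  inside_wake <- lts(BASE, 23.1) + (0:30) * 60
  hrw <- data.frame(ts = inside_wake, bpm = rep(80, 31))
  expect_true(is.na(hr_asleep(hrw, seg$sleep, seg$stages, date1)))

  # 30 samples at 65 and 30 at 75 -> 70
  hr2 <- data.frame(ts = inside_light, bpm = rep(c(65, 75), each = 30))
  expect_equal(hr_asleep(hr2, seg$sleep, seg$stages, date1), 70)
})

test_that("distance_travelled applies haversine with the three filters", {
  t0 <- lts(date1, 10)
  same <- data.frame(ts = c(t0, t0 + 600), lat = c(1.3, 1.3),
                     lon = c(103.8, 103.8), accuracy = c(10, 10))
  expect_equal(distance_travelled(same, date1), 0)

  # 0.1 degree of longitude near the equator, one hour apart
  hop <- data.frame(ts = c(t0, t0 + 3600), lat = c(1.3, 1.3),
                    lon = c(103.8, 103.9), accuracy = c(10, 10))
  # independent spherical-law-of-cosines oracle
  rad <- pi / 180
  oracle <- 6371.0088 * acos(pmin(1, sin(1.3 * rad)^2 +
    cos(1.3 * rad)^2 * cos(0.1 * rad)))
  d <- distance_travelled(hop, date1)
  expect_equal(d, oracle, tolerance = 1e-6)
  expect_equal(d, 11.12, tolerance = 0.01)

  # middle hop at ~500 km/h contributes nothing
  tele <- data.frame(ts = c(t0, t0 + 3600, t0 + 7200),
                     lat = c(1.3, 5.8, 5.81),
                     lon = c(103.8, 103.8, 103.8),
                     accuracy = c(10, 10, 10))
  d_tele <- distance_travelled(tele, date1)
  expect_lt(d_tele, 2)
  expect_equal(d_tele, haversine_km(5.8, 103.8, 5.81, 103.8))

  # sub-threshold jitter (~11 m) contributes nothing
  jit <- data.frame(ts = c(t0, t0 + 600), lat = c(1.3, 1.3001),
                    lon = c(103.8, 103.8), accuracy = c(10, 10))
  expect_equal(distance_travelled(jit, date1), 0)

  # accuracy filter can leave < 2 fixes -> NA
  bad <- data.frame(ts = c(t0, t0 + 600), lat = c(1.3, 1.4),
                    lon = c(103.8, 103.8), accuracy = c(10, 500))
  expect_true(is.na(distance_travelled(bad, date1)))

  expect_error(distance_travelled(
    data.frame(ts = c(t0, t0 + 60), lat = c(1.3, NaN),
               lon = c(103.8, 103.8), accuracy = c(5, 5)), date1),
    "non-finite")
})

test_that("reversing the fix order leaves total distance unchanged", {
  set.seed(8)
  t0 <- lts(date1, 9)
  n <- 40
  fx <- data.frame(ts = t0 + cumsum(runif(n, 60, 600)),
                   lat = 1.3 + cumsum(rnorm(n, 0, 0.002)),
                   lon = 103.8 + cumsum(rnorm(n, 0, 0.002)),
                   accuracy = runif(n, 5, 50))
  rev_fx <- data.frame(ts = fx$ts, lat = rev(fx$lat), lon = rev(fx$lon),
                       accuracy = rev(fx$accuracy))
  expect_equal(distance_travelled(fx, date1, max_speed_kmh = Inf,
                                  min_displacement_m = 0),
               distance_travelled(rev_fx, date1, max_speed_kmh = Inf,
                                  min_displacement_m = 0))
})

test_that("mode_intertap bins session gaps and excludes game taps", {
  t0 <- lts(date1, 12)
  taps <- data.frame(ts = t0 + c(0, .3, .6, .9), in_game = FALSE)
  r <- mode_intertap(taps, date1, min_taps = 3)
  expect_equal(r$mode_intertap_dist, 325)   # modal bin [300, 350)
  expect_equal(r$n_taps_in_window, 3L)

  # alternate taps in games: only the 0 and 600 ms taps remain
  taps$in_game <- c(FALSE, TRUE, FALSE, TRUE)
  r2 <- mode_intertap(taps, date1, min_taps = 1)
  expect_equal(r2$mode_intertap_dist, 625)

  # gaps {200 x5, 800 x3} with bin 50 -> modal bin midpoint 225
  ts <- t0 + c(cumsum(c(0, rep(.2, 5))), 100 + cumsum(c(0, rep(.8, 3))))
  r3 <- mode_intertap(data.frame(ts = ts, in_game = FALSE), date1,
                      min_taps = 8)
  expect_equal(r3$mode_intertap_dist, 225)
  expect_equal(r3$n_taps_in_window, 8L)

  # sparse input -> NA, not an error
  r4 <- mode_intertap(data.frame(ts = t0 + c(0, .3), in_game = FALSE), date1)
  expect_true(is.na(r4$mode_intertap_dist))
})

test_that("mode_intertap equals a brute-force histogram argmax", {
  brute <- function(gaps_ms, bin) {
    tb <- table(floor(gaps_ms / bin))
    top <- names(tb)[tb == max(tb)]
    b <- min(as.numeric(top))              # lowest bin wins ties
    (b + 0.5) * bin
  }
  set.seed(21)
  for (i in 1:30) {
    gaps <- exp(rnorm(80, log(400), 0.5))
    gaps <- pmin(gaps, 4500)
    ts <- lts(date1, 10) + cumsum(c(0, gaps / 1000))
    got <- mode_intertap(data.frame(ts = ts, in_game = FALSE), date1,
                         min_taps = 10)
    expect_equal(got$mode_intertap_dist, brute(gaps, 50))
  }
})

test_that("messages_sent distinguishes zero from missing", {
  t0 <- lts(date1, 10)
  msgs <- data.frame(
    ts = t0 + 1:9 * 60,
    channel = c(rep("carrier", 3), rep("whatsapp", 2), rep("carrier", 4)),
    direction = c(rep("sent", 5), rep("received", 4)),
    stringsAsFactors = FALSE)
  expect_equal(messages_sent(msgs, date1), 5)
  none <- msgs[0, ]
  expect_equal(messages_sent(none, date1, phone_present = TRUE), 0L)
  expect_true(is.na(messages_sent(none, date1, phone_present = FALSE)))
})

test_that("screen_time matches sessions, splits midnight, caps dangling ons", {
  pw <- function(...) {
    x <- list(...)
    data.frame(ts = vapply(x, `[[`, 0, 1),
               state = vapply(x, `[[`, "", 2), stringsAsFactors = FALSE)
  }
  p <- pw(list(lts(date1, 9), "screen_on"), list(lts(date1, 9.5), "screen_off"),
          list(lts(date1, 20), "screen_on"), list(lts(date1, 21.5), "screen_off"))
  expect_equal(screen_time(p, date1), 2)

  # 23:30 -> 00:30 splits half an hour onto each adjacent date
  pm <- pw(list(lts(date1, 23.5), "screen_on"),
           list(lts(date1, 24.5), "screen_off"))
  expect_equal(screen_time(pm, date1), 0.5)
  expect_equal(screen_time(pm, date1 + 1), 0.5)

  # consecutive screen_on: first session capped at the restart
  pr <- pw(list(lts(date1, 10), "screen_on"),
           list(lts(date1, 10 + 5 / 60), "screen_on"),
           list(lts(date1, 10.5), "screen_off"))
  expect_equal(screen_time(pr, date1), 0.5)

  # dangling trailing on capped at max_session_hrs
  pd <- pw(list(lts(date1, 10), "screen_on"))
  expect_equal(screen_time(pd, date1, max_session_hrs = 4), 4)

  expect_true(is.na(screen_time(pw()[0, ], date1, phone_present = FALSE)))
  expect_equal(screen_time(pw()[0, ], date1, phone_present = TRUE), 0)
})

test_that("screen time is conserved across midnight splits", {
  set.seed(4)
  for (rep in 1:20) {
    k <- sample(3:8, 1)
    starts <- sort(lts(BASE, runif(k, 1, 24 * 7)))
    durs <- runif(k, 0.2, 3) * 3600
    durs <- pmin(durs, c(diff(starts), Inf) * 0.9)  # keep sessions disjoint
    pw <- data.frame(ts = as.vector(rbind(starts, starts + durs)),
                     state = rep(c("screen_on", "screen_off"), k),
                     stringsAsFactors = FALSE)
    daily <- vapply(0:8, function(d) {
      v <- screen_time(pw, BASE + d, phone_present = TRUE)
      if (is.na(v)) 0 else v
    }, 0)
    expect_equal(sum(daily), sum(durs) / 3600, tolerance = 1e-9)
  }
})

test_that("daily_measures produces one complete row per day on a compliant bundle", {
  cfg <- cohort_config(n_participants = 2, seed = 31,
                       wearable_presence_prob = 1,
                       phone_presence_prob_own = 1,
                       phone_presence_prob_study = 1, nap_prob = 0)
  co <- generate_cohort(cfg)
  f <- daily_measures(co$bundles[[1]])
  expect_equal(nrow(f$daily), 7)
  expect_false(any(is.na(f$daily$total_sleep_hrs)))
  expect_false(any(is.na(f$daily$hr_asleep)))
  expect_false(any(is.na(f$daily$screen_time)))
  expect_false(any(is.na(f$intertap$mode_intertap_dist)))
  # stage additivity
  expect_equal(f$daily$total_sleep_hrs,
               f$daily$sleep_hrs_light + f$daily$sleep_hrs_deep +
                 f$daily$sleep_hrs_rem, tolerance = 1e-9)
})

test_that("an empty bundle yields all-null rows, not errors", {
  b <- make_bundle()
  f <- daily_measures(b)
  expect_equal(nrow(f$daily), 7)
  meas <- setdiff(names(f$daily), c("participant_id", "local_date"))
  expect_true(all(is.na(as.matrix(f$daily[meas]))))
  expect_true(all(is.na(f$intertap$mode_intertap_dist)))
})
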