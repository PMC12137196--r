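test_that("schedules are contiguous, seeded and respect the horizon", {
  sched <- simulate_schedule(3600, seed = 7)
  expect_equal(sched$start_s[1], 0)
  expect_equal(sched$end_s[nrow(sched)], 3600)
  expect_true(all(abs(sched$start_s[-1] - sched$end_s[-nrow(sched)]) < 1e-9))
  expect_true(all(sched$end_s > sched$start_s))

  expect_identical(sched, simulate_schedule(3600, seed = 7))
  expect_false(identical(sched$behavior,
                         simulate_schedule(3600, seed = 8)$behavior))

  # a dwell far beyond the horizon yields a single entry
  p <- default_behavior_params()
  p$mean_dwell_s <- 1e9
  one <- simulate_schedule(60, params = p, seed = 1,
                           start_behavior = "resting")
  expect_identical(nrow(one), 1L)
  expect_identical(one$behavior, "resting")
  expect_equal(c(one$start_s, one$end_s), c(0, 60))

  expect_error(simulate_schedule(-5), "duration_s")
})

test_that("renewal count matches the exponential-dwell expectation", {
  # with every mean dwell at 60 s a 3600 s horizon holds ~60 bouts; the
  # frozen band is 3x the Poisson sampling error around that mean
  p <- default_behavior_params()
  p$mean_dwell_s <- 60
  n <- nrow(simulate_schedule(3600, params = p, seed = 7))
  expect_gt(n, 60 - 3 * sqrt(60))
  expect_lt(n, 60 + 3 * sqrt(60))
})

test_that("simulated acceleration matches schedule truth and sampling", {
  sched <- simulate_schedule(3600, seed = 3)
  acc <- simulate_accel(sched, seed = 3)
  expect_identical(nrow(acc), 28800L)   # 3600 s x 8 Hz
  # label conservation: each sample carries the covering entry's behaviour
  idx <- sample(nrow(acc), 500)
  ei <- findInterval(acc$time_s[idx], sched$start_s)
  expect_identical(acc$behavior[idx], sched$behavior[ei])
  expect_identical(acc, simulate_accel(sched, seed = 3))
})

test_that("noise-free resting is pure gravity; gait sets the dominant bin", {
  p <- default_behavior_params()
  p$noise_sd <- 0
  sched <- data.frame(behavior = "resting", start_s = 0, end_s = 60,
                      start = as.POSIXct("2021-08-01", tz = "Etc/GMT-2"),
                      end = as.POSIXct("2021-08-01", tz = "Etc/GMT-2") + 60)
  acc <- simulate_accel(sched, params = p, seed = 1)
  expect_true(all(acc$acc_x == 0 & acc$acc_y == 0 & acc$acc_z == 1))

  # noise-free running at 2 Hz: periodogram argmax of the heave axis = 2 Hz
  p$gait_freq_hz[p$behavior == "running"] <- 2
  sched$behavior <- "running"
  acc <- simulate_accel(sched, params = p, seed = 1)
  z <- acc$acc_z - mean(acc$acc_z)
  pw <- Mod(fft(z))^2
  k <- which.max(pw[2:(length(z) / 2)])
  expect_equal(k * 8 / length(z), 2)

  # gait frequency at/above Nyquist is rejected
  p$gait_freq_hz[p$behavior == "running"] <- 4
  expect_error(simulate_accel(sched, params = p, seed = 1), "Nyquist")
})

test_that("annotations shift by the lag and thin by dropout", {
  sched <- simulate_schedule(3600, seed = 11)
  ev0 <- simulate_annotations(sched, lag_s = 0, dropout_fraction = 0)
  expect_equal(as.numeric(ev0$start), as.numeric(sched$start))
  expect_identical(ev0$behavior, sched$behavior)

  ev <- simulate_annotations(sched, lag_s = 120)
  expect_equal(as.numeric(ev$start), as.numeric(sched$start) + 120)
  expect_equal(as.numeric(ev$end), as.numeric(sched$end) + 120)

  # seeded Bernoulli thinning oracle on 100 entries
  sched100 <- sched[rep(seq_len(nrow(sched)), length.out = 100), ]
  set.seed(5)
  expected <- sum(runif(100) >= 0.5)
  ev5 <- simulate_annotations(sched100, dropout_fraction = 0.5, seed = 5)
  expect_identical(nrow(ev5), expected)
  expect_identical(ev5, simulate_annotations(sched100,
                                             dropout_fraction = 0.5,
                                             seed = 5))
  expect_error(simulate_annotations(sched, dropout_fraction = 1))
})

test_that("GPS displacement scales with the active fraction", {
  t0 <- as.POSIXct("2021-08-01", tz = "Etc/GMT-2")
  day <- function(b) data.frame(behavior = b, start_s = 0, end_s = 86400,
                                start = t0, end = t0 + 86400)
  still <- simulate_gps(day("resting"), noise_sd_m = 0, seed = 1)
  expect_identical(nrow(still), 25L)
  expect_true(all(still$x_m == 0 & still$y_m == 0))
  expect_equal(daily_distance(still)$daily_distance_m, 0)

  moving <- simulate_gps(day("walking"), nominal_m_per_h = 500,
                         noise_sd_m = 0, seed = 1)
  expect_equal(daily_distance(moving)$daily_distance_m, 24 * 500)
  expect_identical(moving, simulate_gps(day("walking"),
                                        nominal_m_per_h = 500,
                                        noise_sd_m = 0, seed = 1))
})

test_that("a bimodal diel profile yields crepuscular activity peaks", {
  # hourly active fraction over many simulated days peaks in the profile's
  # two peak hours; schedules suffice (labels drive the fraction)
  diel <- default_diel_profile(peak_hours = c(5, 20))
  sched <- simulate_schedule(100 * 86400, diel = diel, seed = 41)
  grid <- seq(30, 100 * 86400 - 30, by = 60)
  beh <- sched$behavior[findInterval(grid, sched$start_s)]
  hour <- floor(grid / 3600) %% 24
  frac <- tapply(beh %in% c("feeding", "walking"), hour, mean)
  top2 <- as.integer(names(sort(frac, decreasing = TRUE)))[1:2]
  expect_setequal(top2, c(5, 20))
})

test_that("mean per-window ODBA separates the four behaviours", {
  mean_odba <- vapply(bear_behaviors(), function(b) {
    f <- compute_features(single_behavior_series(b, 3 * 1000 + 6,
                                                 seed = 99))
    mean(f$odba_mean[seq_len(1000)])
  }, numeric(1))
  expect_true(mean_odba[["running"]] > mean_odba[["walking"]])
  expect_true(mean_odba[["walking"]] > mean_odba[["feeding"]])
  expect_true(mean_odba[["feeding"]] > mean_odba[["resting"]])
})
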