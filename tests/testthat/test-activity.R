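tz2 <- "Etc/GMT-2"
t0 <- function(date, s = 0) as.POSIXct(paste(date, "00:00:00"),
                                       tz = tz2) + s
label_stream <- function(date, start_s, labels, bear_id = "b1") {
  data.frame(bear_id = bear_id,
             time = t0(date, start_s + 3 * (seq_along(labels) - 1)),
             label = labels)
}

test_that("feedwalking merge conserves counts", {
  lab <- c("walking", "feeding", "resting", "running")
  expect_identical(merge_feedwalk(lab),
                   c("feedwalking", "feedwalking", "resting", "running"))
  expect_identical(merge_feedwalk(rep("resting", 3)), rep("resting", 3))
  set.seed(8)
  lab <- sample(bear_behaviors(), 500, replace = TRUE)
  out <- merge_feedwalk(lab)
  expect_identical(sum(out == "feedwalking"),
                   sum(lab %in% c("walking", "feeding")))
  expect_error(merge_feedwalk(c("resting", "hopping")), "hopping")
})

test_that("bout detection run-length encodes and respects gaps", {
  x <- label_stream("2021-08-05", 0, c("running", "running", "walking",
                                       "running"))
  b <- detect_bouts(x)
  expect_identical(nrow(b), 2L)
  expect_equal(b$duration_s, c(6, 3))
  expect_equal(b$n_windows, c(2L, 1L))
  expect_equal(as.numeric(b$end - b$start, units = "secs"), c(6, 3))

  expect_identical(nrow(detect_bouts(label_stream("2021-08-05", 0,
                                                  rep("resting", 5)))), 0L)

  # a recording gap splits an otherwise continuous run
  y <- label_stream("2021-08-05", 0, rep("running", 4))
  y$time[3:4] <- y$time[3:4] + 30
  expect_identical(nrow(detect_bouts(y)), 2L)

  # bear identity splits runs even at contiguous times
  z <- rbind(label_stream("2021-08-05", 0, rep("running", 2), "b1"),
             label_stream("2021-08-05", 6, rep("running", 2), "b2"))
  expect_identical(nrow(detect_bouts(z)), 2L)
})

test_that("bout detection matches the RLE oracle with conservation", {
  set.seed(31)
  for (i in 1:200) {
    lab <- sample(c("resting", "feedwalking", "running"),
                  sample(5:60, 1), replace = TRUE,
                  prob = c(0.4, 0.4, 0.2))
    x <- label_stream("2021-08-10", 0, lab)
    b <- detect_bouts(x)
    o <- oracle_bouts(lab, "running")
    expect_identical(nrow(b), nrow(o))
    if (nrow(b) > 0) {
      expect_equal(as.numeric(b$start) - as.numeric(x$time[1]),
                   (o$start_i - 1) * 3)
      expect_identical(b$n_windows, o$n)
    }
    expect_identical(sum(b$n_windows), sum(lab == "running"))
  }
})

test_that("legal hours follow solar geometry at the study site", {
  dates <- seq(as.Date("2021-08-01"), as.Date("2021-08-31"), by = "day")
  lh <- legal_hours(dates)
  expect_true(all(lh$end > lh$start))            # August daylight at 61 N
  st <- sun_times(dates)
  expect_equal(as.numeric(lh$start - st$sunrise, units = "hours"),
               rep(-1, 31))
  expect_equal(as.numeric(lh$end - st$sunset, units = "hours"),
               rep(-2, 31))

  # +15 degrees of longitude shifts both bounds one hour earlier
  east <- legal_hours(dates, study_calendar(site_lon = 30))
  expect_equal(as.numeric(east$start - lh$start, units = "hours"),
               rep(-1, 31), tolerance = 1e-6)
  expect_equal(as.numeric(east$end - lh$end, units = "hours"),
               rep(-1, 31), tolerance = 1e-6)

  # half-open interval: start inside, end outside
  d <- as.Date("2021-08-21")
  l1 <- legal_hours(d)
  expect_true(in_legal_hours(l1$start))
  expect_false(in_legal_hours(l1$end))
  expect_false(in_legal_hours(l1$start - 1))

  # lengthening the interval never decreases legal-hour bout counts
  n_in <- function(cal) sum(in_legal_hours(t0("2021-08-10", 3600 * 0:23),
                                           cal))
  expect_gte(n_in(study_calendar(site_lat = 61)),
             n_in(study_calendar(site_lat = 66)))
})

test_that("period assignment partitions August", {
  dates <- seq(as.Date("2021-08-01"), as.Date("2021-08-31"), by = "day")
  p <- assign_period(dates)
  expect_false(any(is.na(p)))
  expect_identical(sum(p == "pre_hunting"), 20L)
  expect_identical(sum(p == "hunting"), 11L)
  expect_identical(assign_period(as.Date("2021-08-20")), "pre_hunting")
  expect_identical(assign_period(as.Date("2021-08-21")), "hunting")
  expect_true(is.na(assign_period(as.Date("2021-07-31"))))
})

test_that("daily metrics count bouts, legal starts and periods", {
  d <- "2021-08-21"
  lh <- legal_hours(as.Date(d))
  in_s <- as.numeric(lh$start) - as.numeric(t0(d)) + 60
  out_s <- as.numeric(lh$end) - as.numeric(t0(d)) + 3600
  lab <- rbind(
    label_stream(d, in_s, rep("running", 2)),
    label_stream(d, in_s + 600, "running"),
    label_stream(d, in_s + 1200, "running"),
    label_stream(d, out_s, "running"),
    label_stream(d, out_s + 600, rep("resting", 10)))
  bouts <- detect_bouts(lab)
  expect_identical(nrow(bouts), 4L)
  demo <- data.frame(bear_id = "b1", group = "adult_male")
  rec <- daily_metrics(bouts, lab, demographics = demo)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$n_running_bouts, 4L)
  expect_identical(rec$n_bouts_legal_hours, 3L)
  expect_equal(rec$prop_legal, 0.75)
  expect_identical(rec$period, "hunting")
  expect_identical(rec$demographic_group, "adult_male")

  # a bear-day without bouts keeps NA proportion, not 0
  quiet <- label_stream("2021-08-05", 43200, rep("resting", 5), "b2")
  demo2 <- rbind(demo, data.frame(bear_id = "b2", group = "adult_male"))
  rec2 <- daily_metrics(bouts, rbind(lab, quiet), demographics = demo2)
  r2 <- rec2[rec2$bear_id == "b2", ]
  expect_identical(r2$n_running_bouts, 0L)
  expect_true(is.na(r2$prop_legal))
  expect_identical(r2$period, "pre_hunting")

  # bears without demographic assignment are excluded with a warning
  expect_warning(rec3 <- daily_metrics(bouts, rbind(lab, quiet),
                                       demographics = demo),
                 "b2")
  expect_identical(nrow(rec3), 1L)

  # bouts forced into legal hours give proportion exactly 1
  only_legal <- daily_metrics(bouts[bouts$start < lh$end &
                                      bouts$start >= lh$start, ],
                              lab, demographics = demo)
  expect_equal(only_legal$prop_legal, 1)
})

test_that("daily distance sums successive-fix segments per day", {
  track <- data.frame(
    timestamp = t0("2021-08-03", c(0, 3600, 7200)),
    x_m = c(0, 300, 300), y_m = c(0, 400, 400))
  expect_equal(daily_distance(track)$daily_distance_m, 500)

  # random 25-fix track against a brute-force pairwise oracle
  set.seed(4)
  tr <- data.frame(timestamp = t0("2021-08-03", 3600 * (0:24)),
                   x_m = cumsum(rnorm(25, 0, 200)),
                   y_m = cumsum(rnorm(25, 0, 200)))
  want <- 0
  for (i in 1:24) {
    want <- want + sqrt((tr$x_m[i + 1] - tr$x_m[i])^2 +
                          (tr$y_m[i + 1] - tr$y_m[i])^2)
  }
  got <- daily_distance(tr)
  expect_identical(nrow(got), 1L)       # all segments start on one date
  expect_equal(got$daily_distance_m, want)

  expect_identical(nrow(daily_distance(tr[1, ])), 0L)
  expect_error(daily_distance(data.frame(timestamp = t0("2021-08-03"))),
               "planar")
})

test_that("hourly subsampling is capped, seeded and order-insensitive", {
  lab <- label_stream("2021-08-10", 0, rep("resting", 1200))
  sub <- subsample_hourly(lab, n_per_hour = 10, seed = 2)
  expect_identical(nrow(sub), 10L)
  few <- label_stream("2021-08-10", 0, rep("resting", 4))
  expect_identical(nrow(subsample_hourly(few, 10, seed = 2)), 4L)

  two_h <- label_stream("2021-08-10", 3000, rep("resting", 1200))
  sub2 <- subsample_hourly(two_h, 10, seed = 2)
  hours <- format(sub2$time, "%H")
  expect_equal(unname(table(hours)), c(10, 10), ignore_attr = TRUE)

  expect_identical(subsample_hourly(lab, 10, seed = 2),
                   subsample_hourly(lab, 10, seed = 2))
  expect_false(identical(subsample_hourly(lab, 10, seed = 2)$time,
                         subsample_hourly(lab, 10, seed = 3)$time))
  # same row set regardless of input ordering
  shuf <- lab[sample(nrow(lab)), ]
  s1 <- subsample_hourly(lab, 10, seed = 5)
  s2 <- subsample_hourly(shuf, 10, seed = 5)
  expect_identical(nrow(s2), 10L)
})

test_that("export tables carry period, time of day and indicators", {
  lab <- rbind(label_stream("2021-08-20", 48600, "feedwalking"),
               label_stream("2021-08-21", 48600, "resting"))
  out <- export_model_table(lab)
  expect_identical(out$windows$time_of_day_s, c(48600, 48600))
  expect_identical(out$windows$is_feedwalking, c(1L, 0L))
  expect_identical(out$windows$is_resting, c(0L, 1L))
  expect_identical(out$windows$period, c("pre_hunting", "hunting"))
  expect_identical(nrow(out$windows), nrow(lab))
  expect_identical(out$windows$year, c(2021L, 2021L))
})

test_that("diel profile estimates per-bin feedwalking with bootstrap CI", {
  lab <- label_stream("2021-08-10", 0, rep("feedwalking", 100))
  pr <- diel_profile(lab, n_boot = 50, seed = 1)
  expect_identical(nrow(pr), 24L)
  expect_equal(pr$prop_feedwalk[1], 1)
  expect_equal(pr$lower[1], 1)
  expect_equal(pr$upper[1], 1)
  expect_true(all(is.na(pr$prop_feedwalk[-1])))

  # n_boot = 1: interval collapses to the point estimate
  set.seed(9)
  lab2 <- label_stream("2021-08-10", 0,
                       sample(c("feedwalking", "resting"), 200, TRUE))
  p1 <- diel_profile(lab2, n_boot = 1, seed = 1)
  expect_equal(p1$lower, p1$prop_feedwalk)
  expect_equal(p1$upper, p1$prop_feedwalk)

  # simulator truth: the two busiest bins match the diel peaks
  diel <- default_diel_profile(peak_hours = c(5, 20))
  sched <- simulate_schedule(40 * 86400, diel = diel, seed = 61)
  grid <- seq(1.5, 40 * 86400 - 3, by = 3)
  lab3 <- data.frame(
    bear_id = "b1",
    time = sched$start[1] - sched$start_s[1] + grid,
    label = merge_feedwalk(sched$behavior[findInterval(grid,
                                                       sched$start_s)]))
  pr3 <- diel_profile(lab3, n_boot = 2, seed = 1)
  top2 <- pr3$hour[order(pr3$prop_feedwalk, decreasing = TRUE)][1:2]
  expect_setequal(top2, c(5, 20))
  expect_true(all(pr3$prop_feedwalk >= 0 & pr3$prop_feedwalk <= 1))
})
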