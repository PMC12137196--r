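# Synthetic collar data: semi-Markov behaviour schedules with diel
# modulation, 8 Hz tri-axial acceleration per behaviour, lagged annotation
# events and hourly GPS fixes. Ground truth is carried everywhere so every
# pipeline stage can be tested without field data.

.default_start_time <- function(tz = "Etc/GMT-2") {
  as.POSIXct("2021-08-01 00:00:00", tz = tz)
}

#' Default per-behaviour signal parameters
#'
#' Fixture parameters for the generator, one row per behaviour: static
#' gravity vector (g) for posture, white-noise amplitude per axis,
#' gait frequency and amplitude of the periodic (surge/heave) component, and
#' the mean bout dwell time for the semi-Markov schedule. Resting and feeding
#' have no gait component; running's short dwell (9 s) mirrors the scale of
#' observed running bouts. The amplitudes are fixtures chosen so that mean
#' per-window ODBA orders running > walking > feeding > resting; they are
#' not estimates of wild-bear accelerations.
#'
#' @return data.frame with columns `behavior`, `grav_x`, `grav_y`, `grav_z`,
#'   `noise_sd`, `gait_freq_hz`, `gait_amp`, `mean_dwell_s`.
#' @export
default_behavior_params <- function() {
  data.frame(
    behavior = c("resting", "feeding", "walking", "running"),
    grav_x = c(0, 0, 0, 0),
    grav_y = c(0, 0.40, 0.10, 0.20),
    grav_z = c(1, 0.90, 0.99, 0.97),
    noise_sd = c(0.02, 0.08, 0.05, 0.10),
    gait_freq_hz = c(0, 0, 1.5, 3),
    gait_amp = c(0, 0, 0.25, 0.8),
    mean_dwell_s = c(600, 180, 60, 9)
  )
}

.check_behavior_params <- function(params, fs = NULL) {
  need <- c("behavior", "grav_x", "grav_y", "grav_z", "noise_sd",
            "gait_freq_hz", "gait_amp", "mean_dwell_s")
  stopifnot(is.data.frame(params), all(need %in% names(params)))
  miss <- setdiff(bear_behaviors(), params$behavior)
  if (length(miss) > 0L) {
    stop("behavior parameters missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(params$noise_sd < 0) || any(params$gait_amp < 0)) {
    stop("noise_sd and gait_amp must be non-negative", call. = FALSE)
  }
  if (any(params$mean_dwell_s <= 0)) {
    stop("mean_dwell_s must be positive", call. = FALSE)
  }
  if (!is.null(fs) && any(params$gait_freq_hz >= fs / 2)) {
    stop("gait_freq_hz must be below the Nyquist frequency fs/2",
         call. = FALSE)
  }
  invisible(params)
}

#' Default bimodal diel activity profile
#'
#' Relative weight of choosing an active foraging state (feeding or walking)
#' at each hour of day, bimodal with crepuscular peaks. Defaults put the
#' peaks at 05:00 and 20:00 local time, around August sunrise/sunset at
#' 61 degrees N.
#'
#' @param peak_hours Two peak hours of day (0--23).
#' @param width_h Gaussian width of each peak, hours; kept narrow so the
#'   activity maximum is identifiable at the peak hour itself.
#' @param floor_w Baseline weight away from the peaks.
#' @return Numeric vector of 24 non-negative weights named "0".."23".
#' @export
default_diel_profile <- function(peak_hours = c(5, 20), width_h = 1,
                                 floor_w = 0.05) {
  h <- 0:23
  w <- floor_w +
    exp(-0.5 * ((h - peak_hours[1]) / width_h)^2) +
    exp(-0.5 * ((h - peak_hours[2]) / width_h)^2)
  stats::setNames(w, as.character(h))
}

#' Simulate a semi-Markov behaviour schedule
#'
#' Generates a contiguous sequence of behaviour bouts covering
#' `[0, duration_s)`. Dwell times are exponential with each behaviour's
#' `mean_dwell_s` (memoryless semi-Markov renewal). At every transition the
#' next state (never the current one) is drawn with weights: resting 1,
#' running `running_weight`, and feeding/walking each weighted by the diel
#' profile at the current hour of day — this produces the crepuscular,
#' bimodal activity pattern of free-ranging bears in late summer.
#'
#' @param duration_s Schedule horizon in seconds (>= 60).
#' @param params Behaviour parameter table, see [default_behavior_params()].
#' @param diel 24-vector of hourly activity weights,
#'   see [default_diel_profile()].
#' @param seed Integer seed; identical seeds give identical schedules.
#' @param start_time `POSIXct` anchor of schedule second 0 (local clock).
#' @param start_behavior Behaviour of the first bout.
#' @param running_weight Relative transition weight of running.
#' @return data.frame with `behavior`, `start_s`, `end_s`, `start`, `end`.
#' @export
#' @examples
#' sched <- simulate_schedule(3600, seed = 1)
#' table(sched$behavior)
simulate_schedule <- function(duration_s,
                              params = default_behavior_params(),
                              diel = default_diel_profile(),
                              seed = 1,
                              start_time = .default_start_time(),
                              start_behavior = "resting",
                              running_weight = 0.15) {
  if (!is.numeric(duration_s) || length(duration_s) != 1L ||
      duration_s < 60) {
    stop("duration_s must be a single number >= 60 seconds", call. = FALSE)
  }
  .check_behavior_params(params)
  stopifnot(length(diel) == 24L, all(diel >= 0), any(diel > 0))
  .assert_behaviors(start_behavior)
  set.seed(seed)
  dwell <- stats::setNames(params$mean_dwell_s, params$behavior)
  tod0 <- as.numeric(start_time) -
    as.numeric(trunc(start_time, units = "days"))
  beh <- character(); st <- numeric(); en <- numeric()
  k <- 0L
  t <- 0; b <- start_behavior
  while (t < duration_s) {
    d <- rexp(1L, rate = 1 / dwell[[b]])
    e <- min(t + d, duration_s)
    k <- k + 1L
    beh[k] <- b; st[k] <- t; en[k] <- e
    t <- e
    if (t >= duration_s) break
    hour <- floor(((tod0 + t) / 3600)) %% 24
    w <- c(resting = 1,
           feeding = unname(diel[hour + 1]),
           walking = unname(diel[hour + 1]),
           running = running_weight)
    w <- w[names(w) != b]
    b <- sample(names(w), 1L, prob = w)
  }
  data.frame(behavior = beh, start_s = st, end_s = en,
             start = start_time + st, end = start_time + en)
}

#' Simulate tri-axial accelerometry from a behaviour schedule
#'
#' For every sample at `1/fs` spacing the signal is the behaviour's static
#' gravity vector, plus (for gaited behaviours) a sinusoid of the gait
#' frequency on the surge (y) axis and the same sinusoid phase-shifted by 90
#' degrees on the heave (z) axis, plus independent Gaussian noise on each
#' axis. The generating behaviour is attached to every sample as ground
#' truth.
#'
#' @param schedule Contiguous schedule from [simulate_schedule()].
#' @param params Behaviour parameter table.
#' @param fs Sampling frequency, Hz (default 8); all gait frequencies must
#'   be below `fs/2`.
#' @param seed Integer seed.
#' @return data.frame: `timestamp` (POSIXct with milliseconds), `time_s`,
#'   `acc_x`, `acc_y`, `acc_z` (g), `behavior`.
#' @export
simulate_accel <- function(schedule, params = default_behavior_params(),
                           fs = 8, seed = 1) {
  stopifnot(fs > 0, nrow(schedule) >= 1L)
  .check_behavior_params(params, fs = fs)
  if (nrow(schedule) > 1L &&
      any(abs(schedule$start_s[-1L] -
              schedule$end_s[-nrow(schedule)]) > 1e-9)) {
    stop("schedule must be contiguous", call. = FALSE)
  }
  set.seed(seed)
  dur <- schedule$end_s[nrow(schedule)] - schedule$start_s[1L]
  n <- floor(dur * fs)
  t <- schedule$start_s[1L] + (seq_len(n) - 1L) / fs
  ei <- findInterval(t, schedule$start_s)
  beh <- schedule$behavior[ei]
  p <- params[match(beh, params$behavior), ]
  phase <- 2 * pi * p$gait_freq_hz * t
  acc_x <- p$grav_x + rnorm(n, 0, p$noise_sd)
  acc_y <- p$grav_y + p$gait_amp * sin(phase) + rnorm(n, 0, p$noise_sd)
  acc_z <- p$grav_z + p$gait_amp * sin(phase + pi / 2) +
    rnorm(n, 0, p$noise_sd)
  start_time <- schedule$start[1L] - schedule$start_s[1L]
  data.frame(timestamp = start_time + t, time_s = t,
             acc_x = acc_x, acc_y = acc_y, acc_z = acc_z,
             behavior = beh)
}

#' Simulate video-annotation events with clock lag and dropout
#'
#' Copies the schedule onto the annotation (video) clock: every event is
#' shifted by `+lag_s` relative to the accelerometer clock, emulating the
#' unsynchronised video timestamps of captive-bear observation sessions
#' (observed lags of one to three minutes), and a random fraction of events
#' is dropped (periods when the animal was out of frame).
#'
#' @param schedule Schedule from [simulate_schedule()].
#' @param lag_s Clock lag in seconds added to every start/end.
#' @param dropout_fraction Probability in `[0, 1)` that an event is missing.
#' @param seed Integer seed for the dropout draw.
#' @return data.frame with `behavior`, `start`, `end` (`POSIXct`, annotation
#'   clock).
#' @export
simulate_annotations <- function(schedule, lag_s = 0, dropout_fraction = 0,
                                 seed = 1) {
  stopifnot(is.finite(lag_s), dropout_fraction >= 0, dropout_fraction < 1)
  set.seed(seed)
  keep <- runif(nrow(schedule)) >= dropout_fraction
  data.frame(behavior = schedule$behavior[keep],
             start = schedule$start[keep] + lag_s,
             end = schedule$end[keep] + lag_s)
}

#' Simulate an hourly GPS track from a behaviour schedule
#'
#' One planar fix per `fix_interval_s`, starting at the schedule origin.
#' The displacement over each interval has magnitude
#' `active_fraction * nominal_m_per_h * (interval/3600) + noise`, where the
#' active fraction is the share of the interval spent feeding, walking or
#' running, and the heading is uniform — hourly step lengths scale with
#' activity, as in free-ranging movement data, without any terrain model.
#'
#' @param schedule Schedule from [simulate_schedule()].
#' @param nominal_m_per_h Displacement per fully active hour, metres.
#' @param noise_sd_m Gaussian noise on each step length, metres.
#' @param fix_interval_s Fix spacing, seconds (default 3600).
#' @param seed Integer seed.
#' @return data.frame with `timestamp` (`POSIXct`), `x_m`, `y_m`.
#' @export
simulate_gps <- function(schedule, nominal_m_per_h = 500, noise_sd_m = 0,
                         fix_interval_s = 3600, seed = 1) {
  stopifnot(fix_interval_s > 0)
  set.seed(seed)
  t0 <- schedule$start_s[1L]
  dur <- schedule$end_s[nrow(schedule)] - t0
  n_int <- floor(dur / fix_interval_s)
  active <- schedule$behavior %in% .active_behaviors
  frac <- vapply(seq_len(n_int), function(k) {
    a <- t0 + (k - 1L) * fix_interval_s
    b <- a + fix_interval_s
    ov <- pmin(schedule$end_s, b) - pmax(schedule$start_s, a)
    sum(pmax(ov, 0)[active]) / fix_interval_s
  }, numeric(1L))
  step <- frac * nominal_m_per_h * (fix_interval_s / 3600) +
    rnorm(n_int, 0, noise_sd_m)
  heading <- runif(n_int, 0, 2 * pi)
  x <- cumsum(c(0, step * cos(heading)))
  y <- cumsum(c(0, step * sin(heading)))
  start_time <- schedule$start[1L]
  data.frame(timestamp = start_time + (0:n_int) * fix_interval_s,
             x_m = x, y_m = y)
}
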