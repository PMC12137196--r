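# Activity budgets: feedwalking merge, bout detection, daily running-bout
# counts, legal-hour proportions, GPS daily distance, hourly subsampling,
# model-ready export and diel profiles.

#' Merge walking and feeding into a feedwalking state
#'
#' In late summer wild bears forage on berries by walking slowly while
#' feeding, which confounds the two accelerometer signatures; walking and
#' feeding predictions are therefore pooled into a single `feedwalking`
#' category, leaving the three-state stream resting / feedwalking / running.
#' Counts are conserved: `count(feedwalking) = count(walking) +
#' count(feeding)`.
#'
#' @param labels Character or factor vector of four-category labels.
#' @return Character vector of three-category labels.
#' @export
merge_feedwalk <- function(labels) {
  lab <- as.character(labels)
  .assert_behaviors(lab)
  lab[lab %in% c("walking", "feeding")] <- "feedwalking"
  lab
}

#' Detect behaviour bouts by run-length encoding
#'
#' A bout is a maximal run of consecutive windows carrying the target label;
#' any other label, a recording gap (window spacing exceeding `window_s`
#' beyond tolerance), or a change of animal ends the bout. Bout duration is
#' the run length times the window length.
#'
#' @param labels data.frame with columns `time` (`POSIXct` or numeric window
#'   start), `label`, and optionally `bear_id`; time-sorted within bear.
#' @param behavior Target label (default `"running"`).
#' @param window_s Window length in seconds.
#' @return data.frame of bouts: `bear_id`, `behavior`, `start`, `end`,
#'   `duration_s`, `n_windows`.
#' @export
#' @examples
#' x <- data.frame(time = seq(0, 9, by = 3),
#'                 label = c("running", "running", "resting", "running"))
#' detect_bouts(x)
detect_bouts <- function(labels, behavior = "running", window_s = 3) {
  stopifnot(all(c("time", "label") %in% names(labels)))
  if (!"bear_id" %in% names(labels)) labels$bear_id <- "bear"
  tm <- as.numeric(labels$time)
  hit <- as.character(labels$label) == behavior
  n <- nrow(labels)
  if (n == 0L || !any(hit)) {
    return(data.frame(bear_id = character(), behavior = character(),
                      start = labels$time[0], end = labels$time[0],
                      duration_s = numeric(), n_windows = integer()))
  }
  # run breaks: target-membership change, bear change, or a time gap
  gap <- c(TRUE, diff(tm) > window_s * 1.01 |
             labels$bear_id[-1L] != labels$bear_id[-n] |
             hit[-1L] != hit[-n])
  run_id <- cumsum(gap)
  first_idx <- which(gap)
  last_idx <- c(first_idx[-1L] - 1L, n)
  sel <- hit[first_idx]
  nw <- (last_idx - first_idx + 1L)[sel]
  out <- data.frame(bear_id = labels$bear_id[first_idx[sel]],
                    behavior = behavior,
                    start = labels$time[first_idx[sel]],
                    end = labels$time[last_idx[sel]] + window_s,
                    duration_s = nw * window_s,
                    n_windows = nw)
  rownames(out) <- NULL
  out
}

#' Daily distance travelled from hourly GPS fixes
#'
#' Sums the straight-line distances between successive fixes; each segment
#' is assigned to the local date of its starting fix, so a full 24 h day of
#' hourly fixes contributes 24 segments. Planar coordinates (`x_m`, `y_m`)
#' use Euclidean distance; geographic coordinates (`lon`, `lat`) use
#' great-circle distance (via the geosphere package). A bear-day with no
#' segment is reported as `NA`.
#'
#' @param track data.frame with `timestamp` (`POSIXct`) plus either
#'   `x_m`/`y_m` or `lon`/`lat`; optional `bear_id`.
#' @param calendar A [study_calendar()] (fixes the local date boundary,
#'   midnight UTC+2 by default).
#' @return data.frame with `bear_id`, `date`, `daily_distance_m`.
#' @export
daily_distance <- function(track, calendar = study_calendar()) {
  stopifnot("timestamp" %in% names(track))
  if (!"bear_id" %in% names(track)) track$bear_id <- "bear"
  planar <- all(c("x_m", "y_m") %in% names(track))
  if (!planar && !all(c("lon", "lat") %in% names(track))) {
    stop("track needs x_m/y_m (planar) or lon/lat (geographic) columns",
         call. = FALSE)
  }
  out <- lapply(split(track, track$bear_id), function(tr) {
    tr <- tr[order(tr$timestamp), , drop = FALSE]
    if (nrow(tr) < 2L) {
      return(data.frame(bear_id = tr$bear_id[0], date = as.Date(character()),
                        daily_distance_m = numeric()))
    }
    seg <- if (planar) {
      sqrt(diff(tr$x_m)^2 + diff(tr$y_m)^2)
    } else {
      if (!requireNamespace("geosphere", quietly = TRUE)) {
        stop("geographic tracks need the geosphere package", call. = FALSE)
      }
      n <- nrow(tr)
      geosphere::distGeo(cbind(tr$lon[-n], tr$lat[-n]),
                         cbind(tr$lon[-1L], tr$lat[-1L]))
    }
    d <- as.Date(tr$timestamp[-nrow(tr)], tz = calendar$tz)
    agg <- tapply(seg, d, sum)
    data.frame(bear_id = tr$bear_id[1L],
               date = as.Date(names(agg)),
               daily_distance_m = as.numeric(agg))
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per bear-day activity records
#'
#' Builds one record per bear-day present in the label stream: the number of
#' running bouts that day, how many of them started inside the legal-hunting
#' interval, their proportion (`NA` on days with no bout), the study period,
#' the bear's demographic group and (when a track is supplied) the daily
#' GPS distance. A bout belongs to a day and to the legal interval by its
#' start timestamp.
#'
#' @param bouts Bout table from [detect_bouts()] (running bouts; any
#'   `behavior` column is filtered to `"running"`).
#' @param labels Window label stream (`bear_id`, `time`) defining the
#'   bear-days covered by recording.
#' @param calendar A [study_calendar()].
#' @param demographics data.frame `bear_id`, `group` (one of
#'   female_with_offspring, subadult_solitary_female, adult_solitary_female,
#'   adult_male); bears without an assignment are excluded with a warning.
#' @param gps Optional GPS track for [daily_distance()].
#' @return data.frame of `DailyActivityRecord`s: `bear_id`, `date`, `year`,
#'   `period`, `demographic_group`, `n_running_bouts`,
#'   `n_bouts_legal_hours`, `prop_legal`, `daily_distance_m`.
#' @export
daily_metrics <- function(bouts, labels, calendar = study_calendar(),
                          demographics = NULL, gps = NULL) {
  stopifnot(all(c("time") %in% names(labels)))
  if (!"bear_id" %in% names(labels)) labels$bear_id <- "bear"
  if ("behavior" %in% names(bouts)) {
    bouts <- bouts[bouts$behavior == "running", , drop = FALSE]
  }
  tz <- calendar$tz
  days <- unique(data.frame(bear_id = labels$bear_id,
                            date = as.Date(labels$time, tz = tz)))
  days <- days[order(days$bear_id, days$date), , drop = FALSE]

  if (nrow(bouts) > 0L) {
    bouts$date <- as.Date(bouts$start, tz = tz)
    bouts$legal <- in_legal_hours(as.POSIXct(bouts$start, tz = tz), calendar)
  }
  rec <- days
  rec$n_running_bouts <- 0L
  rec$n_bouts_legal_hours <- 0L
  if (nrow(bouts) > 0L) {
    key <- paste(rec$bear_id, rec$date)
    bkey <- paste(bouts$bear_id, bouts$date)
    tot <- table(bkey)
    leg <- tapply(bouts$legal, bkey, sum)
    i <- match(key, names(tot))
    rec$n_running_bouts <- ifelse(is.na(i), 0L, as.integer(tot[i]))
    rec$n_bouts_legal_hours <- ifelse(is.na(i), 0L, as.integer(leg[i]))
  }
  rec$prop_legal <- ifelse(rec$n_running_bouts > 0,
                           rec$n_bouts_legal_hours / rec$n_running_bouts,
                           NA_real_)
  rec$period <- assign_period(rec$date, calendar)
  rec$year <- as.integer(format(rec$date, "%Y"))

  if (!is.null(demographics)) {
    stopifnot(all(c("bear_id", "group") %in% names(demographics)))
    i <- match(rec$bear_id, demographics$bear_id)
    drop <- is.na(i)
    if (any(drop)) {
      warning("excluding bear(s) without demographic assignment: ",
              paste(unique(rec$bear_id[drop]), collapse = ", "),
              call. = FALSE)
    }
    rec$demographic_group <- demographics$group[i]
    rec <- rec[!drop, , drop = FALSE]
  } else {
    rec$demographic_group <- NA_character_
  }

  rec$daily_distance_m <- NA_real_
  if (!is.null(gps)) {
    dd <- daily_distance(gps, calendar)
    i <- match(paste(rec$bear_id, rec$date), paste(dd$bear_id, dd$date))
    rec$daily_distance_m <- dd$daily_distance_m[i]
  }
  rec <- rec[, c("bear_id", "date", "year", "period", "demographic_group",
                 "n_running_bouts", "n_bouts_legal_hours", "prop_legal",
                 "daily_distance_m")]
  rownames(rec) <- NULL
  rec
}

#' Subsample windows to n per bear-day-hour
#'
#' Draws `n_per_hour` windows uniformly without replacement within every
#' bear x date x hour cell (all windows are kept when fewer are available).
#' Used to thin the 3 s stream before mixed-model fitting, where using every
#' window induces strong serial dependence.
#'
#' @param windows data.frame with `time` (`POSIXct`) and optional `bear_id`.
#' @param n_per_hour Windows retained per cell (>= 1).
#' @param seed Integer seed; the draw is reproducible and cell-order
#'   independent.
#' @param calendar A [study_calendar()] (local date/hour boundaries).
#' @return The subsampled rows of `windows`, time-ordered within bear.
#' @export
subsample_hourly <- function(windows, n_per_hour = 10, seed = 1,
                             calendar = study_calendar()) {
  stopifnot("time" %in% names(windows), n_per_hour >= 1)
  if (!"bear_id" %in% names(windows)) windows$bear_id <- "bear"
  tz <- calendar$tz
  key <- paste(windows$bear_id,
               format(as.POSIXct(windows$time, tz = tz), "%Y-%m-%d %H",
                      tz = tz))
  set.seed(seed)
  keep <- unlist(lapply(split(seq_len(nrow(windows)), key), function(i) {
    if (length(i) <= n_per_hour) i else sample(i, n_per_hour)
  }), use.names = FALSE)
  out <- windows[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Export analysis-ready model tables
#'
#' Produces the window-level table consumed by downstream additive/mixed
#' models — one row per (subsampled) window with bear, date, time of day in
#' seconds, study period, demographic group and 0/1 indicators for
#' feedwalking and resting — together with the per bear-day records table.
#'
#' @param windows Label stream (typically [subsample_hourly()] output) with
#'   `bear_id`, `time`, `label` (three-category).
#' @param records Daily records from [daily_metrics()] (optional; supplies
#'   the demographic group).
#' @param calendar A [study_calendar()].
#' @return List with `windows` and `daily` data.frames.
#' @export
export_model_table <- function(windows, records = NULL,
                               calendar = study_calendar()) {
  stopifnot(all(c("time", "label") %in% names(windows)))
  if (!"bear_id" %in% names(windows)) windows$bear_id <- "bear"
  tz <- calendar$tz
  tm <- as.POSIXct(windows$time, tz = tz)
  date <- as.Date(tm, tz = tz)
  midnight <- as.POSIXct(paste(date, "00:00:00"), tz = tz)
  lab <- as.character(windows$label)
  out <- data.frame(
    bear_id = windows$bear_id,
    year = as.integer(format(date, "%Y")),
    date = date,
    time_of_day_s = as.numeric(tm) - as.numeric(midnight),
    period = assign_period(date, calendar),
    demographic_group = NA_character_,
    is_feedwalking = as.integer(lab == "feedwalking"),
    is_resting = as.integer(lab == "resting")
  )
  if (!is.null(records)) {
    i <- match(paste(out$bear_id, out$date),
               paste(records$bear_id, records$date))
    out$demographic_group <- records$demographic_group[i]
  }
  list(windows = out, daily = records)
}

#' Diel activity profile with bootstrap confidence band
#'
#' Proportion of windows in the feedwalking state per time-of-day bin, with
#' a percentile bootstrap confidence interval obtained by resampling
#' bear-days with replacement (the natural exchangeable unit: windows within
#' a day are serially dependent). With `n_boot <= 1` no resampling spread is
#' estimable and the interval collapses to the point estimate.
#'
#' @param labels data.frame with `time`, `label` (three-category), optional
#'   `bear_id`.
#' @param bin_minutes Bin width in minutes (must divide 1440).
#' @param n_boot Bootstrap replicates.
#' @param seed Integer seed.
#' @param level Confidence level.
#' @param calendar A [study_calendar()].
#' @return data.frame per bin: `bin_start_s`, `hour`, `n`, `prop_feedwalk`,
#'   `lower`, `upper` (`NA` for empty bins).
#' @export
diel_profile <- function(labels, bin_minutes = 60, n_boot = 500, seed = 1,
                         level = 0.95, calendar = study_calendar()) {
  stopifnot(all(c("time", "label") %in% names(labels)),
            nrow(labels) >= 1L, 1440 %% bin_minutes == 0)
  if (!"bear_id" %in% names(labels)) labels$bear_id <- "bear"
  tz <- calendar$tz
  tm <- as.POSIXct(labels$time, tz = tz)
  date <- as.Date(tm, tz = tz)
  tod <- as.numeric(tm) - as.numeric(as.POSIXct(paste(date, "00:00:00"),
                                                tz = tz))
  n_bins <- as.integer(1440 / bin_minutes)
  bin <- pmin(floor(tod / (bin_minutes * 60)), n_bins - 1L)
  act <- as.character(labels$label) == "feedwalking"
  day_key <- paste(labels$bear_id, date)
  days <- unique(day_key)

  prop_by_bin <- function(idx) {
    num <- tapply(act[idx], factor(bin[idx], levels = 0:(n_bins - 1L)), sum)
    den <- tapply(rep(1L, length(idx)),
                  factor(bin[idx], levels = 0:(n_bins - 1L)), sum)
    as.numeric(num) / as.numeric(den)   # NA where den is NA (empty bin)
  }
  est <- prop_by_bin(seq_along(act))
  n_per_bin <- as.integer(table(factor(bin, levels = 0:(n_bins - 1L))))

  if (n_boot <= 1) {
    lower <- upper <- est
  } else {
    set.seed(seed)
    idx_by_day <- split(seq_along(act), day_key)
    boots <- vapply(seq_len(n_boot), function(b) {
      take <- sample(days, length(days), replace = TRUE)
      prop_by_bin(unlist(idx_by_day[take], use.names = FALSE))
    }, numeric(n_bins))
    a <- (1 - level) / 2
    lower <- apply(boots, 1L, quantile, probs = a, na.rm = TRUE,
                   names = FALSE)
    upper <- apply(boots, 1L, quantile, probs = 1 - a, na.rm = TRUE,
                   names = FALSE)
    lower[is.na(est)] <- NA_real_
    upper[is.na(est)] <- NA_real_
  }
  data.frame(bin_start_s = (0:(n_bins - 1L)) * bin_minutes * 60,
             hour = (0:(n_bins - 1L)) * bin_minutes / 60,
             n = n_per_bin,
             prop_feedwalk = est, lower = lower, upper = upper)
}
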