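# Training-set preparation: clean annotation events, align the video clock
# to the accelerometer clock, and tile labelled 3 s windows inside events.

#' Clean annotation events against the ethogram
#'
#' Canonicalises behaviour labels (case- and whitespace-insensitive), keeps
#' events whose behaviour is in the four-category ethogram, silently drops
#' the known rare behaviours (playing, fighting, shaking, scratching,
#' swimming, tree rubbing, drinking by default), and drops any other label
#' with a warning naming it.
#'
#' @param events data.frame with `behavior`, `start`, `end` columns;
#'   `end > start` for every event.
#' @param ethogram Retained labels (default [bear_behaviors()]).
#' @param excluded Labels dropped without warning
#'   (default [default_excluded_behaviors()]).
#' @return The retained events with canonical labels.
#' @export
clean_events <- function(events, ethogram = bear_behaviors(),
                         excluded = default_excluded_behaviors()) {
  stopifnot(all(c("behavior", "start", "end") %in% names(events)))
  if (any(as.numeric(events$end) <= as.numeric(events$start))) {
    stop("every event must have end > start", call. = FALSE)
  }
  canon <- tolower(trimws(as.character(events$behavior)))
  keep <- canon %in% ethogram
  drop_known <- canon %in% tolower(excluded)
  unknown <- unique(canon[!keep & !drop_known])
  if (length(unknown) > 0L) {
    warning("dropping events with unknown behaviour label(s): ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- events[keep, , drop = FALSE]
  out$behavior <- canon[keep]
  if (nrow(out) == 0L) {
    warning("no events remain after cleaning", call. = FALSE)
  }
  rownames(out) <- NULL
  out
}

#' Shift annotation events onto the accelerometer clock
#'
#' Adds `lag_s` seconds to every event start and end. Applying the negative
#' lag restores the original times exactly.
#'
#' @param events Event data.frame with `start`, `end`.
#' @param lag_s Finite clock shift in seconds.
#' @return Events with shifted times.
#' @export
apply_clock_lag <- function(events, lag_s) {
  stopifnot(is.numeric(lag_s), length(lag_s) == 1L, is.finite(lag_s))
  events$start <- events$start + lag_s
  events$end <- events$end + lag_s
  events
}

#' Estimate the video-to-accelerometer clock lag
#'
#' Automates the visual alignment of annotation and accelerometer streams:
#' for each candidate lag it shifts the events back by that lag onto the
#' accelerometer clock and correlates the resulting binary active/inactive
#' indicator (active = any non-resting behaviour) with the per-second mean
#' ODBA of the series. The returned lag is the candidate maximising that
#' correlation (ties go to the smallest lag); correct the events with
#' `apply_clock_lag(events, -lag)`.
#'
#' @param events Cleaned events on the annotation clock, containing both
#'   resting and non-resting behaviours.
#' @param series Accelerometer stream (`timestamp`/`time_s`,
#'   `acc_x/acc_y/acc_z`).
#' @param search_range_s Two-element numeric, inclusive lag search bounds in
#'   seconds.
#' @param step_s Search step in seconds.
#' @param fs Sampling frequency of `series`, Hz.
#' @return The estimated lag in seconds, with attribute `"objective"`: the
#'   per-candidate correlation table.
#' @export
estimate_clock_lag <- function(events, series, search_range_s = c(0, 180),
                               step_s = 1, fs = 8) {
  stopifnot(length(search_range_s) == 2L, step_s > 0)
  if (diff(search_range_s) < 0) {
    stop("empty lag search range", call. = FALSE)
  }
  active_ev <- events$behavior != "resting"
  if (!any(active_ev) || all(active_ev)) {
    stop("lag estimation needs both active and inactive events ",
         "(the correlation objective is flat otherwise)", call. = FALSE)
  }
  tm <- .series_time(series)
  acc <- .acc_matrix(series)
  ob <- odba(dynamic_body_acceleration(acc, static_acceleration(acc, fs = fs)))
  sec <- floor(tm)
  odba_sec <- tapply(ob, sec, mean)
  sec_mid <- as.numeric(names(odba_sec)) + 0.5
  ev_start <- as.numeric(events$start)
  ev_end <- as.numeric(events$end)
  ord <- order(ev_start)
  ev_start <- ev_start[ord]; ev_end <- ev_end[ord]
  ev_active <- active_ev[ord]
  lags <- seq(search_range_s[1], search_range_s[2], by = step_s)
  obj <- vapply(lags, function(l) {
    # event covering each second midpoint once events are shifted by -l
    i <- findInterval(sec_mid + l, ev_start)
    ok <- i >= 1L & (sec_mid + l) < ev_end[pmax(i, 1L)]
    if (sum(ok) < 3L) return(NA_real_)
    a <- as.numeric(ev_active[i[ok]])
    if (stats::sd(a) == 0 || stats::sd(odba_sec[ok]) == 0) return(NA_real_)
    cor(odba_sec[ok], a)
  }, numeric(1L))
  if (all(is.na(obj))) {
    stop("lag objective undefined over the whole search range", call. = FALSE)
  }
  best <- lags[which.max(obj)]   # which.max: first (smallest) lag on ties
  structure(best, objective = data.frame(lag_s = lags, correlation = obj))
}

#' Build labelled training windows from events and accelerometry
#'
#' Tiles 3 s windows inside each annotated event (the tiling restarts at
#' every event start, so short events are fully usable) and keeps a window
#' only when it is entirely contained in a single event — behavioural
#' transitions are excluded by construction. Features come from the same
#' chain as [compute_features()], with the static component computed on the
#' continuous series. Events shorter than one window contribute nothing; a
#' trailing remainder inside an event is discarded.
#'
#' @param events Cleaned events on the accelerometer clock.
#' @param series Accelerometer stream.
#' @param window_s Window length, seconds.
#' @param fs Sampling frequency, Hz.
#' @return data.frame of labelled windows: `window_start`, the 36 features,
#'   `label`; per-class counts are attached as attribute `"class_counts"`
#'   and reported via `message()`.
#' @export
build_training_windows <- function(events, series, window_s = 3, fs = 8) {
  .assert_behaviors(events$behavior)
  tm <- .series_time(series)
  if (is.unsorted(tm)) stop("series must be sorted by time", call. = FALSE)
  acc <- .acc_matrix(series)
  static <- static_acceleration(acc, span_s = window_s, fs = fs)
  spw <- as.integer(round(window_s * fs))
  tol <- 1.01 / fs
  n <- length(tm)

  starts <- integer(); labels <- character()
  for (i in seq_len(nrow(events))) {
    ev_a <- as.numeric(events$start[i])
    ev_b <- as.numeric(events$end[i])
    in_ev <- which(tm >= ev_a - 1e-9 & tm < ev_b - 1e-9)
    if (length(in_ev) < spw) next
    k <- length(in_ev) %/% spw
    cand <- in_ev[1L] + (seq_len(k) - 1L) * spw
    # windows must be gap-free and fully inside the event
    ok <- vapply(cand, function(s) {
      e <- s + spw - 1L
      e <= n && tm[e] < ev_b - 1e-9 &&
        max(diff(tm[s:e])) <= tol
    }, logical(1L))
    starts <- c(starts, cand[ok])
    labels <- c(labels, rep(events$behavior[i], sum(ok)))
  }
  if (length(starts) == 0L) {
    out <- as.data.frame(matrix(numeric(), 0L, 36L,
                                dimnames = list(NULL, feature_names())))
    out <- cbind(data.frame(window_start = tm[0]), out,
                 data.frame(label = character()))
    attr(out, "class_counts") <- table(factor(character(),
                                              levels = bear_behaviors()))
    return(out)
  }
  fm <- .window_features_at(acc, static, starts, spw, fs)
  ws <- if ("timestamp" %in% names(series)) series$timestamp[starts]
        else tm[starts]
  out <- cbind(data.frame(window_start = ws), as.data.frame(fm))
  out$label <- labels
  rownames(out) <- NULL
  counts <- table(factor(labels, levels = bear_behaviors()))
  attr(out, "class_counts") <- counts
  message("labelled windows per class: ",
          paste(names(counts), counts, sep = "=", collapse = ", "))
  out
}
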