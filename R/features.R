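# Signal chain: static acceleration -> DBA -> ODBA / magnitude, 3 s window
# partitioning and the 36 summary-statistic features.

.acc_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3L)
    return(unname(x))
  }
  stopifnot(is.data.frame(x),
            all(c("acc_x", "acc_y", "acc_z") %in% names(x)))
  cbind(x$acc_x, x$acc_y, x$acc_z)
}

.series_time <- function(series) {
  if ("timestamp" %in% names(series)) return(as.numeric(series$timestamp))
  if ("time_s" %in% names(series)) return(as.numeric(series$time_s))
  stop("series needs a 'timestamp' or 'time_s' column", call. = FALSE)
}

# Truncated centred running mean: sample i averages indices
# [i - back, i + fwd] clipped to the series, where back = floor(width/2) and
# fwd = width - back - 1 (for width 24: 12 before, current, 11 after).
.running_mean <- function(v, width) {
  n <- length(v)
  back <- width %/% 2L
  fwd <- width - back - 1L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - back, 1L)
  hi <- pmin(seq_len(n) + fwd, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Static (postural) acceleration
#'
#' Estimates the gravitational/postural component of each axis as a 3 s
#' running mean of the raw acceleration. The mean is centred (12 samples
#' before, the current sample, 11 after at 8 Hz) and truncated symmetrically
#' at the ends of the series, so no phase lag is introduced and edge samples
#' use the neighbours that exist.
#'
#' @param series data.frame with columns `acc_x`, `acc_y`, `acc_z` (g), or a
#'   3-column matrix.
#' @param span_s Running-mean span in seconds (default 3).
#' @param fs Sampling frequency in Hz (default 8).
#' @return 3-column matrix of static acceleration (g), one row per sample.
#' @export
static_acceleration <- function(series, span_s = 3, fs = 8) {
  acc <- .acc_matrix(series)
  width <- as.integer(round(span_s * fs))
  stopifnot(width >= 1L)
  out <- acc
  for (j in 1:3) out[, j] <- .running_mean(acc[, j], width)
  out
}

#' Dynamic body acceleration (DBA)
#'
#' Raw acceleration minus the static component, per axis. DBA carries the
#' movement signal once posture and gravity are removed; summing with the
#' static component reconstructs the raw stream exactly.
#'
#' @param raw,static Aligned 3-column matrices (or data.frames with
#'   `acc_x/acc_y/acc_z`).
#' @return 3-column matrix of DBA values.
#' @export
dynamic_body_acceleration <- function(raw, static) {
  raw <- .acc_matrix(raw)
  static <- .acc_matrix(static)
  if (!identical(dim(raw), dim(static))) {
    stop("raw and static acceleration have mismatched dimensions",
         call. = FALSE)
  }
  raw - static
}

#' Overall dynamic body acceleration (ODBA)
#'
#' Per-sample sum of the absolute DBA over the three axes, the standard
#' movement-intensity proxy in biologging.
#'
#' @param dba 3-column DBA matrix.
#' @return Numeric vector, one non-negative value per sample.
#' @export
odba <- function(dba) {
  dba <- .acc_matrix(dba)
  rowSums(abs(dba))
}

#' Acceleration magnitude
#'
#' Euclidean norm of the tri-axial acceleration,
#' `sqrt(x^2 + y^2 + z^2)`, per sample.
#'
#' @param series data.frame with `acc_x/acc_y/acc_z` or 3-column matrix.
#' @return Numeric vector of magnitudes (g).
#' @export
magnitude <- function(series) {
  acc <- .acc_matrix(series)
  sqrt(rowSums(acc^2))
}

#' Dominant power spectral density of a window channel
#'
#' Mean-removed one-sided periodogram of the window (no taper, no detrend
#' beyond mean removal), returning the maximal density over the positive
#' frequencies. With 24 samples at 8 Hz the frequency resolution is 1/3 Hz.
#' The density at frequency bin k is `2 |X_k|^2 / (n fs)` (the Nyquist bin,
#' when present, is not doubled), so doubling a sinusoid's amplitude
#' quadruples the returned value. A constant channel returns 0.
#'
#' @param v Numeric vector of channel samples (length >= 4).
#' @param fs Sampling frequency in Hz.
#' @return Maximal spectral density (scalar, >= 0).
#' @export
dominant_power_spectrum <- function(v, fs = 8) {
  n <- length(v)
  if (n < 4L) stop("need at least 4 samples", call. = FALSE)
  v <- v - mean(v)
  if (all(v == 0)) return(0)
  p <- Mod(fft(v))^2 / (n * fs)
  k <- seq_len(n %/% 2L)           # positive frequencies (+ Nyquist if even)
  one_sided <- 2 * p[k + 1L]
  if (n %% 2L == 0L) one_sided[length(k)] <- p[n %/% 2L + 1L]
  max(one_sided)
}

#' Partition a series into consecutive 3 s windows
#'
#' Tiles consecutive, non-overlapping windows of `window_s * fs` samples
#' anchored at the first sample. A window is complete only when it has the
#' full sample count and no internal timestamp gap (all sampling intervals
#' within 1% of `1/fs`); a trailing partial window is discarded, and windows
#' spanning recording gaps are flagged incomplete and excluded from feature
#' computation downstream.
#'
#' @param series data.frame with a `timestamp` (POSIXct) or `time_s`
#'   (numeric seconds) column, sorted by time.
#' @param window_s Window length in seconds (default 3).
#' @param fs Sampling frequency in Hz (default 8).
#' @return data.frame with one row per window: `window`, `start_idx`,
#'   `end_idx`, `start_time`, `complete`.
#' @export
partition_windows <- function(series, window_s = 3, fs = 8) {
  tm <- .series_time(series)
  if (is.unsorted(tm)) stop("series must be sorted by time", call. = FALSE)
  spw <- as.integer(round(window_s * fs))
  n <- length(tm)
  if (n == 0L) {
    return(data.frame(window = integer(), start_idx = integer(),
                      end_idx = integer(), start_time = tm[0],
                      complete = logical()))
  }
  # assign every sample to its 3 s grid slot counted from the first sample
  slot <- floor((tm - tm[1L]) / window_s + 1e-9)
  first <- which(!duplicated(slot))
  last <- c(first[-1L] - 1L, n)
  count <- last - first + 1L
  tol <- 1.01 / fs
  cg <- cumsum(c(0, diff(tm) > tol))   # gaps among intervals 1..i-1
  complete <- count == spw & (cg[last] - cg[first]) == 0
  data.frame(window = as.integer(slot[first]) + 1L,
             start_idx = first, end_idx = last,
             start_time = if ("timestamp" %in% names(series))
               series$timestamp[first] else tm[first],
             complete = complete)
}

# Vectorised feature engine. Channels arrive as (samples x windows)
# matrices; raw and precomputed static share the window layout.
.features_block <- function(xm, ym, zm, sxm, sym, szm, fs) {
  n <- nrow(xm)
  magm <- sqrt(xm^2 + ym^2 + zm^2)
  dxm <- xm - sxm
  dym <- ym - sym
  dzm <- zm - szm
  odbam <- abs(dxm) + abs(dym) + abs(dzm)

  moments <- function(m) {
    mu <- colMeans(m)
    cm <- sweep(m, 2L, mu)
    m2 <- colMeans(cm^2)
    m3 <- colMeans(cm^3)
    m4 <- colMeans(cm^4)
    pos <- m2 > 0
    list(mean = mu,
         std = sqrt(colSums(cm^2) / (n - 1L)),
         max = apply(m, 2L, max),
         min = apply(m, 2L, min),
         kurt = ifelse(pos, m4 / m2^2, 0),
         skew = ifelse(pos, m3 / m2^1.5, 0),
         cm = cm, ss = colSums(cm^2))
  }
  mx <- moments(xm); my <- moments(ym); mz <- moments(zm)
  mm <- moments(magm)

  corr <- function(a, b) {
    den <- sqrt(a$ss * b$ss)
    ifelse(den > 0, colSums(a$cm * b$cm) / den, 0)
  }

  dps <- function(m) {
    cm <- sweep(m, 2L, colMeans(m))
    p <- Mod(mvfft(cm))^2 / (n * fs)
    k <- seq_len(n %/% 2L)
    one_sided <- 2 * p[k + 1L, , drop = FALSE]
    if (n %% 2L == 0L) {
      one_sided[length(k), ] <- p[n %/% 2L + 1L, ]
    }
    apply(one_sided, 2L, max)
  }

  out <- cbind(
    mean_x = mx$mean, mean_y = my$mean, mean_z = mz$mean, mean_mag = mm$mean,
    std_x = mx$std, std_y = my$std, std_z = mz$std, std_mag = mm$std,
    max_x = mx$max, max_y = my$max, max_z = mz$max, max_mag = mm$max,
    min_x = mx$min, min_y = my$min, min_z = mz$min, min_mag = mm$min,
    kurt_x = mx$kurt, kurt_y = my$kurt, kurt_z = mz$kurt, kurt_mag = mm$kurt,
    skew_x = mx$skew, skew_y = my$skew, skew_z = mz$skew, skew_mag = mm$skew,
    cor_xy = corr(mx, my), cor_xz = corr(mx, mz), cor_yz = corr(my, mz),
    mean_dba_x = colMeans(dxm), mean_dba_y = colMeans(dym),
    mean_dba_z = colMeans(dzm),
    odba_total = colSums(odbam), odba_mean = colMeans(odbam),
    dps_x = dps(xm), dps_y = dps(ym), dps_z = dps(zm), dps_mag = dps(magm)
  )
  out[, feature_names(), drop = FALSE]
}

# Features for windows given by start indices into an augmented series
# (raw axes + series-wide static).
.window_features_at <- function(acc, static, start_idx, spw, fs) {
  idx <- outer(seq_len(spw) - 1L, start_idx, "+")
  .features_block(
    matrix(acc[idx, 1L], nrow = spw), matrix(acc[idx, 2L], nrow = spw),
    matrix(acc[idx, 3L], nrow = spw),
    matrix(static[idx, 1L], nrow = spw), matrix(static[idx, 2L], nrow = spw),
    matrix(static[idx, 3L], nrow = spw),
    fs)
}

#' Summarise one complete window into the 36-feature vector
#'
#' Computes the full feature vector from a single window of samples. The
#' static/DBA chain is evaluated on the window itself (truncated running
#' mean at its edges); when windows are cut from a longer recording, prefer
#' [compute_features()], which uses the neighbouring samples of the
#' continuous stream for the running mean.
#'
#' Degenerate inputs are kept classifiable: a zero-variance channel gets
#' correlation, skewness and kurtosis 0 and spectral density 0.
#'
#' @param window data.frame with `acc_x/acc_y/acc_z` (one row per sample) or
#'   3-column matrix; typically 24 rows (3 s at 8 Hz).
#' @param fs Sampling frequency in Hz.
#' @param span_s Running-mean span for the static component, seconds.
#' @return Named numeric vector of the 36 features, in [feature_names()]
#'   order.
#' @export
#' @examples
#' w <- matrix(rnorm(72, sd = 0.05), ncol = 3) + rep(c(0, 0, 1), each = 24)
#' summarize_window(w)[c("mean_z", "odba_mean")]
summarize_window <- function(window, fs = 8, span_s = 3) {
  acc <- .acc_matrix(window)
  static <- static_acceleration(acc, span_s = span_s, fs = fs)
  fm <- .window_features_at(acc, static, 1L, nrow(acc), fs)
  stats::setNames(as.numeric(fm[1L, ]), colnames(fm))
}

#' Window a series and compute all 36 features
#'
#' The main feature-extraction entry point: partitions the stream into
#' consecutive 3 s windows ([partition_windows()]), evaluates the static /
#' DBA / ODBA / magnitude chain on the continuous series, and returns one
#' feature row per complete window. Incomplete windows (gaps, trailing
#' partials) are dropped, never padded.
#'
#' @param series data.frame with `timestamp` (or `time_s`) and
#'   `acc_x/acc_y/acc_z` columns; a `behavior` column, when present, is
#'   carried through as the window's ground-truth label provided the label is
#'   constant across the window (mixed windows get `NA`).
#' @param window_s Window length, seconds.
#' @param fs Sampling frequency, Hz.
#' @param units `"g"` (default) or `"ms2"`; the latter is divided by the
#'   standard gravity 9.80665 before any computation.
#' @param bear_id Optional id attached to every row (taken from a `bear_id`
#'   column when present).
#' @return data.frame: `bear_id` (if known), `window`, `window_start`, then
#'   the 36 feature columns, plus `label` when `series` carried truth labels.
#' @export
compute_features <- function(series, window_s = 3, fs = 8,
                             units = c("g", "ms2"), bear_id = NULL) {
  units <- match.arg(units)
  acc <- .acc_matrix(series)
  if (units == "ms2") acc <- acc / 9.80665
  if (is.null(bear_id) && "bear_id" %in% names(series)) {
    bear_id <- series$bear_id[1L]
  }
  part <- partition_windows(series, window_s = window_s, fs = fs)
  part <- part[part$complete, , drop = FALSE]
  if (nrow(part) == 0L) {
    out <- as.data.frame(matrix(numeric(), 0L, 36L,
                                dimnames = list(NULL, feature_names())))
    return(cbind(data.frame(window = integer(),
                            window_start = part$start_time), out))
  }
  static <- static_acceleration(acc, span_s = window_s, fs = fs)
  spw <- as.integer(round(window_s * fs))
  fm <- .window_features_at(acc, static, part$start_idx, spw, fs)
  out <- data.frame(window = part$window, window_start = part$start_time)
  if (!is.null(bear_id)) out <- cbind(bear_id = bear_id, out)
  out <- cbind(out, as.data.frame(fm))
  if ("behavior" %in% names(series)) {
    lab <- vapply(seq_len(nrow(part)), function(i) {
      b <- unique(series$behavior[part$start_idx[i]:part$end_idx[i]])
      if (length(b) == 1L) as.character(b) else NA_character_
    }, character(1L))
    out$label <- lab
  }
  rownames(out) <- NULL
  out
}
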