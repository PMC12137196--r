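# Delimited-text I/O in the collar-export dialects: ISO-8601 timestamps
# with milliseconds, acceleration in g, annotations as behaviour event
# tables, GPS fixes in planar metres.

.iso_fmt <- "%Y-%m-%dT%H:%M:%OS"

.format_iso <- function(x) format(x, format = paste0(.iso_fmt, "3"))

.parse_iso <- function(x, tz) as.POSIXct(x, format = .iso_fmt, tz = tz)

#' Read and write accelerometry CSV
#'
#' Columns: `timestamp` (ISO-8601 with milliseconds, local clock), `acc_x`,
#' `acc_y`, `acc_z` in g. Extra columns (e.g. a `behavior` ground-truth
#' column from the simulator) are preserved.
#'
#' @param path File path.
#' @param tz Time zone of the timestamps (study local clock by default).
#' @return `read_accel`: data.frame with `timestamp` (`POSIXct`), `time_s`
#'   (seconds from the first sample) and the acceleration columns.
#' @export
read_accel <- function(path, tz = study_calendar()$tz) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "acc_x", "acc_y", "acc_z") %in% names(x)))
  x$timestamp <- .parse_iso(x$timestamp, tz)
  x$time_s <- as.numeric(x$timestamp) - as.numeric(x$timestamp[1L])
  x
}

#' @rdname read_accel
#' @param series Accelerometry data.frame with `timestamp` and
#'   `acc_x/acc_y/acc_z`.
#' @export
write_accel <- function(series, path) {
  out <- series[, intersect(c("timestamp", "acc_x", "acc_y", "acc_z",
                              "behavior"), names(series))]
  out$timestamp <- .format_iso(out$timestamp)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write annotation event tables
#'
#' Columns: `behavior`, `start`, `end` (ISO-8601).
#'
#' @param path File path.
#' @param tz Time zone.
#' @return `read_annotations`: data.frame with `behavior` and `POSIXct`
#'   `start`/`end`.
#' @export
read_annotations <- function(path, tz = study_calendar()$tz) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("behavior", "start", "end") %in% names(x)))
  x$start <- .parse_iso(x$start, tz)
  x$end <- .parse_iso(x$end, tz)
  x
}

#' @rdname read_annotations
#' @param events Event data.frame.
#' @export
write_annotations <- function(events, path) {
  out <- data.frame(behavior = events$behavior,
                    start = .format_iso(events$start),
                    end = .format_iso(events$end))
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write GPS tracks
#'
#' Columns: `timestamp` (ISO-8601), `x_m`, `y_m` (planar metres); an
#' optional `bear_id` column is preserved.
#'
#' @param path File path.
#' @param tz Time zone.
#' @return `read_gps`: data.frame with `POSIXct` `timestamp`, `x_m`, `y_m`.
#' @export
read_gps <- function(path, tz = study_calendar()$tz) {
  x <- read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("timestamp", "x_m", "y_m") %in% names(x)))
  x$timestamp <- .parse_iso(x$timestamp, tz)
  x
}

#' @rdname read_gps
#' @param track GPS data.frame.
#' @export
write_gps <- function(track, path) {
  out <- track[, intersect(c("bear_id", "timestamp", "x_m", "y_m"),
                           names(track))]
  out$timestamp <- .format_iso(out$timestamp)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
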