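#' Study calendar and site parameters
#'
#' Bundles the temporal stratification and solar-geometry inputs of the study
#' design: the pre-hunting period (August 1--20), the analysed part of the
#' hunting season (August 21--31), the site centroid (about 61 degrees N,
#' 15 degrees E in south-central Sweden) and the fixed local clock offset
#' (UTC+2, local summer time).
#'
#' @param site_lat Latitude of the study-area centroid, decimal degrees
#'   (positive north).
#' @param site_lon Longitude of the centroid, decimal degrees (positive east).
#' @param utc_offset Local clock offset from UTC in hours.
#' @param pre_hunting Month-day bounds (inclusive) of the pre-hunting period.
#' @param hunting Month-day bounds (inclusive) of the hunting period.
#' @return An object of class `study_calendar`.
#' @export
#' @examples
#' cal <- study_calendar()
#' assign_period(as.Date(c("2021-08-20", "2021-08-21")), cal)
study_calendar <- function(site_lat = 61, site_lon = 15, utc_offset = 2,
                           pre_hunting = c("08-01", "08-20"),
                           hunting = c("08-21", "08-31")) {
  stopifnot(is.numeric(site_lat), is.numeric(site_lon),
            abs(site_lat) <= 90)
  cal <- list(site_lat = site_lat, site_lon = site_lon,
              utc_offset = utc_offset,
              pre_hunting = pre_hunting, hunting = hunting,
              tz = sprintf("Etc/GMT%+d", -as.integer(utc_offset)))
  class(cal) <- "study_calendar"
  cal
}

#' @export
print.study_calendar <- function(x, ...) {
  cat(sprintf("Study calendar: %.1f N, %.1f E, UTC%+d\n",
              x$site_lat, x$site_lon, x$utc_offset))
  cat(sprintf("  pre-hunting %s..%s, hunting %s..%s\n",
              x$pre_hunting[1], x$pre_hunting[2],
              x$hunting[1], x$hunting[2]))
  invisible(x)
}

#' Assign study period to dates
#'
#' Maps each date to `"pre_hunting"` (Aug 1--20) or `"hunting"` (Aug 21--31);
#' dates outside the study window get `NA`. Every August date belongs to
#' exactly one period.
#'
#' @param dates `Date` vector (or coercible).
#' @param calendar A [study_calendar()].
#' @return Character vector, same length as `dates`.
#' @export
assign_period <- function(dates, calendar = study_calendar()) {
  dates <- as.Date(dates)
  md <- format(dates, "%m-%d")
  out <- rep(NA_character_, length(dates))
  out[md >= calendar$pre_hunting[1] & md <= calendar$pre_hunting[2]] <-
    "pre_hunting"
  out[md >= calendar$hunting[1] & md <= calendar$hunting[2]] <- "hunting"
  out
}

# NOAA solar position (low-accuracy form, good to ~1 minute at these
# latitudes): fractional-year expansion for the equation of time and solar
# declination, hour angle at the standard refraction-corrected zenith.
.noaa_sun_utc_minutes <- function(dates, lat, lon, zenith_deg = 90.833) {
  dates <- as.Date(dates)
  doy <- as.integer(format(dates, "%j"))
  g <- 2 * pi / 365 * (doy - 1 + (12 - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  phi <- lat * pi / 180
  cos_ha <- cos(zenith_deg * pi / 180) / (cos(phi) * cos(decl)) -
    tan(phi) * tan(decl)
  if (any(cos_ha < -1 | cos_ha > 1)) {
    stop("sun does not cross the requested zenith on some dates ",
         "(polar day/night)", call. = FALSE)
  }
  ha_deg <- acos(cos_ha) * 180 / pi
  list(sunrise = 720 - 4 * (lon + ha_deg) - eqtime,
       sunset = 720 - 4 * (lon - ha_deg) - eqtime)
}

#' Local sunrise and sunset times
#'
#' NOAA solar-geometry sunrise/sunset (zenith 90.833 degrees, i.e. standard
#' atmospheric refraction plus the solar radius) at the study centroid,
#' returned on the calendar's fixed local clock.
#'
#' @param dates `Date` vector.
#' @param calendar A [study_calendar()].
#' @return data.frame with columns `date`, `sunrise`, `sunset` (`POSIXct` in
#'   the calendar's time zone).
#' @export
#' @examples
#' sun_times(as.Date("2021-08-21"))
sun_times <- function(dates, calendar = study_calendar()) {
  dates <- as.Date(dates)
  m <- .noaa_sun_utc_minutes(dates, calendar$site_lat, calendar$site_lon)
  midnight_utc <- as.POSIXct(paste(dates, "00:00:00"), tz = "UTC")
  data.frame(
    date = dates,
    sunrise = as.POSIXct(midnight_utc + m$sunrise * 60,
                         tz = calendar$tz),
    sunset = as.POSIXct(midnight_utc + m$sunset * 60,
                        tz = calendar$tz)
  )
}

#' Legal hunting hours for a date
#'
#' Swedish bear-hunting regulations allow hunting from one hour before local
#' sunrise until two hours before local sunset. The interval is half-open:
#' a timestamp exactly at `start` is inside, one exactly at `end` is outside.
#'
#' @param dates `Date` vector.
#' @param calendar A [study_calendar()].
#' @return data.frame with columns `date`, `start`, `end` (`POSIXct`, local).
#' @export
#' @examples
#' legal_hours(as.Date("2021-08-21"))
legal_hours <- function(dates, calendar = study_calendar()) {
  st <- sun_times(dates, calendar)
  out <- data.frame(date = st$date,
                    start = st$sunrise - 3600,
                    end = st$sunset - 7200)
  if (any(out$end <= out$start)) {
    stop("empty legal-hour interval on some dates", call. = FALSE)
  }
  out
}

#' Test timestamps for membership in the legal-hunting interval
#'
#' @param times `POSIXct` timestamps.
#' @param calendar A [study_calendar()].
#' @return Logical vector: `TRUE` when the timestamp falls in
#'   `[sunrise - 1 h, sunset - 2 h)` on its own local date.
#' @export
in_legal_hours <- function(times, calendar = study_calendar()) {
  dates <- as.Date(times, tz = calendar$tz)
  lh <- legal_hours(unique(dates), calendar)
  i <- match(dates, lh$date)
  times >= lh$start[i] & times < lh$end[i]
}
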