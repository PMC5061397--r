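#' Sunrise, sunset and day length for one or more dates
#'
#' Computes sunrise and sunset in local civil time with the NOAA
#' low-precision solar ephemeris (geometric mean longitude, equation of
#' centre, apparent longitude, equation of time), using the official zenith
#' of 90.833 degrees so that atmospheric refraction and the solar radius are
#' accounted for. The equation of time and declination are evaluated at the
#' date's local solar noon (one fixed-point refinement), which keeps rise and
#' set times within about a minute of high-precision ephemerides at
#' mid-latitudes.
#'
#' @param dates a `Date` vector (or anything coercible via [as.Date()]).
#' @param latitude site latitude in decimal degrees, positive north.
#'   Latitudes poleward of 66 degrees are rejected: the twilight/day/night
#'   partition assumes the sun rises and sets every day.
#' @param longitude site longitude in decimal degrees, positive east.
#' @param utc_offset fixed offset of local civil time from UTC in hours
#'   (no daylight saving).
#' @return a data frame with one row per date: `date`, `sunrise` and
#'   `sunset` (minutes after local midnight), and `day_length` (minutes).
#' @examples
#' solar_times(as.Date("2013-06-21"), 42.75, 141.45, 9)
#' @seealso [solar_calendar()], [diel_period_of()]
#' @export
solar_times <- function(dates, latitude, longitude, utc_offset) {
  dates <- as.Date(dates)
  stopifnot(length(dates) >= 1, !anyNA(dates))
  if (abs(latitude) >= 66) {
    stop("latitudes poleward of 66 degrees (polar day/night) are not supported")
  }
  d2r <- pi / 180
  ## Julian day of local midnight, then evaluate at approximate solar noon
  jd0 <- as.numeric(dates) + 2440587.5 - utc_offset / 24
  noon_min <- rep(720, length(dates))
  for (pass in 1:2) {
    t <- (jd0 + noon_min / 1440 - 2451545) / 36525
    L0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
    M <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
    ecc <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
    C <- sin(M * d2r) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
      sin(2 * M * d2r) * (0.019993 - 0.000101 * t) +
      sin(3 * M * d2r) * 0.000289
    omega <- 125.04 - 1934.136 * t
    lambda <- L0 + C - 0.00569 - 0.00478 * sin(omega * d2r)
    eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
    eps <- eps0 + 0.00256 * cos(omega * d2r)
    decl <- asin(sin(eps * d2r) * sin(lambda * d2r))
    y <- tan(eps * d2r / 2)^2
    eot <- 4 / d2r * (y * sin(2 * L0 * d2r) - 2 * ecc * sin(M * d2r) +
      4 * ecc * y * sin(M * d2r) * cos(2 * L0 * d2r) -
      0.5 * y^2 * sin(4 * L0 * d2r) - 1.25 * ecc^2 * sin(2 * M * d2r))
    noon_min <- 720 - 4 * longitude - eot + 60 * utc_offset
  }
  cosH <- (cos(90.833 * d2r) - sin(latitude * d2r) * sin(decl)) /
    (cos(latitude * d2r) * cos(decl))
  if (any(abs(cosH) >= 1)) {
    stop("sun does not rise or set on some requested dates; site unsupported")
  }
  H <- acos(cosH) / d2r # hour angle, degrees
  data.frame(
    date = dates,
    sunrise = noon_min - 4 * H,
    sunset = noon_min + 4 * H,
    day_length = 8 * H
  )
}

#' Build a solar calendar for a site
#'
#' Convenience wrapper producing one [solar_times()] row per date in a range,
#' the lookup table used by [diel_period_of()], [daily_frequencies()] and the
#' survey simulator. An external table of published sunrise/sunset times
#' (columns `date`, `sunrise`, `sunset` as "HH:MM" strings or minutes) can be
#' injected through `override` and is used verbatim.
#'
#' @param start,end first and last date (inclusive).
#' @param latitude,longitude,utc_offset site description, see [solar_times()].
#' @param override optional data frame of published solar times replacing the
#'   computed ones.
#' @return data frame of class `solar_calendar` with columns `date`,
#'   `sunrise`, `sunset`, `day_length` (minutes).
#' @export
solar_calendar <- function(start, end, latitude, longitude, utc_offset,
                           override = NULL) {
  start <- as.Date(start)
  end <- as.Date(end)
  stopifnot(start <= end)
  if (is.null(override)) {
    cal <- solar_times(seq(start, end, by = "day"), latitude, longitude, utc_offset)
  } else {
    stopifnot(all(c("date", "sunrise", "sunset") %in% names(override)))
    to_min <- function(x) {
      if (is.numeric(x)) return(x)
      hm <- strsplit(as.character(x), ":", fixed = TRUE)
      vapply(hm, function(p) as.numeric(p[1]) * 60 + as.numeric(p[2]), 0)
    }
    cal <- data.frame(
      date = as.Date(override$date),
      sunrise = to_min(override$sunrise),
      sunset = to_min(override$sunset)
    )
    cal$day_length <- cal$sunset - cal$sunrise
    cal <- cal[order(cal$date), , drop = FALSE]
  }
  stopifnot(all(cal$sunrise < cal$sunset), all(cal$day_length > 0 & cal$day_length < 1440))
  attr(cal, "site") <- list(
    latitude = if (is.null(override)) latitude else NA_real_,
    longitude = if (is.null(override)) longitude else NA_real_,
    utc_offset = if (is.null(override)) utc_offset else NA_real_
  )
  class(cal) <- c("solar_calendar", "data.frame")
  cal
}

cal_lookup <- function(calendar, dates) {
  i <- match(as.Date(dates), calendar$date)
  if (anyNA(i)) {
    stop(
      "solar calendar does not cover date(s): ",
      paste(unique(as.Date(dates)[is.na(i)]), collapse = ", ")
    )
  }
  i
}

#' Diel period of a timestamp
#'
#' Classifies each timestamp into one of the three diel periods: `twilight`
#' (from one hour before to one hour after sunrise, and likewise around
#' sunset), `day` (one hour after sunrise to one hour before sunset) and
#' `night` (one hour after sunset to one hour before the next sunrise). The
#' twilight intervals are closed at both ends; day and night take the open
#' remainder, so a timestamp exactly at sunrise or at sunrise + 60 min is
#' twilight. The night period spans midnight; a pre-dawn timestamp belongs to
#' the night that ends at that morning's sunrise.
#'
#' @param timestamps `POSIXct` vector in local civil time.
#' @param calendar a [solar_calendar()] covering every timestamp's date.
#' @return factor with levels `twilight`, `day`, `night`.
#' @export
diel_period_of <- function(timestamps, calendar) {
  stopifnot(inherits(timestamps, "POSIXct"))
  dt <- as.Date(timestamps, tz = "UTC")
  i <- cal_lookup(calendar, dt)
  m <- minute_of_day(timestamps)
  sr <- calendar$sunrise[i]
  ss <- calendar$sunset[i]
  tw <- (m >= sr - 60 & m <= sr + 60) | (m >= ss - 60 & m <= ss + 60)
  day <- m > sr + 60 & m < ss - 60
  out <- ifelse(tw, "twilight", ifelse(day, "day", "night"))
  factor(out, levels = c("twilight", "day", "night"))
}

minute_of_day <- function(timestamps) {
  lt <- as.POSIXlt(timestamps, tz = "UTC")
  lt$hour * 60 + lt$min + lt$sec / 60
}

#' Durations of the three diel periods on each date
#'
#' On every date the twilight windows total exactly 4 h, the day period lasts
#' day length minus 2 h, and night takes the remaining hours of the 24 h
#' cycle, so the three durations always sum to 24 h.
#'
#' @param calendar a [solar_calendar()].
#' @param dates dates to report (default: all calendar dates).
#' @return data frame with columns `date`, `twilight`, `day`, `night`
#'   (hours).
#' @export
diel_durations <- function(calendar, dates = calendar$date) {
  i <- cal_lookup(calendar, dates)
  len_h <- calendar$day_length[i] / 60
  data.frame(
    date = as.Date(dates),
    twilight = rep(4, length(i)),
    day = len_h - 2,
    night = 24 - 4 - (len_h - 2)
  )
}

#' Season of a date
#'
#' Calendar-quarter seasons: winter is January-March, spring April-June,
#' summer July-September, autumn October-December.
#'
#' @param dates a `Date` vector.
#' @return factor with levels `winter`, `spring`, `summer`, `autumn`.
#' @export
season_of <- function(dates) {
  m <- as.POSIXlt(as.Date(dates))$mon + 1
  s <- c(
    "winter", "winter", "winter", "spring", "spring", "spring",
    "summer", "summer", "summer", "autumn", "autumn", "autumn"
  )[m]
  factor(s, levels = c("winter", "spring", "summer", "autumn"))
}

#' Mean day length over a date range
#'
#' @param start,end first and last date (inclusive).
#' @param latitude,longitude,utc_offset site description, see [solar_times()].
#' @return mean day length in minutes.
#' @export
mean_day_length <- function(start, end, latitude, longitude, utc_offset) {
  start <- as.Date(start)
  end <- as.Date(end)
  if (start > end) stop("empty date range")
  st <- solar_times(seq(start, end, by = "day"), latitude, longitude, utc_offset)
  mean(st$day_length)
}
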