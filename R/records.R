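#' Read detection events from CSV
#'
#' One row per capture event (a single camera trigger; a burst of photos
#' taken on one trigger is one event carrying the first photo's timestamp).
#' The file must be comma-separated UTF-8 with a header naming the columns
#' `camera_id`, `species` and `timestamp`; timestamps are ISO-8601 local
#' civil time (`YYYY-MM-DD HH:MM` or `HH:MM:SS`). Timestamps are stored as
#' `POSIXct` with a fixed-offset clock (no daylight saving); the site's UTC
#' offset only enters the solar computations.
#'
#' @param path path to the event CSV.
#' @return data frame with columns `camera_id`, `species` (character) and
#'   `timestamp` (`POSIXct`), input order preserved.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) stop("event file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  need <- c("camera_id", "species", "timestamp")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("event file ", path, " lacks required column(s): ", paste(miss, collapse = ", "))
  }
  ev <- parse_events(raw[need], src = path)
  message(sprintf("read %d detection events from %s", nrow(ev), path))
  ev
}

parse_events <- function(df, src = "events") {
  ts <- parse_timestamp(df$timestamp)
  if (anyNA(ts)) {
    bad <- which(is.na(ts))[1]
    stop(sprintf(
      "%s: malformed timestamp %s at data line %d",
      src, dQuote(df$timestamp[bad]), bad + 1L
    ))
  }
  if (any(!nzchar(df$camera_id)) || any(!nzchar(df$species))) {
    stop(src, ": empty camera_id or species field")
  }
  data.frame(
    camera_id = df$camera_id, species = df$species, timestamp = ts
  )
}

parse_timestamp <- function(x) {
  x <- trimws(x)
  ts <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%d %H:%M:%S")
  retry <- is.na(ts)
  ts[retry] <- as.POSIXct(x[retry], tz = "UTC", format = "%Y-%m-%d %H:%M")
  ## reject calendar-invalid fields that strptime silently rolls over
  canon <- format(ts, "%Y-%m-%d %H:%M")
  ok <- !is.na(ts) & substr(x, 1, 16) == canon
  ts[!ok] <- NA
  ts
}

#' Read a camera effort ledger from CSV
#'
#' Columns `camera_id`, `start_date`, `end_date`: one row per continuous
#' active interval, closed on both end dates (a camera active on its start
#' and end date earns both trap-days).
#'
#' @param path path to the effort CSV.
#' @return data frame of class `effort_ledger` with `camera_id` (character),
#'   `start_date` and `end_date` (`Date`).
#' @export
read_effort <- function(path) {
  if (!file.exists(path)) stop("effort file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character")
  need <- c("camera_id", "start_date", "end_date")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    stop("effort file ", path, " lacks required column(s): ", paste(miss, collapse = ", "))
  }
  effort_ledger(raw$camera_id, as.Date(raw$start_date), as.Date(raw$end_date))
}

#' Construct an effort ledger
#'
#' @param camera_id character vector of camera identifiers.
#' @param start_date,end_date `Date` vectors; each row is a closed interval
#'   of whole dates during which the camera was active. Intervals of the
#'   same camera must not overlap.
#' @return data frame of class `effort_ledger`.
#' @export
effort_ledger <- function(camera_id, start_date, end_date) {
  start_date <- as.Date(start_date)
  end_date <- as.Date(end_date)
  stopifnot(length(camera_id) == length(start_date), length(start_date) == length(end_date))
  if (any(is.na(start_date) | is.na(end_date))) stop("effort ledger has unparseable dates")
  if (any(end_date < start_date)) stop("effort interval ends before it starts")
  led <- data.frame(
    camera_id = as.character(camera_id),
    start_date = start_date, end_date = end_date
  )
  led <- led[order(led$camera_id, led$start_date), , drop = FALSE]
  for (cam in unique(led$camera_id)) {
    rows <- led[led$camera_id == cam, , drop = FALSE]
    if (nrow(rows) > 1 &&
      any(rows$start_date[-1] <= rows$end_date[-nrow(rows)])) {
      stop("overlapping effort intervals for camera ", cam)
    }
  }
  class(led) <- c("effort_ledger", "data.frame")
  led
}

#' Total trap-days in an effort ledger
#'
#' One trap-day is one camera active for one calendar date.
#'
#' @param effort an [effort_ledger()].
#' @return total number of trap-days (integer-valued).
#' @export
trap_days <- function(effort) {
  sum(as.numeric(effort$end_date - effort$start_date) + 1)
}

#' Number of cameras active on each date
#'
#' @param effort an [effort_ledger()].
#' @param dates `Date` vector.
#' @return integer vector parallel to `dates`.
#' @export
cameras_active <- function(effort, dates) {
  dates <- as.Date(dates)
  vapply(dates, function(d) {
    sum(effort$start_date <= d & d <= effort$end_date)
  }, 0L)
}

#' Filter detection events for temporal independence
#'
#' Within each camera-by-species stream (sorted by time), an event is
#' retained if and only if it falls at least `window_minutes` after the last
#' *retained* event of that stream. This mirrors the camera's hardware
#' refractory delay and makes the filter idempotent: filtering an already
#' filtered stream changes nothing.
#'
#' @param events event data frame as from [read_events()].
#' @param window_minutes positive refractory window (the survey convention
#'   is 5 minutes).
#' @return the retained events, sorted by camera, species, time.
#' @export
filter_independent_events <- function(events, window_minutes = 5) {
  stopifnot(window_minutes > 0)
  if (nrow(events) == 0) return(events)
  ev <- events[order(events$camera_id, events$species, events$timestamp), , drop = FALSE]
  keep <- logical(nrow(ev))
  key <- paste(ev$camera_id, ev$species, sep = "\r")
  t <- as.numeric(ev$timestamp) / 60
  last_key <- ""
  last_t <- -Inf
  for (k in seq_len(nrow(ev))) {
    if (key[k] != last_key || t[k] - last_t >= window_minutes) {
      keep[k] <- TRUE
      last_key <- key[k]
      last_t <- t[k]
    }
  }
  out <- ev[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Season-by-species count summary
#'
#' Tabulates independent events by species and season, with per-species
#' totals, each species' percentage of all records (to 2 decimals), season
#' totals and the grand total — the survey-level bookkeeping used to audit a
#' multi-year camera-trap data set.
#'
#' @param events event data frame; seasons are derived from the timestamps
#'   via [season_of()] unless a `season` column is already present.
#' @return list of class `count_summary`: `table` (species x season counts
#'   with species totals and percentages), `season_totals`, `grand_total`.
#' @export
summarize_counts <- function(events) {
  season <- if ("season" %in% names(events)) {
    factor(events$season, levels = levels(season_of(Sys.Date())))
  } else {
    season_of(as.Date(events$timestamp, tz = "UTC"))
  }
  tab <- table(
    species = factor(events$species),
    season = season
  )
  counts <- as.data.frame.matrix(tab)
  counts$total <- rowSums(counts)
  grand <- sum(tab)
  if (grand > 0) {
    counts$percentage <- round(100 * counts$total / grand, 2)
  } else {
    counts$percentage <- rep(NA_real_, nrow(counts))
    warning("no events: percentages undefined")
  }
  out <- list(
    table = counts,
    season_totals = colSums(as.data.frame.matrix(tab)),
    grand_total = grand
  )
  class(out) <- "count_summary"
  out
}

#' @export
print.count_summary <- function(x, ...) {
  cat("Detection summary:", x$grand_total, "events,",
    nrow(x$table), "species\n\n")
  print(x$table)
  cat("\nSeason totals:\n")
  print(x$season_totals)
  invisible(x)
}

#' Survey-level detection rate
#'
#' @param total_events number of independent events.
#' @param trap_days total survey effort in trap-days.
#' @return events per trap-day.
#' @export
survey_rate <- function(total_events, trap_days) {
  if (trap_days <= 0) stop("trap_days must be positive")
  total_events / trap_days
}
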