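#' Daily photographic frequencies per diel period
#'
#' Converts independent detection events into the response analysed across
#' diel periods: for every active date `d`, species `s` and period `p`,
#'
#'   `f = count(s, p, d) / hours(p, d) / cameras_active(d) * 100`
#'
#' i.e. detections per hour of the period per 100 trap-days, the calendar
#' day (pooled over cameras) being the sampling unit. Period durations come
#' from that date's own sunrise and sunset, so `hours(twilight, d)` is
#' always 4 while day and night lengths track the season. Rows with zero
#' detections are included for every date on which at least one camera was
#' active; dates with no active camera are dropped with a warning if they
#' carry events.
#'
#' @param events independent events (see [filter_independent_events()]).
#' @param effort an [effort_ledger()].
#' @param calendar a [solar_calendar()] covering the effort range.
#' @param species optional character vector fixing the species set (default:
#'   those present in `events`).
#' @return data frame with columns `date`, `season`, `species`, `period`,
#'   `count`, `hours`, `cameras`, `frequency`.
#' @export
daily_frequencies <- function(events, effort, calendar, species = NULL) {
  if (is.null(species)) species <- sort(unique(events$species))
  dates <- sort(unique(do.call(c, Map(seq, effort$start_date, effort$end_date, by = "day"))))
  ncam <- cameras_active(effort, dates)
  dates <- dates[ncam > 0]
  ncam <- ncam[ncam > 0]
  if (nrow(events)) {
    ev_date <- as.Date(events$timestamp, tz = "UTC")
    off <- !(ev_date %in% dates)
    if (any(off)) {
      warning(sum(off), " event(s) fall on dates with no active camera; excluded")
      events <- events[!off, , drop = FALSE]
      ev_date <- ev_date[!off]
    }
  }
  periods <- c("twilight", "day", "night")
  grid <- expand.grid(
    date = dates, species = species, period = factor(periods, levels = periods),
    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE
  )
  if (nrow(events)) {
    per <- diel_period_of(events$timestamp, calendar)
    cnt <- as.data.frame(table(
      date = factor(as.character(ev_date), levels = as.character(dates)),
      species = factor(events$species, levels = species),
      period = per
    ), stringsAsFactors = FALSE)
    cnt$date <- as.Date(cnt$date)
    grid <- merge(grid, cnt, by = c("date", "species", "period"), all.x = TRUE)
    grid$Freq[is.na(grid$Freq)] <- 0
  } else {
    grid$Freq <- 0
  }
  names(grid)[names(grid) == "Freq"] <- "count"
  dur <- diel_durations(calendar, dates)
  hrs <- as.matrix(dur[, c("twilight", "day", "night")])
  rownames(hrs) <- as.character(dur$date)
  grid$hours <- hrs[cbind(as.character(grid$date), as.character(grid$period))]
  grid$cameras <- ncam[match(grid$date, dates)]
  grid$season <- season_of(grid$date)
  grid$frequency <- grid$count / grid$hours / grid$cameras * 100
  grid <- grid[order(grid$species, grid$date, grid$period),
    c("date", "season", "species", "period", "count", "hours", "cameras", "frequency")]
  rownames(grid) <- NULL
  grid
}

vm_kernel <- function(theta, mu, kappa) {
  ## von Mises density, overflow-safe via exponentially scaled Bessel I0
  exp(kappa * (cos(theta - mu) - 1)) / (2 * pi * besselI(kappa, 0, expon.scaled = TRUE))
}

#' Circular kernel density estimate of an activity curve
#'
#' Estimates the diel activity probability density from event times-of-day
#' using a von Mises kernel on the 24 h circle:
#' `density(theta) = mean_i vonMises(theta; mu = t_i, kappa)`.
#' Being a mixture of unit-mass kernels, the estimate integrates to one over
#' the circle by construction.
#'
#' @param event_times event times-of-day in radians on `[0, 2*pi)`
#'   (`hours / 24 * 2 * pi`); at least 2 events required.
#' @param kappa kernel concentration; defaults to the rule-of-thumb
#'   [select_concentration()].
#' @param grid_size number of equally spaced evaluation points (>= 256).
#' @param label optional species/scope label carried in the result.
#' @return list of class `activity_density`: `theta` (radians), `hours`
#'   (clock hours), `density` (per radian), `kappa`, `n`, `label`.
#' @export
circular_kde <- function(event_times, kappa = NULL, grid_size = 256, label = NULL) {
  if (length(event_times) < 2) {
    stop("need at least 2 events for a kernel density estimate")
  }
  stopifnot(grid_size >= 256)
  if (is.null(kappa)) kappa <- select_concentration(event_times)
  stopifnot(kappa > 0)
  theta <- seq(0, 2 * pi, length.out = grid_size + 1)[-(grid_size + 1)]
  dens <- rowMeans(outer(theta, event_times, vm_kernel, kappa = kappa))
  out <- list(
    theta = theta, hours = theta / (2 * pi) * 24, density = dens,
    kappa = kappa, n = length(event_times), label = label
  )
  class(out) <- "activity_density"
  out
}

#' Trapezoidal integral of an activity density over the circle
#'
#' @param ad an [circular_kde()] result.
#' @return the integral (1 up to quadrature error for a valid density).
#' @export
circular_integral <- function(ad) {
  h <- 2 * pi / length(ad$theta)
  sum(ad$density) * h
}

#' Rule-of-thumb kernel concentration for circular KDE
#'
#' Fits a von Mises distribution to the event times by inverting the mean
#' resultant length (Fisher's piecewise approximation to A^-1), then sharpens
#' the fitted concentration with the usual nonparametric `n^(2/5)` rate so
#' the kernel narrows as data accumulate: `kappa_kde = kappa_hat * n^(2/5)`.
#' Near-uniform data (resultant length < 0.05) have no meaningful von Mises
#' fit; the concentration is floored at 0.1, giving an almost flat kernel.
#'
#' @param event_times event times-of-day in radians; at least 10 events.
#' @return positive kernel concentration.
#' @export
select_concentration <- function(event_times) {
  n <- length(event_times)
  if (n < 10) stop("need at least 10 events to select a concentration")
  rbar <- sqrt(mean(cos(event_times))^2 + mean(sin(event_times))^2)
  if (rbar < 0.05) return(0.1)
  kap <- if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
  max(kap * n^(2 / 5), 0.1)
}

#' Hours-of-day to radians
#'
#' @param hours clock hours in `[0, 24)`.
#' @return radians in `[0, 2*pi)`.
#' @export
hours_to_radians <- function(hours) hours / 24 * 2 * pi

#' Plot an activity curve with night and twilight shading
#'
#' Draws the kernel density estimate over the 24 h clock with shaded bands
#' for the (season-averaged) night and twilight periods, in the style of
#' camera-trap activity figures.
#'
#' @param ad an [circular_kde()] result.
#' @param calendar optional [solar_calendar()]; when given, mean sunrise and
#'   sunset over the calendar define the shading.
#' @param ... further arguments to [graphics::plot()].
#' @return invisibly, the density object.
#' @export
plot_activity <- function(ad, calendar = NULL, ...) {
  dens_h <- ad$density * 2 * pi / 24 # per-hour scale for plotting
  graphics::plot(ad$hours, dens_h,
    type = "n", xlab = "Time of day (h)",
    ylab = "Density (per hour)", xlim = c(0, 24),
    ylim = c(0, max(dens_h) * 1.05), xaxs = "i", yaxs = "i",
    main = if (!is.null(ad$label)) ad$label else "", ...
  )
  if (!is.null(calendar)) {
    sr <- mean(calendar$sunrise) / 60
    ss <- mean(calendar$sunset) / 60
    usr <- graphics::par("usr")
    shade <- function(a, b, col) graphics::rect(a, usr[3], b, usr[4], col = col, border = NA)
    shade(0, sr - 1, "grey55")
    shade(ss + 1, 24, "grey55")
    shade(sr - 1, sr + 1, "grey85")
    shade(ss - 1, ss + 1, "grey85")
  }
  graphics::lines(ad$hours, dens_h, lwd = 2)
  graphics::box()
  invisible(ad)
}
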