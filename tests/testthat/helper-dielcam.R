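# Shared fixtures and independent oracles for the test suite.

STUDY_LAT <- 42.75
STUDY_LON <- 141.45
STUDY_TZ <- 9

ts_utc <- function(x) as.POSIXct(x, tz = "UTC")

make_events <- function(camera_id, species, timestamp) {
  data.frame(
    camera_id = camera_id, species = species, timestamp = ts_utc(timestamp)
  )
}

# expand a species-by-season count table into one event row per count,
# placing each event mid-season at noon (exact dates are irrelevant to the
# season bookkeeping being tested)
events_from_counts <- function(counts) {
  mid <- c(
    winter = "2013-02-15 12:00:00", spring = "2013-05-15 12:00:00",
    summer = "2013-08-15 12:00:00", autumn = "2013-11-15 12:00:00"
  )
  rows <- list()
  for (sp in rownames(counts)) {
    for (se in colnames(counts)) {
      n <- counts[sp, se]
      if (n > 0) {
        rows[[paste(sp, se)]] <- make_events(
          rep("CAM01", n), rep(sp, n), rep(mid[[se]], n)
        )
      }
    }
  }
  do.call(rbind, rows)
}

# season-by-species capture-event counts of the published two-year
# boreal-forest survey (rows: species, cols: winter/spring/summer/autumn)
published_counts <- function() {
  path <- system.file("extdata", "example_survey_counts.csv", package = "dielcam")
  tab <- utils::read.csv(path, comment.char = "#", row.names = 1)
  as.matrix(tab)
}

# Independent diel-period oracle: explicit comparisons against the interval
# definitions, structured differently from diel_period_of (no factor logic,
# interval endpoints spelled out one by one).
oracle_period <- function(minute, sunrise, sunset) {
  in_closed <- function(m, a, b) m >= a && m <= b
  if (in_closed(minute, sunrise - 60, sunrise + 60)) return("twilight")
  if (in_closed(minute, sunset - 60, sunset + 60)) return("twilight")
  if (minute > sunrise + 60 && minute < sunset - 60) return("day")
  "night"
}

# Independent one-way ANOVA oracle: textbook sums-of-squares decomposition.
oracle_anova <- function(groups) {
  y <- unlist(groups)
  n <- lengths(groups)
  gbar <- mean(y)
  ssb <- sum(n * (vapply(groups, mean, 0) - gbar)^2)
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df1 <- length(groups) - 1
  df2 <- length(y) - length(groups)
  F <- (ssb / df1) / (ssw / df2)
  list(F = F, p = stats::pf(F, df1, df2, lower.tail = FALSE))
}

# Independent standardised rank-sum oracle via the Mann-Whitney U
# parametrisation with the classical tie-correction term.
oracle_pair_z <- function(a, b) {
  n1 <- length(a)
  n2 <- length(b)
  N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(c(a, b))
  V <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (V <= 0) return(0)
  (U - n1 * n2 / 2) / sqrt(V)
}

# Exhaustive familywise Steel-Dwass oracle: enumerate every assignment of
# the pooled observations into groups of the given sizes and compute, for
# each pair, P(max over pairs of t* >= observed t*).
oracle_steel_dwass_exact <- function(groups) {
  y <- unlist(groups)
  n <- lengths(groups)
  N <- sum(n)
  tstar <- function(a, b) sqrt(2) * abs(oracle_pair_z(a, b))
  obs <- c(
    tstar(groups[[1]], groups[[2]]),
    tstar(groups[[1]], groups[[3]]),
    tstar(groups[[2]], groups[[3]])
  )
  c1 <- utils::combn(N, n[1])
  maxs <- numeric(0)
  acc <- vector("list", ncol(c1))
  for (i in seq_len(ncol(c1))) {
    g1 <- c1[, i]
    rest <- setdiff(seq_len(N), g1)
    c2 <- utils::combn(rest, n[2])
    m <- numeric(ncol(c2))
    for (j in seq_len(ncol(c2))) {
      g2 <- c2[, j]
      g3 <- setdiff(rest, g2)
      m[j] <- max(
        tstar(y[g1], y[g2]), tstar(y[g1], y[g3]), tstar(y[g2], y[g3])
      )
    }
    acc[[i]] <- m
  }
  maxs <- unlist(acc)
  vapply(obs, function(t0) mean(maxs >= t0 - 1e-9), 0)
}

# Small synthetic survey with four planted profiles of prescribed strength
# (rate 2 events/camera/day, concentrations >= 4, intensity ratios >= 3).
strong_profiles <- function() {
  list(
    diurnal = species_profile(
      "diurnal", 2, data.frame(weight = 1, at = 12.5, kappa = 6)
    ),
    nocturnal = species_profile(
      "nocturnal", 2, data.frame(weight = 1, at = 0.5, kappa = 4)
    ),
    crepuscular = species_profile(
      "crepuscular", 2,
      data.frame(
        weight = c(0.5, 0.5), at = c(0, 0), kappa = c(8, 8),
        anchor = c("sunrise", "sunset")
      )
    ),
    uniform = species_profile("uniform", 2)
  )
}

spring_design <- function(seed, n_cameras = 6) {
  survey_design(
    n_cameras = n_cameras, start = "2013-04-01", end = "2013-05-12", seed = seed
  )
}

spring_calendar <- function() {
  solar_calendar("2013-04-01", "2013-05-12", STUDY_LAT, STUDY_LON, STUDY_TZ)
}

# simulate one site-count table from the Poisson random-intercept model
simulate_glmm_data <- function(n_sites, n_units, beta0, beta1, sigma2, seed) {
  set.seed(seed)
  site <- rep(sprintf("S%02d", seq_len(n_sites)), each = n_units)
  u <- rep(stats::rnorm(n_sites, 0, sqrt(sigma2)), each = n_units)
  x <- stats::rpois(n_sites * n_units, 1)
  y <- stats::rpois(n_sites * n_units, exp(beta0 + beta1 * x + u))
  data.frame(site = site, response = y, x = x)
}
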