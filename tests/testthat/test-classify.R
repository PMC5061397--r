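test_that("one-way ANOVA matches the sums-of-squares hand calculation", {
  groups <- list(
    c(3.1, 4.2, 2.8, 5.0, 3.7),
    c(6.4, 5.9, 7.2, 6.8, 6.1),
    c(2.2, 1.9, 3.0, 2.5, 2.7)
  )
  got <- oneway_anova(groups)
  want <- oracle_anova(groups)
  expect_equal(got$F, want$F, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)
})

test_that("ANOVA conventions: identical groups, separation, tiny groups", {
  same <- list(rep(2, 4), rep(2, 4), rep(2, 4))
  got <- oneway_anova(same)
  expect_equal(got$F, 0)
  expect_equal(got$p, 1)

  jitter <- c(1e-6, -1e-6, 2e-6, -2e-6)
  sep <- list(0 + jitter, 10 + jitter, 0 + jitter)
  expect_lt(oneway_anova(sep)$p, 0.001)

  expect_error(oneway_anova(list(1, c(1, 2))), "at least 2")
})

test_that("Steel-Dwass standardised statistic equals the tie-corrected rank-sum oracle", {
  set.seed(21)
  for (rep in 1:20) {
    a <- sample(0:6, 6, TRUE) + stats::rbinom(6, 1, 0.5) * 0.5
    b <- sample(0:6, 7, TRUE)
    g <- list(p1 = a, p2 = b, p3 = sample(0:9, 6, TRUE))
    sd <- steel_dwass(g)
    z12 <- sd$z[sd$group1 == "p1" & sd$group2 == "p2"]
    expect_equal(z12, oracle_pair_z(a, b), tolerance = 1e-12)
  }
})

test_that("Steel-Dwass degenerate and tie behaviour", {
  same <- list(a = rep(1, 4), b = rep(1, 4), c = rep(1, 4))
  res <- steel_dwass(same)
  expect_equal(res$z, rep(0, 3))
  expect_equal(res$p, rep(1, 3))

  ## replacing distinct values by ties shrinks |z| for the affected pair
  untied <- list(a = c(1, 2, 3, 4), b = c(5, 6, 7, 8), c = c(1, 3, 5, 7))
  tied <- list(a = c(1, 2, 3, 4), b = c(4, 6, 7, 8), c = c(1, 3, 5, 7))
  more <- list(a = c(1, 2, 4, 4), b = c(4, 4, 7, 8), c = c(1, 3, 5, 7))
  z <- function(g) abs(steel_dwass(g)$z[1])
  expect_lt(z(tied), z(untied))
  expect_lt(z(more), z(tied))

  expect_error(steel_dwass(list(1:3, 1:4, 1:4)), "at least 4")
})

test_that("category assignment reproduces the published decision patterns", {
  pw <- function(p12, p13, p23) {
    data.frame(
      group1 = c("twilight", "twilight", "day"),
      group2 = c("day", "night", "night"),
      z = 0, tstar = 0, p = c(p12, p13, p23)
    )
  }
  ## non-significant ANOVA is cathemeral regardless of the means
  expect_equal(
    assign_category(c(twilight = 0.44, day = 0.35, night = 0.24), 0.32, pw(1, 1, 1)),
    "Ca"
  )
  ## twilight dominant and separated from both: crepuscular
  expect_equal(
    assign_category(
      c(twilight = 133.26, day = 50.70, night = 45.37), 1e-9,
      pw(0.001, 0.001, 0.4)
    ),
    "Cr"
  )
  ## night ~ day, both above twilight: composite D/N
  expect_equal(
    assign_category(
      c(twilight = 2.31, day = 3.95, night = 4.57), 0.004,
      pw(0.03, 0.02, 0.9)
    ),
    "D/N"
  )
  ## night leads but separated from neither: undetermined, not forced
  expect_equal(
    assign_category(
      c(twilight = 1, day = 2, night = 3), 0.01, pw(0.5, 0.2, 0.3)
    ),
    "undetermined"
  )
  ## composite ordering is Cr before N
  expect_equal(
    assign_category(
      c(twilight = 3, day = 0.5, night = 2.8), 0.001, pw(0.01, 0.6, 0.01)
    ),
    "Cr/N"
  )
})

test_that("category assignment is scale-invariant", {
  set.seed(33)
  for (rep in 1:20) {
    m <- stats::runif(3, 0, 5)
    names(m) <- c("twilight", "day", "night")
    pwp <- stats::runif(3)
    pw <- data.frame(
      group1 = c("twilight", "twilight", "day"),
      group2 = c("day", "night", "night"),
      z = 0, tstar = 0, p = pwp
    )
    ap <- stats::runif(1)
    expect_equal(
      assign_category(m, ap, pw),
      assign_category(m * 7.3, ap, pw)
    )
  }
})

test_that("classify_species recovers a hard-wired diurnal pattern and reports SEs", {
  dates <- seq(as.Date("2013-05-01"), as.Date("2013-05-20"), by = "day")
  cal <- solar_calendar(min(dates), max(dates), override = data.frame(
    date = dates, sunrise = "06:00", sunset = "18:00"
  ))
  effort <- effort_ledger("CAM01", min(dates), max(dates))
  ## all activity 10:00-14:00, 3 events per day
  ev <- make_events(
    rep("CAM01", 3 * length(dates)),
    rep("midday_sp", 3 * length(dates)),
    paste(rep(dates, each = 3), c("10:30:00", "12:00:00", "13:30:00"))
  )
  fr <- daily_frequencies(ev, effort, cal)
  cl <- classify_species(fr, "midday_sp", "spring")
  expect_equal(cl$category, "D")
  expect_equal(unname(cl$means["day"]), 3 / 10 / 1 * 100)
  expect_equal(unname(cl$se["day"]), 0)
  expect_lt(cl$anova$p, 1e-6)

  empty <- classify_species(fr, "midday_sp", "winter")
  expect_equal(empty$category, "undetermined")
  expect_match(empty$note, "not tested")
})

test_that("classify_all mirrors the species-by-scope table layout", {
  cal <- spring_calendar()
  sim <- simulate_survey(
    strong_profiles()[c("diurnal", "nocturnal")], spring_design(seed = 77), cal
  )
  fr <- daily_frequencies(sim$events, sim$effort, cal)
  tab <- classify_all(fr, scopes = c("annual", "spring"))
  expect_equal(nrow(tab), 2 * 2)
  expect_equal(tab$category[tab$species == "diurnal" & tab$scope == "spring"], "D")
  expect_equal(tab$category[tab$species == "nocturnal" & tab$scope == "spring"], "N")
  expect_true(all(c("twilight_se", "day_se", "night_se", "F", "p") %in% names(tab)))
})
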