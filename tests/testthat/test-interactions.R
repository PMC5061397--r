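test_that("site-count aggregation counts focal and covariate events per unit", {
  d <- as.Date("2013-05-01")
  effort <- effort_ledger("CAM01", d, d)
  ev <- make_events(
    rep("CAM01", 4), c("hare", "hare", "marten", "deer"),
    paste("2013-05-01", c("02:00:00", "23:00:00", "03:00:00", "12:00:00"))
  )
  tab <- aggregate_site_counts(ev, effort, "hare", c("marten", "fox"), unit = "day")
  expect_equal(nrow(tab), 1)
  expect_equal(tab$response, 2L)
  expect_equal(tab$marten, 1L)
  expect_equal(tab$fox, 0L) # unlisted deer ignored, absent fox zero
})

test_that("season-total aggregation collapses to per-site season sums", {
  dates <- seq(as.Date("2013-04-01"), as.Date("2013-04-10"), by = "day")
  effort <- effort_ledger(c("CAM01", "CAM02"), rep(dates[1], 2), rep(dates[10], 2))
  ev <- make_events(
    c("CAM01", "CAM01", "CAM02"), rep("hare", 3),
    c("2013-04-02 05:00:00", "2013-04-07 05:00:00", "2013-04-03 05:00:00")
  )
  daily <- aggregate_site_counts(ev, effort, "hare", "fox",
    season = "spring", unit = "day")
  expect_equal(nrow(daily), 2 * 10)
  total <- aggregate_site_counts(ev, effort, "hare", "fox",
    season = "spring", unit = "season-total")
  expect_equal(nrow(total), 2)
  expect_equal(total$response[total$site == "CAM01"], 2L)
  expect_equal(
    tapply(daily$response, daily$site, sum),
    structure(c(2L, 1L), dim = 2, dimnames = list(c("CAM01", "CAM02")))
  )
  expect_warning(
    empty <- aggregate_site_counts(ev, effort, "hare", "fox", season = "winter"),
    "no effort"
  )
  expect_equal(nrow(empty), 0)
})

test_that("marginal log-likelihood with sigma2 = 0 is the plain Poisson log-likelihood", {
  dat <- simulate_glmm_data(6, 8, -1, 0.5, 0.3, seed = 91)
  beta <- c(-1, 0.5)
  ll_pois <- sum(stats::dpois(dat$response, exp(beta[1] + beta[2] * dat$x), log = TRUE))
  expect_equal(glmm_marginal_loglik(beta, 0, dat, "x", method = "laplace"), ll_pois)
  expect_equal(glmm_marginal_loglik(beta, 0, dat, "x", method = "quadrature"), ll_pois)
  expect_error(glmm_marginal_loglik(beta, -0.1, dat, "x"), "non-negative")
})

test_that("Laplace and adaptive quadrature agree closely off and at the optimum", {
  dat <- simulate_glmm_data(10, 12, -1.2, 0.6, 0.4, seed = 92)
  for (par in list(c(-1.2, 0.6, 0.4), c(-0.8, 0.3, 0.8), c(-1.5, 0.9, 0.2))) {
    la <- glmm_marginal_loglik(par[1:2], par[3], dat, "x", method = "laplace")
    qu <- glmm_marginal_loglik(par[1:2], par[3], dat, "x", method = "quadrature")
    expect_lt(abs(la - qu) / abs(qu), 1e-3)
  }
})

test_that("quadrature log-likelihood peaks at the fitted optimum", {
  dat <- simulate_glmm_data(12, 15, -1, 0.7, 0.3, seed = 93)
  fit <- fit_poisson_glmm(dat, "x")
  b <- fit$coefficients$estimate
  s2 <- fit$sigma2_site
  ll0 <- glmm_marginal_loglik(b, s2, dat, "x", method = "quadrature")
  for (shift in list(c(0.15, 0), c(-0.15, 0), c(0, 0.15), c(0, -0.15))) {
    expect_lt(glmm_marginal_loglik(b + shift, s2, dat, "x", method = "quadrature"), ll0)
  }
  ## the fitter's Laplace objective is reproduced by the direct computation
  la <- glmm_marginal_loglik(b, s2, dat, "x", method = "laplace")
  expect_equal(la, fit$loglik, tolerance = 1e-4)
})

test_that("fit recovers planted parameters and degenerates to the Poisson GLM", {
  dat <- simulate_glmm_data(50, 30, -2, 0.8, 0.5, seed = 94)
  fit <- fit_poisson_glmm(dat, "x")
  co <- fit$coefficients
  expect_lt(abs(co$estimate[co$term == "x"] - 0.8), 3 * co$se[co$term == "x"])
  expect_lt(abs(co$estimate[co$term == "(Intercept)"] + 2),
    3 * co$se[co$term == "(Intercept)"])
  expect_lt(abs(fit$sigma2_site - 0.5), 0.3)
  expect_equal(co$z, co$estimate / co$se)
  expect_equal(co$p, 2 * stats::pnorm(-abs(co$z)))

  ## no site heterogeneity: variance hits the boundary and beta matches the GLM
  hom <- simulate_glmm_data(40, 25, -1, 0.5, 0, seed = 102)
  fit0 <- fit_poisson_glmm(hom, "x")
  glm0 <- stats::glm(response ~ x, data = hom, family = stats::poisson())
  expect_lt(fit0$sigma2_site, 1e-6)
  expect_equal(
    fit0$coefficients$estimate, unname(stats::coef(glm0)), tolerance = 1e-4
  )
})

test_that("separation pathologies are surfaced, not hidden", {
  ## quasi-separation: focal never detected where the covariate was —
  ## the coefficient drifts far negative with an enormous standard error
  set.seed(96)
  dat <- data.frame(
    site = rep(sprintf("S%02d", 1:10), each = 20),
    x = stats::rbinom(200, 1, 0.08)
  )
  dat$response <- stats::rpois(200, exp(-1))
  dat$response[dat$x > 0] <- 0L
  fit <- suppressWarnings(fit_poisson_glmm(dat, "x"))
  co <- fit$coefficients
  expect_lt(co$estimate[co$term == "x"], -3)
  expect_gt(co$se[co$term == "x"], 10)
  expect_gt(co$p[co$term == "x"], 0.5)

  ## a covariate with no detections at all is unidentifiable: NA row + warning
  dat$ghost <- 0L
  ## lme4 also warns about the ill-conditioned Hessian here; assert ours
  w <- capture_warnings(fit2 <- fit_poisson_glmm(dat, c("x", "ghost")))
  expect_true(any(grepl("unidentifiable", w)))
  expect_true(is.na(fit2$coefficients$estimate[fit2$coefficients$term == "ghost"]))
  expect_error(fit_poisson_glmm(dat[dat$site %in% unique(dat$site)[1:3], ], "x"),
    "at least 5 sites")
})
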