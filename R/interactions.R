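#' Aggregate detections into site-by-unit count rows for co-detection GLMMs
#'
#' Builds the modelling table for predator-prey or competitor co-detection:
#' for every camera site and aggregation unit (calendar day, ISO week, or a
#' single season total per site) within a season, the count of focal-species
#' events is the response and the counts of each explanatory species are the
#' covariates. Units with zero detections are included for every date the
#' site was active — the zeros carry most of the information in a sparse
#' survey. Events of species in neither list are ignored.
#'
#' @param events independent events.
#' @param effort an [effort_ledger()].
#' @param focal focal (response) species.
#' @param explanatory character vector of explanatory species.
#' @param season optional season name restricting the table (via
#'   [season_of()] on the event/effort dates); `NULL` uses all dates.
#' @param unit `"day"`, `"week"` or `"season-total"`.
#' @return data frame with columns `site`, `unit`, `response`, and one count
#'   column per explanatory species.
#' @export
aggregate_site_counts <- function(events, effort, focal, explanatory,
                                  season = NULL, unit = c("day", "week", "season-total")) {
  unit <- match.arg(unit)
  per_site <- Map(seq, effort$start_date, effort$end_date, by = "day")
  site_of <- rep(effort$camera_id, lengths(per_site))
  date_of <- do.call(c, per_site)
  if (!is.null(season)) {
    keep <- as.character(season_of(date_of)) == season
    site_of <- site_of[keep]
    date_of <- date_of[keep]
  }
  if (length(date_of) == 0) {
    warning("no effort in the requested season; empty table")
    out <- data.frame(site = character(), unit = character(), response = integer())
    for (sp in explanatory) out[[make_cov_name(sp)]] <- integer()
    return(out)
  }
  unit_key <- switch(unit,
    "day" = as.character(date_of),
    "week" = format(date_of, "%G-W%V"),
    "season-total" = rep("total", length(date_of))
  )
  frame <- unique(data.frame(site = site_of, unit = unit_key))
  frame <- frame[order(frame$site, frame$unit), , drop = FALSE]
  ev <- events
  ed <- as.Date(ev$timestamp, tz = "UTC")
  if (!is.null(season)) {
    keep <- as.character(season_of(ed)) == season
    ev <- ev[keep, , drop = FALSE]
    ed <- ed[keep]
  }
  ev_key <- switch(unit,
    "day" = as.character(ed),
    "week" = format(ed, "%G-W%V"),
    "season-total" = rep("total", length(ed))
  )
  count_sp <- function(sp) {
    sel <- ev$species == sp
    if (!any(sel)) return(integer(nrow(frame)))
    tab <- table(paste(ev$camera_id[sel], ev_key[sel], sep = "\r"))
    out <- as.integer(tab[paste(frame$site, frame$unit, sep = "\r")])
    out[is.na(out)] <- 0L
    out
  }
  frame$response <- count_sp(focal)
  for (sp in explanatory) frame[[make_cov_name(sp)]] <- count_sp(sp)
  rownames(frame) <- NULL
  frame
}

make_cov_name <- function(sp) make.names(sp)

#' Fit a Poisson mixed model with a camera-site random intercept
#'
#' Fits `response ~ covariates + (1 | site)` with a Poisson response by
#' maximising the Laplace-approximated marginal likelihood (via
#' [lme4::glmer()]), the model used to test whether a focal species is
#' detected more often at sites and times where an interacting species is
#' also detected. Wald `Z = beta / SE` and two-sided p values are reported
#' per coefficient. Sparse surveys routinely produce quasi-separated
#' covariates (the focal species is never detected in any unit where the
#' covariate species was): their coefficients drift to large negative values
#' with enormous standard errors, which the coefficient table reports as-is.
#' A covariate with no detections anywhere is unidentifiable outright; it is
#' flagged with a warning and reported as an NA row.
#'
#' @param data table from [aggregate_site_counts()] (columns `site`,
#'   `response`, covariates), needing at least 5 sites.
#' @param covariates covariate column names (default: everything except
#'   `site`, `unit`, `response`).
#' @return list of class `glmm_fit`: `coefficients` (data frame with
#'   `estimate`, `se`, `z`, `p`), `sigma2_site`, `loglik`, `converged`,
#'   `n_sites`, `n_obs`, and the underlying `model`.
#' @export
fit_poisson_glmm <- function(data, covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c("site", "unit", "response"))
  }
  if (length(unique(data$site)) < 5) stop("need at least 5 sites")
  zero_cov <- covariates[vapply(covariates, function(v) all(data[[v]] == 0), TRUE)]
  if (length(zero_cov)) {
    warning(
      "covariate(s) with no detections at all: ", paste(zero_cov, collapse = ", "),
      "; their coefficients are unidentifiable and reported as NA"
    )
  }
  rhs <- if (length(covariates)) paste(covariates, collapse = " + ") else "1"
  form <- stats::as.formula(paste("response ~", rhs, "+ (1 | site)"))
  fit <- suppressWarnings(
    lme4::glmer(form, data = data, family = stats::poisson())
  )
  sm <- summary(fit)$coefficients
  coefs <- data.frame(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    z = sm[, "z value"],
    p = sm[, "Pr(>|z|)"]
  )
  ## constant (all-zero) covariates are dropped from the model matrix;
  ## re-add them as explicit NA rows so the coefficient table is complete
  dropped <- setdiff(c("(Intercept)", covariates), coefs$term)
  if (length(dropped)) {
    coefs <- rbind(coefs, data.frame(
      term = dropped, estimate = NA_real_, se = NA_real_,
      z = NA_real_, p = NA_real_
    ))
    coefs <- coefs[match(c("(Intercept)", covariates), coefs$term), ]
  }
  rownames(coefs) <- NULL
  conv <- length(fit@optinfo$conv$lme4$messages) == 0 && fit@optinfo$conv$opt == 0
  out <- list(
    coefficients = coefs,
    sigma2_site = unname(lme4::VarCorr(fit)$site[1, 1]),
    loglik = as.numeric(stats::logLik(fit)),
    converged = conv,
    n_sites = length(unique(data$site)),
    n_obs = nrow(data),
    model = fit
  )
  class(out) <- "glmm_fit"
  out
}

#' @export
print.glmm_fit <- function(x, ...) {
  cat(sprintf(
    "Poisson GLMM (site random intercept): %d obs, %d sites, sigma2_site = %.4g, logLik = %.2f%s\n",
    x$n_obs, x$n_sites, x$sigma2_site, x$loglik,
    if (x$converged) "" else "  [NOT CONVERGED]"
  ))
  print(transform(x$coefficients,
    estimate = round(estimate, 3), se = round(se, 3),
    z = round(z, 2), p = signif(p, 3)
  ))
  invisible(x)
}

#' Marginal log-likelihood of the Poisson random-intercept model
#'
#' Direct computation of the marginal likelihood
#' `prod_i integral Pois(y_ij | exp(x_ij' beta + u)) N(u; 0, sigma2) du`,
#' integrating each site's random effect either by the Laplace approximation
#' (Gaussian expansion around the site mode, found by Newton iteration) or
#' by adaptive Gauss-Hermite quadrature centred and scaled at that mode.
#' The quadrature mode is the numerical gold standard against which the
#' Laplace approximation — and any external fitter — can be verified. With
#' `sigma2 = 0` both modes reduce exactly to the ordinary Poisson
#' log-likelihood.
#'
#' @param beta fixed-effect vector (intercept first, matching `covariates`).
#' @param sigma2 random-intercept variance (>= 0).
#' @param data site-count table as for [fit_poisson_glmm()].
#' @param covariates covariate column names.
#' @param method `"laplace"` or `"quadrature"`.
#' @param nodes number of Gauss-Hermite nodes for the quadrature method.
#' @return total marginal log-likelihood.
#' @export
glmm_marginal_loglik <- function(beta, sigma2, data, covariates = NULL,
                                 method = c("laplace", "quadrature"), nodes = 21) {
  method <- match.arg(method)
  if (sigma2 < 0) stop("sigma2 must be non-negative")
  if (is.null(covariates)) {
    covariates <- setdiff(names(data), c("site", "unit", "response"))
  }
  X <- cbind(1, as.matrix(data[, covariates, drop = FALSE]))
  stopifnot(length(beta) == ncol(X))
  eta0 <- drop(X %*% beta)
  y <- data$response
  const <- -sum(lgamma(y + 1))
  if (sigma2 == 0) {
    return(sum(y * eta0 - exp(eta0)) + const)
  }
  gh <- pracma::gaussHermite(nodes)
  ll <- 0
  for (s in unique(data$site)) {
    idx <- data$site == s
    ys <- y[idx]
    es <- eta0[idx]
    ## site-mode Newton solve: maximise sum(y*(e+u) - exp(e+u)) - u^2/(2*sigma2)
    u <- 0
    for (it in 1:50) {
      mu <- exp(es + u)
      g <- sum(ys - mu) - u / sigma2
      h <- -sum(mu) - 1 / sigma2
      step <- g / h
      u <- u - step
      if (abs(step) < 1e-12) break
    }
    mu <- exp(es + u)
    hmod <- sum(ys * (es + u) - mu) - u^2 / (2 * sigma2)
    H <- sum(mu) + 1 / sigma2 # negative curvature at the mode
    if (method == "laplace") {
      ll <- ll + hmod - 0.5 * log(sigma2 * H)
    } else {
      ## adaptive GH: u = u_hat + sqrt(2/H) * x_k
      sc <- sqrt(2 / H)
      uk <- u + sc * gh$x
      hk <- vapply(uk, function(uu) {
        sum(ys * (es + uu) - exp(es + uu)) - uu^2 / (2 * sigma2)
      }, 0)
      lt <- log(gh$w) + gh$x^2 + hk
      m <- max(lt)
      ll <- ll + m + log(sum(exp(lt - m))) + log(sc) - 0.5 * log(2 * pi * sigma2)
    }
  }
  ll + const
}
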