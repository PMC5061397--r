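#' One-way fixed-effects ANOVA across diel periods
#'
#' Classical one-way ANOVA comparing daily photographic frequencies among
#' groups (normally the three diel periods). Degenerate input in which every
#' group is constant with equal means carries no evidence of a difference
#' and returns `F = 0, p = 1` by convention.
#'
#' @param groups list of numeric vectors, each with at least 2 observations.
#' @return list with `F`, `p`, `df` (numerator, denominator).
#' @export
oneway_anova <- function(groups) {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (any(lengths(groups) < 2)) stop("every group needs at least 2 observations")
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  if (stats::var(y) == 0) {
    return(list(F = 0, p = 1, df = c(length(groups) - 1, length(y) - length(groups))))
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  Fv <- unname(ft$statistic)
  p <- unname(ft$p.value)
  if (!is.finite(Fv)) { # zero within-group variance, unequal means
    Fv <- Inf
    p <- 0
  }
  list(F = Fv, p = p, df = unname(ft$parameter))
}

#' Steel-Dwass all-pairs multiple comparison
#'
#' Nonparametric all-pairs comparison controlling the familywise error rate.
#' For each pair of groups the Wilcoxon rank-sum statistic is computed on the
#' two groups alone (mid-ranks for ties), standardised by its exact null mean
#' and tie-corrected variance, and the statistic `t* = sqrt(2) * |z|` is
#' referred to the studentized range distribution with `k` groups and
#' infinite degrees of freedom (the standard large-sample Steel-Dwass form).
#' A pair whose pooled observations are all tied carries no information and
#' gets `p = 1`.
#'
#' @param groups list of `k >= 2` numeric vectors (the diel-period use case
#'   has `k = 3`), each with at least 4 observations.
#' @return data frame with one row per pair: `group1`, `group2`, `z`
#'   (standardised rank-sum statistic), `tstar`, `p`.
#' @export
steel_dwass <- function(groups) {
  k <- length(groups)
  stopifnot(k >= 2)
  if (any(lengths(groups) < 4)) stop("every group needs at least 4 observations")
  nm <- names(groups)
  if (is.null(nm)) nm <- as.character(seq_len(k))
  pairs <- utils::combn(k, 2)
  res <- apply(pairs, 2, function(ij) {
    a <- groups[[ij[1]]]
    b <- groups[[ij[2]]]
    z <- sd_pair_z(a, b)
    tstar <- sqrt(2) * abs(z)
    p <- if (tstar == 0) 1 else stats::ptukey(tstar, nmeans = k, df = Inf, lower.tail = FALSE)
    c(z = z, tstar = tstar, p = p)
  })
  data.frame(
    group1 = nm[pairs[1, ]], group2 = nm[pairs[2, ]],
    z = res["z", ], tstar = res["tstar", ], p = res["p", ]
  )
}

## standardised pairwise rank-sum statistic with tie-corrected variance
sd_pair_z <- function(a, b) {
  N <- length(a) + length(b)
  r <- rank(c(a, b)) # mid-ranks
  W <- sum(r[seq_along(a)])
  EW <- length(a) * (N + 1) / 2
  VW <- length(a) * length(b) / (N * (N - 1)) * (sum(r^2) - N * (N + 1)^2 / 4)
  if (VW <= 0) return(0) # all observations tied
  (W - EW) / sqrt(VW)
}

#' Assign a diel activity category
#'
#' Implements the formal categorisation: cathemeral (`Ca`) when the ANOVA
#' finds no difference among the three periods (`anova_p >= alpha`);
#' otherwise the periods are ranked by mean frequency and the pairwise
#' Steel-Dwass results decide whether the top period stands alone (diurnal
#' `D`, nocturnal `N` or crepuscular `Cr` according to which period it is),
#' or whether the top two are mutually indistinguishable but both exceed the
#' third (composite `Cr/D`, `Cr/N` or `D/N`). Orderings the procedure cannot
#' resolve (e.g. a significant ANOVA with no separated pair) are labelled
#' `undetermined` rather than silently forced into a category.
#'
#' @param period_means named numeric vector of mean frequencies for
#'   `twilight`, `day`, `night`.
#' @param anova_p p value from [oneway_anova()].
#' @param pairwise data frame from [steel_dwass()] on the same three groups.
#' @param alpha significance level (default 0.05).
#' @return one of `"D"`, `"N"`, `"Cr"`, `"Ca"`, `"Cr/D"`, `"Cr/N"`,
#'   `"D/N"`, `"undetermined"`.
#' @export
assign_category <- function(period_means, anova_p, pairwise, alpha = 0.05) {
  stopifnot(all(c("twilight", "day", "night") %in% names(period_means)))
  if (is.na(anova_p) || anova_p >= alpha) return("Ca")
  code <- c(twilight = "Cr", day = "D", night = "N")
  ord <- names(sort(period_means, decreasing = TRUE))
  pair_p <- function(p1, p2) {
    hit <- (pairwise$group1 == p1 & pairwise$group2 == p2) |
      (pairwise$group1 == p2 & pairwise$group2 == p1)
    pairwise$p[hit][1]
  }
  top_vs_2nd <- pair_p(ord[1], ord[2])
  top_vs_3rd <- pair_p(ord[1], ord[3])
  snd_vs_3rd <- pair_p(ord[2], ord[3])
  if (top_vs_2nd < alpha && top_vs_3rd < alpha) {
    return(code[[ord[1]]])
  }
  if (top_vs_2nd >= alpha && top_vs_3rd < alpha && snd_vs_3rd < alpha) {
    ## composite of the two leading periods, written Cr before D before N
    lead <- c("Cr", "D", "N")[c("Cr", "D", "N") %in% code[ord[1:2]]]
    return(paste(lead, collapse = "/"))
  }
  "undetermined"
}

#' Classify a species' diel activity from a frequency table
#'
#' Composes [oneway_anova()], [steel_dwass()] and [assign_category()] for
#' one species over a scope (`"annual"` or a single season), reporting the
#' per-period mean and standard error of the daily frequencies alongside the
#' test results. Data covering fewer than 4 days are reported as
#' `undetermined` with a diagnostic rather than tested.
#'
#' @param freq daily frequency table from [daily_frequencies()].
#' @param species species to classify.
#' @param scope `"annual"` or one of `"winter"`, `"spring"`, `"summer"`,
#'   `"autumn"`.
#' @param alpha significance level.
#' @return list of class `diel_classification`: `species`, `scope`, `n_days`,
#'   `means`, `se`, `anova` (`F`, `p`), `pairwise`, `category`.
#' @export
classify_species <- function(freq, species, scope = "annual", alpha = 0.05) {
  stopifnot(scope %in% c("annual", "winter", "spring", "summer", "autumn"))
  sub <- freq[freq$species == species, , drop = FALSE]
  if (scope != "annual") sub <- sub[as.character(sub$season) == scope, , drop = FALSE]
  n_days <- length(unique(sub$date))
  out <- list(
    species = species, scope = scope, n_days = n_days,
    means = c(twilight = NA_real_, day = NA_real_, night = NA_real_),
    se = c(twilight = NA_real_, day = NA_real_, night = NA_real_),
    anova = list(F = NA_real_, p = NA_real_), pairwise = NULL,
    category = "undetermined", note = NULL
  )
  class(out) <- "diel_classification"
  if (n_days < 4) {
    out$note <- sprintf("only %d day(s) of data in scope; not tested", n_days)
    return(out)
  }
  groups <- split(sub$frequency, factor(as.character(sub$period),
    levels = c("twilight", "day", "night")))
  out$means <- vapply(groups, mean, 0)
  out$se <- vapply(groups, function(x) stats::sd(x) / sqrt(length(x)), 0)
  an <- oneway_anova(groups)
  pw <- steel_dwass(groups)
  out$anova <- an[c("F", "p")]
  out$pairwise <- pw
  out$category <- assign_category(out$means, an$p, pw, alpha)
  out
}

#' @export
print.diel_classification <- function(x, ...) {
  cat(sprintf(
    "%s (%s): %s  [ANOVA F = %.3g, p = %.3g, %d days]\n",
    x$species, x$scope, x$category, x$anova$F, x$anova$p, x$n_days
  ))
  m <- rbind(mean = x$means, se = x$se)
  print(round(m, 3))
  if (!is.null(x$note)) cat("note:", x$note, "\n")
  invisible(x)
}

#' Classify all species, annually and per season
#'
#' @param freq daily frequency table from [daily_frequencies()].
#' @param scopes scopes to report (default annual plus the four seasons).
#' @param alpha significance level.
#' @return data frame with one row per species x scope: means, SEs, F, p
#'   and category — the layout of a published activity-category table.
#' @export
classify_all <- function(freq, scopes = c("annual", "winter", "spring", "summer", "autumn"),
                         alpha = 0.05) {
  species <- sort(unique(freq$species))
  rows <- lapply(species, function(sp) {
    do.call(rbind, lapply(scopes, function(sc) {
      cl <- classify_species(freq, sp, sc, alpha)
      data.frame(
        species = sp, scope = sc,
        twilight = cl$means[["twilight"]], twilight_se = cl$se[["twilight"]],
        day = cl$means[["day"]], day_se = cl$se[["day"]],
        night = cl$means[["night"]], night_se = cl$se[["night"]],
        F = cl$anova$F, p = cl$anova$p, category = cl$category
      )
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
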