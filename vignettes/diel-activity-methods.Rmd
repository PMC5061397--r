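---
title: "Classifying diel activity from camera-trap detections: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying diel activity from camera-trap detections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dielcam)
```

Camera traps sample an animal community's *temporal* niche: every trigger
is a timestamped point in the 24 h cycle. This vignette documents the
statistical machinery `dielcam` builds on those points — what is assumed,
which knobs matter, and where the design was genuinely open.

## Detection events and independence

The unit of analysis is the *capture event*: one camera trigger, however
many photos the burst contains. Consecutive triggers of the same species
at the same camera within a short refractory window are not independent
passes — typically one animal lingering in front of the sensor — so
`filter_independent_events()` keeps an event only if it falls at least
`window_minutes` (default 5, matching the common trigger-delay setting)
after the last *kept* event of that camera × species stream. Measuring
from the last kept event rather than the last raw event mirrors what the
camera hardware does and makes the filter idempotent, a property the test
suite checks directly. Streams are independent across cameras and across
species: two species photographed 3 min apart at one camera are both kept.

## The solar clock and the three diel periods

Because twilight moves with the seasons, diel periods are anchored to the
sun, not the clock. `solar_times()` implements the NOAA low-precision
ephemeris (geometric mean solar longitude, equation of centre, apparent
longitude, obliquity, equation of time) at the official zenith of 90.833°,
which folds in atmospheric refraction and the solar radius. The equation
of time and declination are evaluated at each date's local solar noon with
one fixed-point refinement; at mid-latitudes this is accurate to about a
minute, and the suite cross-checks annual day-length profiles against an
independent astronomical model (`geosphere::daylength`). Latitudes
poleward of 66° are rejected outright — the partition below presumes the
sun rises and sets daily.

Each date is partitioned into:

* **twilight** — [sunrise − 1 h, sunrise + 1 h] ∪ [sunset − 1 h,
  sunset + 1 h]; exactly 4 h on every date;
* **day** — (sunrise + 1 h, sunset − 1 h);
* **night** — the open remainder, spanning midnight.

Twilight intervals are closed at both ends; a timestamp exactly at sunrise
is twilight. The three durations sum to 24 h identically (day-length − 2 h
for day, 26 h − day-length for night). Night belongs to the evening's
sunset and the following morning's sunrise; since period *labels* do not
depend on which night an observation falls in, the implementation resolves
a timestamp against its own civil date, which is exact wherever the
twilight buffers never cross midnight (true throughout the mid-latitude
range the package targets). Seasons are calendar quarters: winter
January–March, spring April–June, summer July–September, autumn
October–December. Timestamps are treated as local civil time with a fixed
UTC offset and no daylight-saving transitions; the offset only enters the
solar computation. A published sunrise/sunset table can be injected
verbatim via `solar_calendar(override =)` when bit-exact agreement with an
almanac is wanted.

## Photographic frequencies

The response compared across periods is the *daily photographic
frequency*: for date $d$, species $s$, period $p$,

$$f(d,s,p) = \frac{\text{count}(s,p,d)}{\text{hours}(p,d)\cdot
\text{cameras}(d)} \times 100,$$

detections per period-hour per 100 trap-days. The sampling unit is the
calendar day pooled over cameras; each day is normalised by its own
active-camera count and its own period durations, so a 14 h summer day and
a 9 h winter day are on the same footing. This is the only normalisation
consistent with both "per hour" and "per 100 trap-days"; published
survey tables do not always carry enough information to reverse-engineer
their exact scaling, so no attempt is made to match any specific printed
frequency magnitude — the arithmetic identity
$\sum_p f \cdot \text{hours} \cdot \text{cameras} / 100 =$ daily count is
instead enforced exactly in the tests. Zero-count days are real data and
are retained for every date with at least one active camera.

## The categorisation rule

For one species and scope (a season, or the year), the three period groups
of daily frequencies enter a classical one-way fixed-effects ANOVA. If the
ANOVA finds no difference ($p \ge \alpha$, default $\alpha = 0.05$) the
species is **cathemeral (Ca)** — active round the clock. Otherwise the
Steel–Dwass all-pairs test ranks the periods: for each pair, the rank sum
on the two groups alone (mid-ranks under ties) is standardised by its
exact null mean and tie-corrected variance, and $t^* = \sqrt{2}\,|z|$ is
referred to the studentized range $q_{k,\infty}$ with $k = 3$, the
standard large-sample form that controls the familywise error over the
three comparisons. The label is then:

* the top period's label — **D** (day), **N** (night), **Cr** (twilight) —
  when the top period is separated from both others ($p < \alpha$);
* a composite — **D/N**, **Cr/N**, **Cr/D**, written with Cr before D
  before N — when the top two are not separated from each other but both
  beat the third. Published activity tables print such composites without
  defining them; this formalisation is the package's own and is stated
  here for that reason;
* **undetermined** when neither pattern holds (e.g. a significant ANOVA
  with no separated pair). Silently forcing such cases into a category
  would fabricate structure; they are flagged instead.

Labels are invariant to rescaling all frequencies, so the ×100 convention
is cosmetic for classification. No multiple-testing correction is applied
*across* species × season cells, matching standard practice in activity
studies; the Steel–Dwass reference already handles the three within-cell
comparisons. Cells with fewer than 4 days of data are reported
`undetermined` with a diagnostic note rather than tested.

At $n = 4$ observations per group the $q_{3,\infty}$ reference is
noticeably coarser than the exact permutation distribution in the middle
of the p scale (differences up to ~0.15), though it tracks the exact tail
closely where decisions at $\alpha = 0.05$ are made (within 0.02). The
test suite therefore verifies the standardised statistic *exactly*
(against enumerated permutation moments and an independent tie-corrected
Mann–Whitney formulation) and the p values against an exhaustive
familywise max-statistic enumeration in the separated regime. Real
surveys have dozens of days per cell, where the approximation is good.

## Activity curves

Time-of-day is circular, so smoothing uses the von Mises kernel:
$\hat g(\theta) = n^{-1}\sum_i \mathrm{vM}(\theta;\, t_i, \kappa)$,
evaluated on a 256-point grid (denser on request). Being a mixture of
unit-mass kernels the estimate integrates to 1 by construction; the
trapezoidal check `circular_integral()` guards the implementation to
1e−6. The concentration is chosen deterministically by
`select_concentration()`: fit a von Mises by inverting the mean resultant
length (Fisher's piecewise approximation), then sharpen with the usual
nonparametric rate, $\kappa_{\mathrm{kde}} = \hat\kappa\, n^{2/5}$, so the
kernel narrows as data accumulate. Near-uniform samples (resultant
< 0.05) have no meaningful fit and get a floor of $\kappa = 0.1$, i.e. an
almost flat kernel. Curves are estimated on clock time — the convention
of published activity figures, which shade night and twilight bands onto
a 24 h axis (`plot_activity()` reproduces that style) — not on
sun-anchored time.

## Co-detection GLMMs

Whether two species use the same places at the same times is asked with a
Poisson mixed model: the count of focal-species events per camera site and
aggregation unit is regressed on the counts of each covariate species in
the same site-unit, with a site random intercept absorbing between-camera
heterogeneity (trail quality, placement, local density):

$$y_{ij} \sim \mathrm{Pois}(\mu_{ij}),\quad
\log \mu_{ij} = \beta_0 + \boldsymbol\beta^\top \mathbf{x}_{ij} + u_i,
\quad u_i \sim \mathcal N(0, \sigma^2).$$

The default unit is the site-day: a single season total per site would
leave the random intercept unidentifiable (one observation per level),
whereas site-days give the intercept replication and put the intercept on
the scale of small per-day counts. Week and season-total units are
retained for sensitivity analysis. No offset is used; effort differences
between sites load on the intercept. Positive coefficients mean the focal
species is detected more where and when the covariate species is.

Fitting maximises the Laplace-approximated marginal likelihood via
`lme4::glmer`; `glmm_marginal_loglik()` is an independent, direct
implementation of the same integral — an inner Newton solve for each
site's random-effect mode, then either the Laplace expansion or adaptive
Gauss–Hermite quadrature (21 nodes by default) centred and scaled at that
mode — and serves as the verification oracle: the suite requires the
Laplace value to match quadrature to 0.5% and to reproduce the fitter's
own objective, and checks 94–95% empirical coverage of nominal 95% Wald
intervals in parameter-recovery simulations. Sparse surveys routinely
quasi-separate (the focal species never co-detected with a covariate):
the coefficient runs off to a large negative value with a standard error
in the tens — such rows are reported as-is, since the enormous SE is
itself the correct statement of no information, and a covariate with no
detections anywhere is returned as an explicit NA row with a warning.

## The synthetic-data generator

`simulate_survey()` emulates the surveys the pipeline targets. Each
species' intensity on a given day is
$\lambda(t) = \text{base rate} \times \text{season factor} \times g(t)$
with $g$ a von Mises mixture (per-hour scale, unit daily integral) whose
components sit at clock times or at offsets from that day's sunrise or
sunset. Event times are drawn by Lewis–Shedler thinning — exact for
continuous-time intensities, independent of any grid — and then passed
through the refractory filter exactly as real cameras impose it.
Dependence between species multiplies a site-day rate by
$e^{\gamma\cdot\text{count}}$ of the covariate species' events that
site-day. `planted_category()` supplies the ground-truth label by
integrating the planted density over the diel partition, averaged over
the design's dates; profiles whose max/min period intensity ratio is
below 1.2 are declared cathemeral by convention — a generator-side
threshold marking profiles too even for any frequency test to separate.

What the generator deliberately omits: imperfect and size-dependent
detectability, animal movement and home ranges (detections are
independent across cameras), camera failures beyond effort gaps, and
weather covariates. Passing the recovery tests therefore demonstrates
that the *statistical chain* is correct and well calibrated under the
stated model — not that any real community will be classified correctly
when those ignored processes matter.

## Validation problem sizes and numerical conventions

The validation suite was sized to be decisive yet quick to rerun:
category-recovery uses 200 independent surveys of 6 cameras × 42 spring
days with strong planted profiles (2 events/camera/day, kernel
concentrations ≥ 4, period-intensity ratios ≥ 3), on which recovery of
planted D/N/Cr is ≥ 95% and planted-uniform species are labelled Ca at
the nominal 1 − α rate; the full-scale default design (30 cameras, two
years, an eight-species deer-dominated community) is exercised as a smoke
test. GLMM coverage uses 100 fits of 50 sites × 30 units at
$\beta_0 = -2,\ \beta_1 = 0.8,\ \sigma^2 = 0.5$; quadrature comparisons
use 10-site fixtures. Other conventions: ANOVA on groups that are all
constant and equal returns $p = 1$ (no evidence of difference) and
all-constant unequal groups return $p = 0$; Steel–Dwass pairs with every
observation tied return $p = 1$; the solar calendar is computed per
calendar date and year, never recycled across years; timestamps are
stored minute- or second-precise and compared in minutes-from-midnight;
the categorisation's $\alpha$ defaults to 0.05 everywhere, the
conventional threshold in the activity-pattern literature.
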