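# dielcam

Diel activity classification and co-detection analysis for camera-trap
surveys.

Triggered trail cameras record *when* animals move past a point, around the
clock and across seasons, at a fraction of the cost of telemetry. `dielcam`
turns a multi-camera detection table into a formal answer to the question
"is this species diurnal, nocturnal, crepuscular, or cathemeral — and does
that change with season?", and tests whether potentially interacting
species (predator and prey, or competitors) are detected together more
often than chance expects. It is written for field ecologists and
quantitative wildlife biologists analysing medium-to-large mammal surveys.

## The method

1. **Solar-anchored diel periods.** For each calendar date the package
   computes sunrise and sunset (NOAA low-precision ephemeris, zenith
   90.833°) and partitions the 24 h cycle into **twilight** (±1 h around
   sunrise and around sunset; 4 h on every date), **day** (sunrise + 1 h to
   sunset − 1 h) and **night** (sunset + 1 h to the next sunrise − 1 h).
2. **Independence filtering.** Within each camera × species stream, an
   event is kept only if it falls ≥ 5 min (configurable) after the last
   *kept* event, mirroring the camera's trigger-delay hardware.
3. **Photographic frequencies.** For date *d*, species *s*, period *p*:

   *f(d,s,p) = count(s,p,d) / hours(p,d) / cameras_active(d) × 100*

   — detections per hour of the period per 100 trap-days, with the
   calendar day as sampling unit.
4. **Formal categorisation.** One-way ANOVA compares the daily frequencies
   among the three periods; the Steel–Dwass all-pairs test (standardised
   pairwise rank sums referred to the studentized range *q₃,∞*) ranks them.
   Non-significant ANOVA ⇒ cathemeral (**Ca**); a top period separated from
   both others ⇒ **D** / **N** / **Cr**; top two inseparable but both above
   the third ⇒ a composite (**D/N**, **Cr/N**, **Cr/D**).
5. **Activity curves.** Circular kernel density estimates on the 24 h clock
   with a von Mises kernel, `density(θ) = (1/n) Σᵢ vM(θ; tᵢ, κ)`, with a
   deterministic rule-of-thumb concentration.
6. **Co-detection GLMMs.** `count_focal ~ count_covariates + (1 | site)`
   with a Poisson response, fitted by Laplace-approximated maximum
   likelihood; a hand-rolled Laplace/adaptive Gauss–Hermite marginal
   log-likelihood verifies every fit.
7. **Synthetic surveys.** An inhomogeneous-Poisson (Lewis–Shedler thinning)
   generator plants known diel structure — clock- or sun-anchored von Mises
   mixtures, seasonal rate factors, co-detection dependence — so the whole
   chain is validated against ground truth.

## Worked example

Simulate a 6-camera, 6-week spring survey with a planted crepuscular
species and classify it:

```r
library(dielcam)

design <- survey_design(n_cameras = 6, start = "2013-04-01",
                        end = "2013-05-12", seed = 42)
crep <- species_profile("crepuscular", base_rate = 2,
  components = data.frame(weight = c(0.5, 0.5), at = c(0, 0),
                          kappa = c(8, 8), anchor = c("sunrise", "sunset")))

sim  <- simulate_survey(crep, design)
freq <- daily_frequencies(sim$events, sim$effort, sim$calendar)
classify_species(freq, "crepuscular", scope = "spring")
```

```
crepuscular (spring): Cr  [ANOVA F = 259, p = 8.51e-45, 42 days]
     twilight   day night
mean   30.258 3.904 6.321
se      1.406 0.336 0.609
```

The twilight frequency (≈ 30 detections · h⁻¹ · (100 trap-days)⁻¹) towers
over day and night; the ANOVA is decisive and Steel–Dwass separates
twilight from both other periods, so the species is labelled **Cr**
(crepuscular) — exactly the category planted in the generator
(`planted_category(crep, design)$category` is `"Cr"`). A smooth activity
curve for plotting comes from
`circular_kde(hours_to_radians(as.POSIXlt(sim$events$timestamp)$hour))`,
and `run_pipeline()` drives the same stages from CSV inputs to a CSV
output bundle.

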