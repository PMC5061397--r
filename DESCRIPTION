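Package: dielcam
Title: Diel Activity Classification and Co-Detection Analysis for Camera-Trap Surveys
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing diel (24-hour) activity patterns of mammals
    from camera-trap detection records. Computes sunrise and sunset with a
    low-precision NOAA ephemeris and partitions each day into twilight, day
    and night; filters detections for temporal independence; normalises
    detection counts into photographic frequencies per hour per 100 trap-days;
    formally classifies each species as diurnal, nocturnal, crepuscular or
    cathemeral using one-way ANOVA with Steel-Dwass all-pairs ranking;
    estimates smooth activity curves by circular (von Mises) kernel density
    estimation; and tests predator-prey and competitor co-detection with
    Poisson mixed models using a camera-site random intercept. Includes a
    synthetic survey generator with planted diel structure (inhomogeneous
    Poisson thinning, optionally sun-anchored) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    lme4,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    geosphere,
    jsonlite,
    withr
Config/testthat/edition: 3
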