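Package: dialvol
Title: Absolute Blood Volume and Vascular Refilling Kinetics in Hemodialysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing intradialytic fluid-volume kinetics in
    maintenance hemodialysis. Estimates absolute blood volume at treatment
    start from the relative-blood-volume response to a dialysate bolus of
    known volume (indicator dilution), decomposes the intradialytic volume
    balance into ultrafiltration and vascular refilling (volumes, rates and
    refilling fractions), and provides the longitudinal statistics layer
    used for thrice-weekly treatment schedules: linear mixed models with
    AIC-based selection of random study-day slopes, repeated-measures
    correlation, per-patient coefficients of variation, bootstrap confidence
    intervals of the mean and Benjamini-Hochberg false-discovery-rate
    control. A two-compartment (intravascular/interstitial) fluid-kinetics
    simulator generates synthetic cohorts with known ground truth for
    validation, including machine sampling dialects, signal artifacts and
    sawtooth interdialytic fluid-overload accumulation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
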