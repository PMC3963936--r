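Package: stunmird
Title: MIRD Internal Dosimetry and Thyroid Stunning Analysis for Tc-99m
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale internal dosimetry and radiobiology analysis for
    Tc-99m pertechnetate in the mouse thyroid.  Provides a seeded Monte
    Carlo calculator for the thyroid self S-value on a synthetic voxel
    phantom (range-based electron transport with a packaged stopping-power
    table, analytic mean-chord photon absorption), time-activity curve
    fitting (linear uptake, mono-exponential washout) with closed-form
    cumulated activity, the MIRD absorbed-dose chain, stunning
    dose-threshold detection, longitudinal recovery profiling, comparative
    Ct (2^-dCt) expression analysis, and seeded synthetic cohort
    generators so that the whole pipeline is testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
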