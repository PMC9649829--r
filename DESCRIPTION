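Package: sleepwm
Title: White-Matter Microstructure and Sleep-Wake Disturbance Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for linking regional white-matter fractional anisotropy (FA)
    to subjective and objective sleep-wake measures in two-group clinical
    cohorts. Implements Karolinska Sleep Questionnaire indices (disturbed sleep
    and disturbed awakening), Cole-Kripke scoring of 1-min actigraphy epochs
    within diary-defined rest intervals, aggregation of 48 JHU-atlas ROI FA
    values into global and callosal summaries, covariate-adjusted group tests
    and partial correlations with bootstrap confidence intervals and
    Benjamini-Hochberg false-discovery-rate control, percentile-bootstrap
    simple mediation, and two-block partial least squares correlation (PLS-C)
    with inertia permutation testing and Procrustes-aligned bootstrap salience
    confidence intervals. A synthetic-cohort simulator with planted latent
    structure supports calibration and power checks, and a pipeline driver
    orchestrates the full analysis reproducibly from a single seed.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
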