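Package: midvif
Title: Design Diagnostics and Bias Simulation for Rapid-Event fMRI GLMs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for diagnosing collinearity in task-fMRI general linear
    model designs and for quantifying the estimation bias introduced by common
    collinearity work-arounds. Implements contrast efficiency, the traditional
    variance inflation factor (tVIF), and a contrast-based variance inflation
    factor (cVIF) that detects condition-signal overlap invisible to tVIF;
    an emulator for Monetary Incentive Delay (MID) task schedules with the
    trial structure used in large developmental cohort studies; a simulation
    engine comparing a cue-plus-feedback impulse model against a saturated
    boxcar model (bias, type I error, power); and group-level one-sample
    inference with site-stratified sign-flip cluster-extent permutation
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    yaml,
    optparse,
    ggplot2,
    RNifti
Config/testthat/edition: 3
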