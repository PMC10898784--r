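Package: connectoprint
Title: Functional Connectome Fingerprinting and Idiosyncrasy-Informed
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacological brain-fingerprinting analyses of
    parcellated BOLD time series: split-half functional connectomes,
    within-condition identifiability metrics (Iself, Iothers, Idiff),
    edgewise class-1 intraclass correlation maps of connectome
    idiosyncrasy, PCA-based prediction of subjective drug experience with
    random and spherical-rotation (spin) null ensembles, and
    characterization of predictive connectivity patterns at the
    resting-state-network level. Includes a synthetic cohort generator
    that emulates a two-condition (drug vs. placebo) study with
    subject-stable idiosyncratic covariance structure and a planted
    behavior-coupled default-mode-network edge pattern.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
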