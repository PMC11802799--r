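Package: srclock
Title: Singularity-Response Analysis of Circadian Phase Resetting
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies circadian phase resetting with singularity-response
    (SR) parameters: a circular limit-cycle stimulus model that generates and
    classifies phase response curves (PRCs), estimators of SR amplitude and
    phase from model PRCs, single-cell phase-response records, or plate
    bioluminescence time series, an inverse map that reconstructs PRCs from SR
    parameters, Hill dose-response parameterization, prediction models for
    mixed stimuli, background (pre-treatment) effects and receptor
    antagonists, and a Stuart-Landau oscillator-ensemble simulator used to
    validate the whole chain on synthetic plates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
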