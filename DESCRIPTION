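Package: gammarep
Title: Stimulus-Specific Repetition Effects on V1 Firing Rates and Gamma Synchronization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for stimulus-repetition effects in
    primary visual cortex recordings. Generates synthetic multi-site LFP and
    multi-unit-envelope sessions with controlled repetition trajectories
    (natural-image interleaved sequences and grating/location block designs),
    estimates LFP power (Hann and DPSS multitaper) and MUA-LFP pairwise phase
    consistency, detects and validates per-stimulus gamma-band peaks, fits
    early/late repetition slopes and repetition-related change (RRC), measures
    drive dependence of repetition effects with cross-validated intercept-slope
    correlations, and tests stimulus specificity with a split-half correlation
    of z-scored repetition trajectories against a stimulus-reshuffling
    permutation null. Includes sign-flip and exchange permutation tests,
    bootstrap standard errors, FDR correction, block-design regression models,
    and microsaccade/pupil preprocessing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
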