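Package: pollendiary
Title: Symptom Scores, Pollen Seasons and User Filtering for Crowdsourced Hayfever Diaries
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for electronically collected pollen-allergy symptom
    diaries. Implements four symptom-score calculations for daily diary entries
    (a combined symptom and medication score with a weighted medication table, its
    0-10 symptom load index normalization, an eyes-and-nose score following the
    European Medicines Agency immunotherapy-trial directive, and its symptom load
    index), pollen-season definition from percentiles of the Annual Pollen
    Integral, correlation-based selection of allergy-responsive users, daily
    pooled score series with organ and medication contribution decompositions,
    and detrended (first-differenced) pairwise Pearson comparison of the score
    calculation methods. Includes a synthetic cohort generator producing seasonal
    pollen curves and dose-responsive diaries so the whole pipeline is testable
    without access to the original diary database.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    stats,
    utils,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
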