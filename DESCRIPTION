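Package: bhsii
Title: Scoring and Psychometric Validation of the Bologna Healing Stifle
    Injury Index
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for scoring the Bologna Healing Stifle Injury Index
    (BHSII), a 34-item combined owner and clinician outcome instrument for
    dogs treated surgically for cranial cruciate ligament rupture, and for
    running its full clinimetric validation pipeline: test-retest
    reliability (intraclass correlation), internal consistency
    (Cronbach's alpha), construct validity (ROC discrimination with exact
    binomial confidence intervals, Spearman correlation matrices with
    qualitative banding), and responsiveness to clinical change (paired
    Wilcoxon, Kruskal-Wallis, chi-squared). Includes an ordinal
    item-response simulator that generates synthetic control and surgical
    cohorts with tunable inter-item correlation, test-retest stability,
    group separation, healing trajectories, and dropout, so the pipeline
    can be exercised end to end without access to clinical data.
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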