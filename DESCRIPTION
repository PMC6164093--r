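Package: vidffq
Title: Scoring and Validation of Vitamin D Food Frequency Questionnaires
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores brief vitamin-D-only food frequency questionnaires
    (FFQs) against a per-serving content key with an individualized fish
    calculation key, scores 3-day dietary records through a pluggable food
    composition table, and runs the full method-agreement battery used in
    FFQ validation studies: Bland-Altman analysis (natural and log scale)
    with the Bland-Altman index, quartile cross-classification with linearly
    weighted Cohen's kappa, adequacy classification against the Estimated
    Average Requirement cutpoint, Spearman rank correlation, Mann-Whitney U,
    Shapiro-Wilk screening, and ICC(3,1) with Shrout-Fleiss confidence
    intervals. Ships the Cro-VIDEO-FFQ instrument key as a packaged fixture
    and a synthetic cohort generator with controllable intake distributions
    and between-method agreement for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    yaml,
    jsonlite,
    withr,
    stats,
    generics
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
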