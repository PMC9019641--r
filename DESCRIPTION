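Package: eq5dhrqol
Title: EQ-5D-3L Utility Scoring, Health-State Grading and Cohort Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for analysing health-related quality of life measured with
    the EQ-5D-3L descriptive system in cross-sectional survey cohorts. Scores
    5-digit health states to utilities with the Chinese time trade-off value
    set, grades states into four severity classes from their distance to full
    health, and compares groups with Pearson chi-square tests (with Yates
    continuity correction on 2x2 tables), the Freeman-Halton exact test for
    r x c contingency tables, Welch t tests from summary statistics, and
    proportional-odds ordinal logistic regression fitted by Newton iteration.
    Includes a synthetic-cohort generator with a latent-severity copula so the
    full analysis pipeline is testable without respondent-level data, and a
    deterministic 250-respondent fixture cohort reproducing the marginal
    tables of a cross-sectional study of HIV-positive and HIV-negative
    pregnant women.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
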