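Package: carecomplexity
Title: Care-Complexity Scoring and Allocation Analysis for Inpatient Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools to measure the complexity of inpatient care and evaluate
    whether patients are allocated to care settings consistent with it.
    Implements National Early Warning Score (NEWS) computation from vital
    signs with a configurable band table, the eight-dimension modified Index
    of Caring Dependence (mICD), and their matrix combination into a
    categorical Index of Caring Complexity (ICC). Provides cohort analyses
    on hospital records: patient-day expansion, cross-tabulation of
    complexity by care setting and ward with chi-square tests,
    allocation-consistency rates, per-patient outcome summaries, and
    nonparametric group comparisons. Includes a seeded synthetic-cohort
    generator that emulates a medical-area hospital population so the whole
    pipeline can be exercised without access to real records, plus CSV
    readers/writers and tidy report output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    yaml,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
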