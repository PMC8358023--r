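Package: ctdnaflow
Title: Longitudinal Circulating Tumor DNA Variant Filtering and Response Tracking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for targeted-panel circulating tumor DNA (ctDNA)
    analysis in patients under treatment: molecular-barcode (UMI) duplicate
    collapsing, a cfDNA/tissue/PBMC variant filter cascade with matched-normal
    germline subtraction and a cohort-level clonal-hematopoiesis blacklist,
    longitudinal average-VAF trajectories with a clearance cutoff,
    tissue-plasma concordance with sub-threshold rescue, emergent
    resistance-mutation detection at progression, and the accompanying cohort
    statistics (Kaplan-Meier/log-rank, correlations, rank tests, frequency
    tables, exact binomial power). Includes a synthetic cohort generator so
    every stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    purrr,
    rlang,
    jsonlite,
    yaml,
    vcfR,
    survival,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
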