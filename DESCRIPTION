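Package: faersqt
Title: Disproportionality Screening of Drug-Induced QT Prolongation and
    Torsade de Pointes in FAERS-Style Report Streams
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance signal
    detection of drug-induced QT-interval prolongation and torsade de
    pointes from spontaneous adverse-event report streams in the openFDA
    drug-event JSON dialect. Identifies target reports with the
    narrow-scope standardized MedDRA query for torsade de pointes / QT
    prolongation, curates a primary-suspect drug list (synonym merging,
    ambiguous-name exclusion, ATC coding) with a fully audited exclusion
    ledger, computes reporting odds ratios with 95% confidence intervals
    from two-by-two contingency tables at the preferred-term and SMQ
    levels, classifies positive signals, and integrates results into
    ranked reporting-proportion tables, positive-signal-count
    distributions, and ATC-class signal profiles. Ships a synthetic
    report-stream generator with planted association strengths so every
    stage is testable against known ground truth.
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
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
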