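Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event
    Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: An end-to-end pharmacovigilance pipeline for quarterly
    spontaneous-report extracts in the FAERS (FDA Adverse Event Reporting
    System) layout: parsing of the "$"-delimited DEMO/DRUG/REAC/OUTC/INDI
    tables, multi-version case deduplication, indication-restricted cohort
    construction with drug-name and MedDRA preferred-term dictionaries,
    drug-event disproportionality statistics (proportional reporting ratio,
    reporting odds ratio, Yates-corrected chi-square, BCPNN information
    component with asymmetric credibility bounds) with per-metric signal
    flags, and pairwise between-drug comparisons of event constituent
    ratios and outcome severity.  A seeded synthetic-report generator with
    planted reporting-rate ratios makes the whole pipeline testable without
    any download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
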