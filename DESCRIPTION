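Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection from spontaneous
    reporting data in the FDA Adverse Event Reporting System (FAERS) quarterly
    ASCII dialect. Reads and merges DEMO/DRUG/REAC quarterly extracts,
    deduplicates multi-version cases, standardizes drug names and adverse event
    terms with user-supplied mapping tables, computes reporting odds ratios
    (ROR) and proportional reporting ratios (PRR) with Woolf confidence
    intervals and Yates-corrected chi-squared statistics from per-pair 2x2
    contingency tables, ranks top-N drugs per event, classifies multi-event
    high/medium signaling drugs by set intersection, and profiles configurable
    drug panels across events. Includes a synthetic-report generator with
    planted odds ratios so every pipeline stage is testable without a FAERS
    download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr (>= 1.1.0),
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
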