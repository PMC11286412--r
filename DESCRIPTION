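Package: pvsignal
Title: Disproportionality Signal Detection for Spontaneous Adverse-Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A pharmacovigilance pipeline for spontaneous-report databases in
    the style of the FDA Adverse Event Reporting System (FAERS): reading and
    writing report tables, report cleaning (duplicate removal with
    latest-event retention, drug-name standardization, exclusions),
    MedDRA preferred-term event matching, four-fold contingency tables, and
    signal detection with the reporting odds ratio (ROR, Wald 95% CI) and the
    proportional reporting ratio (PRR, continuity-corrected chi-square).
    Includes therapeutic-category rollups, demographic descriptives, and a
    seeded synthetic-report generator with configurable true reporting odds
    ratios for validation studies.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    vctrs,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
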