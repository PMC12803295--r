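Package: crfqa
Title: Edit Checks and Quality-Assurance Monitoring for Multi-Site
    Longitudinal Study Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A computational back end for data quality assurance in
    multi-site longitudinal clinical studies that capture case report
    forms (CRFs) and patient-reported outcomes (PROs) in REDCap-style
    flat exports. Provides schema-driven ingest of records and data
    dictionaries into tidy observation tables, a declarative edit-check
    engine (missingness, duplicate-entry mismatch, conditional
    missingness, chronology, location mismatch, unspecified reasons,
    range), completion and error status classification with
    subject-level streaks and UpSet-style completeness combinations,
    score distribution summaries with Tukey-fence outlier flagging,
    time-windowed site-level error reports with CSV/spreadsheet/HTML
    export, and Poisson/negative-binomial trend models quantifying the
    monthly change in error counts. A built-in synthetic-study
    simulator with ground-truth error injection makes every component
    testable without access to restricted study data.
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
    lubridate,
    MASS,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
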