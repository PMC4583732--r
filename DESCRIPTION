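Package: mtoburden
Title: Economic Burden Analysis of Overseas Medical Treatment
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the household and national economic burden of
    overseas medical treatment (MTO) from traveler-level survey microdata:
    per-visit cost accounting with payer split and per-capita allocation
    between patient and caretakers, catastrophic health expenditure statistics
    (headcount, overshoot, mean positive overshoot), national cost
    extrapolation with bootstrap standard errors, ICD-10 chapter aggregation,
    non-parametric group and trend tests, and a calibrated synthetic survey
    generator so the full pipeline can be exercised without confidential data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    readr,
    rlang,
    jsonlite,
    yaml,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
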