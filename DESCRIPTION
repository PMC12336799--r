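Package: rtnomen
Title: Harmonizing Radiotherapy Structure Names to the TG-263 Nomenclature
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for standardizing radiotherapy organ-at-risk (OAR) structure
    names to the AAPM TG-263 nomenclature. Extracts ROI names from DICOM RT
    Structure Set files or tabular exports, filters auxiliary and target
    structures, deduplicates center-specific names, and maps them to TG-263
    standard names through a pluggable renaming backend (a deterministic
    multilingual fuzzy-matching backend is included; remote chat-completion
    endpoints are supported). Includes the full evaluation stack: five-part
    prompt construction, structured response parsing, unique and overall
    renaming accuracy, a five-category error taxonomy (wrong OAR,
    laterality/locality, plurality, misspelling, no match), self-reported
    confidence correlation, and Monte-Carlo label-entropy uncertainty
    estimation, plus a synthetic multilingual corpus generator for
    benchmarking without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
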