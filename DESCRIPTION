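Package: claimscope
Title: Transparent Claim Extraction and Evidence Synthesis for Cell-Level
    Outcomes in Biomedical Abstracts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A knowledge-based pipeline that scans MEDLINE/PubMed abstracts for
    cell-death, cell-proliferation and general cell-change outcomes and
    characterizes each mention as supporting, neutral or refuting evidence for a
    chemical of interest. Implements markup-aware abstract ingestion, biomedical
    sentence segmentation with itemized-list expansion, resolution of elliptical
    coordinated compound noun phrases over dependency parses, lexicon-driven
    outcome matching with outcome-level negation, anchor-verb claim extraction
    with claim-level negation, reconciliation onto a six-step evidence direction
    scale, and claim- versus abstract-level aggregation with waffle-plot
    reporting for risk-assessment decision support. Includes a seeded synthetic
    abstract generator with gold dependency parses so every stage is testable
    offline.
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
    xml2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
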