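Package: psarag
Title: Guideline-Concordant PSA Testing Recommendations via a
    Retrieval-Augmented Rule Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Clinical decision-support pipeline for prostate-specific
    antigen (PSA) testing recommendations. Implements an age-adjusted
    Charlson Comorbidity Index calculator with a ten-year life-expectancy
    gate, a deterministic dual-guideline (EAU/AUA) recommendation engine,
    a retrieval-augmented generation architecture with pluggable offline
    backends (lexical BM25 retrieval, prompt assembly, mock and scripted
    generators), an evaluation harness with a four-way recommendation
    error taxonomy, Fleiss kappa interrater agreement with bootstrap
    confidence intervals, and a seeded synthetic case-cohort generator
    with gold-standard labels.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    yaml,
    digest,
    optparse,
    stats,
    utils,
    tools
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
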