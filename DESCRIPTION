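Package: omicscout
Title: Disease-Scoped Literature and Omics-Repository Scanning with
    Curation Ledgers and Over-Representation Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Offline-first toolkit for disease-scoped surveys of the
    biomedical literature and public omics repositories. Builds PubMed-style
    boolean queries, parses PubMed XML and MEDLINE records into a corpus
    store, atomizes abstracts into ranked word, gene and drug mention
    tables with sentence-level context extraction, assigns articles and
    deposited studies to omics categories by keyword rules, performs
    hypergeometric over-representation analysis with Benjamini-Hochberg
    false-discovery control over GMT gene-set collections, and tabulates
    study metadata with sample-count aggregation. Every filtering step is
    accounted for in explicit curation ledgers, and a deterministic
    synthetic-fixture generator with planted, exactly recoverable counts
    makes the whole pipeline testable without network access.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    jsonlite,
    rlang,
    stats,
    stringr,
    tibble,
    tools,
    utils,
    withr,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
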