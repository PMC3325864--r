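Package: ripare
Title: RIP-Chip Enrichment, ARE Motif Scanning, Dose-Response and
    Drug-Combination Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying RNA-binding-protein-driven drug response in
    cancer cell lines: four-parameter logistic (4PL) dose-response fitting
    with IC50 and fold-resistance estimation; Loewe-additivity combination
    index analysis for fixed-ratio two-drug designs with bootstrap
    classification of synergy and antagonism; a RIP-chip microarray
    filtering pipeline (log2 transform, 75th-percentile-shift
    normalisation, median baselining, detection-flag and
    coefficient-of-variation filters, Welch t-tests with
    Benjamini-Hochberg correction, fold-change thresholds); AU-rich
    element (ARE) motif counting in 3'UTRs with EASE-score ranked nested
    enrichment scans; per-cell nucleocytoplasmic translocation z-scores;
    and synthetic-data generators that emulate every input so the whole
    pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    Biostrings,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
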