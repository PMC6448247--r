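Package: graftquant
Title: Co-Localization Quantification of Grafted Cells and Category-Level
    Functional Enrichment Aggregation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies marker co-expression of grafted cells in multi-channel
    confocal sections with an automated macro-style chain (channel
    multiplication, thresholding, distance-transform watershed, size and
    circularity gating) and aggregates gene-set over-representation results
    into manually curated functional categories using a median-FDR plus
    correlation-adjusted competitive gene-set test dual significance rule.
    Includes an assumption-driven statistical test-selection workflow and
    synthetic-data generators (planted co-localization images and planted
    enrichment studies) so every stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    EBImage,
    SummarizedExperiment,
    S4Vectors,
    fgsea,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
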