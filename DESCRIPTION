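Package: oimet
Title: Expression Signatures and Regulatory Enrichment for OVOL-Induced
    Mesenchymal-to-Epithelial Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds differential-expression signatures for OVOL-induced
    mesenchymal-to-epithelial transition (OI-MET) across breast and prostate
    cancer models, calls gene- and isoform-level regulation patterns
    (up, down, up/down, isoform switch), tests gene sets for literature
    co-occurrence enrichment with a resampling null and a contingency
    chi-square, scores single-motif and motif-pair over-representation in
    promoter sets under a product-of-folds independence expectation, and
    quantifies transcription-factor promoter/peak co-occupancy from ChIP-Seq
    intervals against an independence expectation. A synthetic-data module
    generates inputs with known ground truth for every stage, and a
    parsimonious seed-network builder reconstructs transcription-factor
    target networks from edge lists.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
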