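Package: asmtp
Title: Text-Processing Similarity Measures for Ligand-Based Virtual Screening
Version: 1.0.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements the Adapted Similarity Measure of Text Processing
    (ASMTP) for molecular count fingerprints, together with the standard
    comparison coefficients (Tanimoto in continuous and binary form, Dice,
    cosine, Euclidean, extended Jaccard) and a complete simulated
    virtual-screening harness: seeded random reference selection per activity
    class, deterministic decreasing-order ranking of a compound database, and
    early-recognition evaluation (recall at percentage cutoffs, sensitivity
    and specificity, ROC/AUC, enrichment factors, and BEDROC). A synthetic
    generator produces class-structured sparse count-fingerprint datasets so
    the whole pipeline is testable without licensed chemical databases, and a
    small command-line interface orchestrates simulate, screen and evaluate
    runs with JSON manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    jsonlite,
    methods,
    optparse,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
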