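Package: taascreen
Title: Single-Sample Gene Expression State Inference and Tumor-Associated
    Antigen Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers binary gene expression states (expressed / not expressed)
    in individual bulk RNA-seq samples from a two-component lognormal mixture
    fitted by expectation-maximization with housekeeping-gene-informed
    initialization, and converts abundances to posterior expression
    probabilities by Bayes' rule. Aggregates single-sample calls into
    tissue-level non-expressed ratios to identify dormant genes across a
    normal-tissue atlas and predicts candidate tumor-associated antigens
    (TAAs) from tumor cohorts. Includes comparator methods (fixed TPM
    thresholds, zFPKM, exponential + negative-binomial mixture), a
    chromatin-state reference-standard builder, per-sample and tissue-level
    precision-recall benchmarking, and a seeded multi-tissue cohort simulator
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse,
    withr
Config/testthat/edition: 3
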