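Package: ethysmall
Title: Small RNA Discovery, miRNA Target Scoring and Differential
    Expression for Ethylene-Treated Plant Tissues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale reimplementation of a plant small-RNA analysis
    workflow: de novo miRNA identification from small RNA-seq reads (quality
    filtering, adapter trimming, tag collapsing, exact genome matching,
    structural-RNA exclusion, hairpin folding with mismatch-ratio screening
    of the miRNA/miRNA* duplex), miRNA target prediction with a
    position-dependent mispairing penalty system, differential expression
    of miRNAs (CP10M) and genes (FPKM/RPKM) with Benjamini-Hochberg
    correction, and the tissue-specific / genotype-dependent set integration
    that pairs up-regulated miRNAs with down-regulated targets. Ships a
    synthetic-data generator that plants miRNA hairpin loci, structural RNAs,
    target sites of known penalty score and differential effects with
    machine-readable ground truth, so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    BiocGenerics,
    Biostrings,
    Rcpp,
    generics,
    dplyr,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    GenomicRanges,
    rtracklayer,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
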