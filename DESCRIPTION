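Package: tsrpipe
Title: Multi-Tissue Space Responsiveness Analysis for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Medaka", "Transcriptomics", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for quantifying and ranking transcriptome
    responses to spaceflight across multiple tissues. Implements RPKM
    quantification over flattened (integrated-exon) gene models, expression
    filtering, per-tissue log2 space-responsiveness scores (SR), the
    cross-tissue composite norm ||TSR||, twofold/multi-tissue/tissue-specific
    responder classification, Fisher's exact inter-tissue comparisons,
    ortholog-chain GO over-representation with hypergeometric tests and
    Benjamini-Hochberg FDR control, Cluster 3.0 compatible hierarchical
    clustering (CDT/GTR output), and a negative-binomial count simulator
    with planted effects so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    IRanges,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    GenomicRanges
Config/testthat/edition: 3
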