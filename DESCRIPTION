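Package: tagdge
Title: Tag-Based Digital Gene Expression Profiling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for restriction-enzyme anchored (NlaIII/MmeI)
    digital gene expression tag profiling. Builds a virtual CATG+17 reference
    tag library from a transcriptome, filters raw tag reads into clean tag
    libraries, maps clean tags to genes allowing at most one mismatch with
    exact-match priority, normalizes unambiguous per-gene counts to tags per
    million (TPM), and calls differentially expressed genes with the
    Audic-Claverie exact test under Benjamini-Hochberg false discovery rate
    control and fold-change thresholds. Includes saturation and correlation
    diagnostics, hypergeometric term enrichment of gene sets, delta-delta-Ct
    qPCR summaries, and a synthetic-data generator with planted ground truth
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    BiocGenerics,
    Biostrings,
    methods,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
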