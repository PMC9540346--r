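Package: regenhancer
Title: Regeneration-Responsive Enhancer Discovery from Single-Cell Chromatin Accessibility
Version: 0.1.0
Authors@R: person("Analysis", "Pipeline", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Identifies regeneration-responsive elements (RREs) from
    differential single-cell ATAC-seq peaks, links them to differentially
    expressed genes within +/-50 kb windows, tests overlap enrichment with an
    upper-tail hypergeometric statistic computed in log space, discovers de
    novo sequence motifs and motif co-occurrence with a small four-layer
    convolutional neural network trained on 400 bp elements, and partitions
    enhancers by Sox/Six motif content.  A synthetic-data generator produces
    every pipeline input with a known ground-truth manifest so that each
    stage can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    jsonlite,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
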