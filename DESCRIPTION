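Package: h2azdyn
Title: Histone Variant H2A.Z Occupancy Dynamics from ChIP-Seq Tag Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end ChIP-seq occupancy analysis for histone variant
    H2A.Z across a somatic-cell reprogramming time course (fibroblast,
    intermediate, induced pluripotent stem cell). Provides a Poisson
    sliding-window peak caller, a strand-aware seven-class genomic feature
    partition (promoter, 5'UTR, CDS, intron, 3'UTR, downstream, intergenic),
    peak-to-feature assignment with a relative-enrichment statistic,
    TSS/TES composite (metagene) coverage profiles with expression-class
    stratification, occupied-gene set dynamics across samples, generic
    hypergeometric gene-set over-representation, ChIP-qPCR fold-over-IgG,
    and a seeded synthetic tag simulator with planted ground truth so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    data.table,
    jsonlite,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
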