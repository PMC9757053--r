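Package: dysnet
Title: Cis-Regulatory Mutations and Trans-Dysregulation of Gene Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts protein-coding and miRNA genes whose cis-regulatory
    (transcription factor binding site) or loss-of-function somatic mutations
    are associated with trans-dysregulation of their gene networks in cancer
    cohorts. Implements a hierarchical Bayesian model that decomposes each
    network partner's expression into down/neutral/up regulatory statuses via
    Gaussian mixtures and computes exact posterior probabilities of
    dysregulation per sample (SSD) and across the cohort (DAC), with an
    empirical false discovery rate based on shuffled network and mutation
    controls. Includes genomic interval arithmetic for binding-site and flank
    analyses, mutation-rate shuffling nulls, expression normalization and
    expressed-gene filtering, weighted gene-gene and miRNA-target network
    construction, enrichment and survival utilities, and a synthetic cohort
    simulator with planted cis-regulatory drivers for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    methods,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    edgeR,
    igraph,
    survival,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    VariantAnnotation,
    SummarizedExperiment,
    mclust
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
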