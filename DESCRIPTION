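Package: clonetrace
Title: Clonal Phylogeny Reconstruction and Rare-Lineage Tracking from
    Serial Tumor Sequencing
Version: 0.1.0
Authors@R:
    person("Packaging", "Team", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Reconstructs the clonal architecture of serially sampled
    cancers from multi-sample somatic variant read counts. Provides
    quality and germline filtering with an exact binomial test and
    Benjamini-Hochberg control, a beta-binomial site-specific error
    model for presence calling, Dirichlet-process binomial mixture
    clustering of mutations in per-sample cancer-cell-fraction space,
    pigeonhole-principle clone-tree construction, per-branch
    96-channel mutational-signature extraction and refitting,
    position-weight-matrix scanning for recombination signal
    sequences near deletion breakpoints with exact p-values, and a
    statistically powered aggregated-site test that detects a defined
    lineage at very low cell fractions. A fully specified synthetic
    study generator with machine-readable ground truth makes every
    stage testable without access to controlled patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    data.table,
    jsonlite,
    Rcpp,
    Biostrings,
    ape
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation,
    GenomicRanges,
    SummarizedExperiment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
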