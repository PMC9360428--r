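Package: screvolve
Title: Single-Cell Regulatory Network States and Treatment-Response
    Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription-factor regulons from single-nucleus RNA-seq
    data, scores their per-cell activity as eigengenes with permutation
    significance, groups regulons into transcriptional programs and cells into
    network states, computes chromVAR-style motif accessibility deviations and
    TSS-proximity gene scores from snATAC-seq fragments, calls consensus
    transcription factors supported by both modalities, and classifies regulon
    activity trajectories across longitudinal treatment stages (pre-treatment
    to recurrence). Ships a coupled multi-omic synthetic data generator with a
    planted TF-regulon-program-state hierarchy so every stage of the pipeline
    can be validated against a known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    cluster,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    mclust,
    jsonlite,
    withr
Config/testthat/edition: 3
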