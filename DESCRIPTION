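Package: scshift
Title: Quantifying Condition-Driven Transcriptional Shifts in Single-Cell Clusters
Version: 0.1.0
Authors@R: person("scshift", "maintainers", email = "scshift@example.org", role = c("aut", "cre"))
Description: Quantifies how strongly a disease condition perturbs the
    transcriptional state of each cell population in a droplet scRNA-seq
    experiment. The core statistic is the Bhattacharyya distance between
    condition-specific cell clouds in principal-component space, estimated by
    repeated subsampling and calibrated against a mixed-population null in
    which the two groups are pooled and resampled. Around it the package
    provides 10x-style MatrixMarket input/output, the standard quality-control
    filters (detected-gene bounds, mitochondrial/ribosomal UMI fraction),
    log-normalization, variable-gene selection, PCA, per-cluster
    differential-expression counting, gene-set mean-activity scoring,
    cell-proportion shift tests, a negative-binomial synthetic-data generator
    with planted perturbations, and a reproducible command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
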