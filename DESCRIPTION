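Package: plstate
Title: Phase-Locking State Analysis of Dynamic Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Leading-eigenvector dynamics analysis (LEiDA) of parcellated
    BOLD time series: instantaneous phases via the analytic signal, dynamic
    phase-coherence matrices and their sign-canonicalized leading
    eigenvectors, detection of recurrent phase-locking states by k-means
    clustering under cosine distance across a range of granularities,
    fractional-occupancy statistics with permutation group tests and
    Hedges' g effect sizes, grouping of states into cross-granularity
    coupling modes, and Spearman correlation of occupancies with subject
    covariates under Holm-Bonferroni correction. Includes a synthetic
    cohort generator that plants known phase-locking states so every stage
    of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    jsonlite,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
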