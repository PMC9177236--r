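Package: gango
Title: Greedy Adjacencies and Non-Gaussian Orientations for Causal Connectomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Constructs directed ("causal") connectomes from parcellated
    resting-state time series using a two-stage pipeline: a score-based
    greedy equivalence search (BIC-penalized likelihood) recovers a sparse
    adjacency structure, which is then symmetrized and every adjacency is
    oriented with an outlier-robust skewness-based pairwise likelihood-ratio
    statistic under the linear non-Gaussian acyclic model. Includes a
    per-subject non-Gaussianity gate (rank-sum test of parcel skewness
    against Gaussian surrogates), directed-graph centrality and
    participation-coefficient analytics with random-digraph hub nulls,
    module-level (resting-state network) connectivity and direction
    statistics, virtual-lesion vulnerability analysis, and a linear
    non-Gaussian synthetic-data generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
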