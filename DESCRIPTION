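Package: orthonet
Title: Ortholog Detection from Aligned Protein Interaction and Gene
    Coexpression Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scores candidate cross-species ortholog pairs by combining
    sequence homology with the similarity of their local network
    neighborhoods. Candidate pairs (taken from bidirectional BLAST hits)
    are described by homology-weighted shortest-path and random-walk graph
    kernels computed over 1- and 2-hop neighborhoods, together with
    normalized centrality agreement scores (BaryCenter, betweenness,
    degree, HITS), and classified as orthologous or not with boosted
    trees, naive Bayes, support vector machines, logistic regression and
    their ensemble. Includes weighted coexpression-network construction
    from expression matrices (Spearman correlation with an absolute-value
    cutoff), a reciprocal-best-BLAST-hit baseline, ten-fold
    cross-validated AUC evaluation with average-rank method comparison,
    and synthetic generators that plant known orthologs so the whole
    pipeline can be exercised without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
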