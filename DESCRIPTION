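Package: fairgibbs
Title: Gibbs Posterior Inference for Fair Clustering Under Balance Constraints
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generalized Bayesian (Gibbs posterior) inference for clustering
    under a balance constraint on a two-level protected attribute. Observations
    are decomposed into fairlets (minimal balanced sets) by constrained binary
    optimal transport, fairlet centers are clustered under a factorized loss
    (squared Euclidean / k-means or Manhattan / k-medians), and a
    Metropolis-within-Gibbs sampler explores the joint posterior over fairlet
    decompositions and cluster configurations. Every posterior draw is balanced
    by construction, so point estimates inherit fairness while the draws supply
    uncertainty summaries: pairwise co-clustering probabilities, the
    least-squares configuration, and per-observation misclassification
    probabilities. Includes synthetic-data generators for well-specified
    (Gaussian) and heavy-tailed (Student-t) two-cluster designs, tidy accessors,
    and a small command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    MASS,
    mclust,
    rlang,
    tibble,
    dplyr,
    tidyr,
    purrr,
    readr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
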