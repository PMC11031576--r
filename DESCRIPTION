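Package: consensusbn
Title: Consensus Bayesian Networks from Multi-Batch Discretized Expression Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Learns robust gene-interaction networks from heterogeneous
    gene-expression experiments. Provides differential-expression signal
    selection with false-discovery-rate thresholding, per-dataset
    equal-frequency discretization into three ordered states, cross-dataset
    merging, Bayesian-network structure learning by simulated annealing under
    the BDeu marginal-likelihood score, consensus-network construction from
    the top-scoring networks of each search, and weighted aggregation of
    repeated consensus runs with a majority-support arc filter. Includes a
    synthetic-data generator (ground-truth networks, conditional probability
    tables, ancestral sampling, multi-batch continuous emission) so that
    every stage of the pipeline can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
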