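Package: tegem
Title: Interpretable Contrastive Embeddings of Time-Evolving Graphs with
    Metastable Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns low-dimensional embeddings of time-evolving graphs that
    preserve metastable dynamics, with applications to microbial
    co-occurrence networks built from OTU count tables. Provides an
    overdamped Langevin simulator for multi-well potentials, generators of
    synthetic time-evolving graphs with planted state-discriminating
    topology, an adjacency-masked Transformer encoder with a recurrent
    master node trained with an InfoNCE contrastive objective,
    attention-gradient relevance propagation for per-node interpretability,
    and clustering-based evaluation (k-means, adjusted Rand index) against a
    PCA baseline on flattened adjacency matrices.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
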