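Package: atompool
Title: Atomic Graph Pooling via Boolean Matrix Factorization for Graph
    Classification
Version: 0.1.0
Authors@R:
    person("Atompool", "Developers", email = "atompool@example.org",
           role = c("aut", "cre"))
Description: Hierarchical graph pooling for graph classification built on
    sparse structural representation. Each node's degree-capped ego-network
    is vectorized into a binary sampling matrix which is factorized, over
    the Boolean semiring, into a dictionary of recurring structural "atoms"
    and a sparse code by a greedy coverage algorithm. Atom/node co-occurrence
    counts are normalized into a column-stochastic assignment matrix that
    coarsens node features (X' = S X) and adjacency (A' = S A S') in one
    pooling step. The package ships a complete graph classification network
    (embedding GCN, stacked convolution + pooling blocks, max/mean/sum
    readout, MLP head) with Adam training, early stopping and stratified
    cross-validation, a TU-format flat-file reader/writer, a motif-planting
    synthetic dataset generator with ground truth, and atom-level
    interpretability reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
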