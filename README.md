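# atompool

Interpretable hierarchical graph pooling for graph classification, built on
sparse structural representation.

## Who this is for

Anyone classifying small graphs — molecules, protein contact maps, social
ego-networks — who wants the pooling step of a GNN to be *inspectable*:
instead of clustering nodes by learned scores, each super-node here is an
explicit recurring subgraph pattern (an **atom**, e.g. a functional group or
a community motif), and every node's assignment to it can be traced.

## The method

One pooling step, for a graph with adjacency `A` (binary, symmetric) and
features `X`:

1. **Ego-network sampling.** Per node: the node plus its up-to-`S−1`
   highest-degree neighbors; the induced adjacency, zero-padded to `S×S` and
   vectorized, becomes a column of the sampling matrix
   `Y ∈ {0,1}^(S²×N)`.
2. **Boolean matrix factorization.** `Y ≈ D ∘ C` over the Boolean semiring
   (`∘` = OR-of-ANDs), by greedy coverage: candidates are rows of the
   confidence matrix `R_ij = 1[⟨y_i,y_j⟩/⟨y_i,y_i⟩ ≥ φ]`; each step adds the
   candidate maximizing `ω·(new 1s covered) − (0s overwritten)`. Columns of
   `D` reshape to `S×S` atom subgraphs; `C` marks which atoms occur in which
   ego-network.
3. **Assignment.** With affiliation matrix `M` (`M[j,t]=1` iff node j is in
   ego-network t), raw weights `(C Mᵀ)_ij / |E(v_j)|` are renormalized per
   column into a column-stochastic `S ∈ R^(k×N)`.
4. **Coarsening.** `X′ = S X`, `A′ = S A Sᵀ`.

The bundled classifier (APNN) stacks an embedding GCN layer, three GCN
layers with this pooling after the first and second, a max‖mean‖sum readout
collected at four stages, and a two-layer MLP — trained with Adam,
cross-entropy, dropout 0.5 and early stopping, evaluated by stratified
10-fold cross-validation.

## Worked example

```r
library(atompool)

# two-class planted dataset: 4-cliques (class 0) vs 5-stars (class 1)
res <- generate_two_class_dataset(synthetic_config(graphs_per_class = 20, seed = 7))
ds  <- res$dataset
ds
#> <graph_dataset> synthetic-two-class: 40 graphs, 2 classes, feature dim 5

# one pooling step on the first graph (a single 4-clique)
g  <- ds$graphs[[1]]
pl <- pool_layer(g$adjacency, g$features, pooling_config())
pl$factorization
#> <bmf_result> k=1 atoms, residual |.|_1 = 0
colSums(pl$assignment$matrix)   # column-stochastic: all exactly 1
#> [1] 1 1 1 1

# which atoms discriminate the classes?
atom_report(ds)
#> <atom_report> 25 distinct atoms (ego size 5)
#>  atom support activation_class0 activation_class1 n_edges
#>     1      19         0.9500000         0.0000000       6
#>     5      19         0.0000000         0.8887500       4
#>     2      13         0.5752083         0.0000000       7
#>     4      10         0.0000000         0.4633333       1
#>  ...

# cross-validated classification (small model for a quick demo)
cv <- cross_validate(ds,
                     model_config(hidden_dim = 32, mlp_hidden = 16),
                     train_config(max_epochs = 30, patience = 29, seed = 1,
                                  folds = 5, batch_size = 16),
                     pooling_config())
cv
#> <apnn_cv> test accuracy 1.000 +/- 0.000 over 5 folds
```

Reading the report: atom 1 has 6 edges on ≤5 nodes — the planted 4-clique —
and activates on 95% of nodes in class-0 graphs but never in class 1;
atom 5 is the 4-edge star with the mirror-image profile. That per-class
activation disparity is the package's interpretability statistic: the model
can say *which* substructures carried the decision.

A command-line front end lives at `inst/cli/atompool`
(`make-synthetic`, `extract-atoms`, `pool`, `train`, `report-atoms`).

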