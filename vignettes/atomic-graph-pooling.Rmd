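---
title: "Atomic graph pooling: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Atomic graph pooling: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(atompool)
```

## The problem

Graph classification — deciding, say, whether a molecule is mutagenic or a
protein belongs to a functional class — needs a fixed-length representation
of graphs of varying size. Hierarchical pooling builds one by repeatedly
coarsening the graph. Most pooling operators rank or cluster nodes using
learned scores, which discards local topology and leaves no account of *what*
substructure a super-node stands for. The operator implemented here takes the
opposite route: it first decomposes the graph into a small dictionary of
recurring structural patterns ("atoms" — think functional groups in molecules
or community motifs in social graphs) and then pools nodes onto those atoms.
Every super-node is an explicit subgraph pattern, so pooling decisions can be
traced back to structure.

## The model

For a graph with binary symmetric adjacency $A \in \{0,1\}^{N \times N}$
(zero diagonal) and features $X \in \mathbb{R}^{N \times d}$, one pooling
step runs four stages.

**1. Ego-network sampling.** For each node $v$, take $v$ plus its
$\min(\deg(v), S-1)$ highest-degree neighbors, the induced adjacency on these
members (center first), zero-padded to $S \times S$ and vectorized row-major.
Stacking the $N$ columns gives the sampling matrix
$Y \in \{0,1\}^{S^2 \times N}$.

**2. Boolean matrix factorization.** $Y \approx D \circ C$ over the Boolean
semiring, with dictionary $D \in \{0,1\}^{S^2 \times k}$ and sparse code
$C \in \{0,1\}^{k \times N}$ ($C_{i,t}=1$ when atom $i$ occurs in
ego-network $t$). Factorization is greedy coverage maximization: candidate
dictionary columns are the rows of the association matrix
$R_{ij} = \mathbb{1}[\langle y_i, y_j\rangle / \langle y_i, y_i\rangle \ge \phi]$
(the standard association-rule construction); each iteration picks the
candidate whose optimal usage row maximizes
$\omega \cdot (\text{newly covered 1s}) - (\text{newly overwritten 0s})$,
and stops at $k_{\max}$ atoms, at residual $\le \tau$, or when no candidate
scores positive. Because the score is separable over columns of $Y$, the
optimal usage row is computed exactly per column; the first greedy pick is
therefore optimal over all candidate (column, row) pairs, which the test
suite verifies by enumeration.

**3. Assignment.** With the affiliation matrix $M \in \{0,1\}^{N \times T}$
($M_{j,t}=1$ iff node $j$ is in ego-network $t$; $M_{t,t}=1$ always), the raw
assignment weight of node $j$ on atom $i$ is the normalized co-occurrence
$(C M^\top)_{ij} / |E(v_j)|$, where $|E(v_j)| = \sum_t M_{j,t}$. Each column
is then renormalized to sum to one, making $S \in \mathbb{R}^{k \times N}$
column-stochastic.

**4. Coarsening.** $X' = S X$ and $A' = S A S^\top$. Column-stochasticity
preserves total feature mass ($\mathbf{1}^\top X' = \mathbf{1}^\top X$).

The classification network (APNN) stacks an embedding GCN layer
($H = \mathrm{ReLU}(\hat{D}^{-1/2}(A+I)\hat{D}^{-1/2} X W)$), three further
GCN layers with atomic pooling after the first and second, a readout
(columnwise max ‖ mean ‖ sum) collected at several stages, and a two-layer
MLP classifier trained with Adam and early stopping.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `ego_size` (S) | max ego-network order | 5 | unreported in the source protocol; 5 captures the size of typical chemical functional groups while keeping $S^2 = 25$ patterns tractable |
| `confidence_threshold` ($\phi$) | association gate | 0.6 | standard mid-range confidence for association-rule BMF; 1.0 is appropriate for noiseless data |
| `coverage_weight` ($\omega$) | 1-coverage vs 0-overwrite trade-off | 1.0 | symmetric penalty |
| `error_tolerance` ($\tau$) | residual stop | 0 | factorize until no candidate helps |
| `pooling_ratio` | bound on $N'/N$ | 0.5 | benchmark protocol value; per layer $k_{\max} = \max(1, \lceil 0.5 N \rceil)$ |
| `hidden_dim` / `mlp_hidden` | widths | 128 / 64 | benchmark protocol |
| optimizer | Adam, lr 0.001, weight decay 5e-4, batch 64, dropout 0.5, patience 50, max 500 epochs, 10 folds | — | benchmark protocol |

## Design choices where the design was open

* **Neighbor ranking and ties.** "Highest-degree neighbors" is read as degree
  in the *full* graph; ties break by ascending node id. Some deterministic
  rule is mandatory because the vectorization — and hence which atoms are
  discoverable — depends on member order.
* **Association formula.** The factorization's "row correlation" is the
  asymmetric confidence $\langle y_i,y_j\rangle/\langle y_i,y_i\rangle$
  thresholded at $\phi$, the established construction for greedy Boolean
  factorization; only the inputs $\phi,\omega$ are named by the protocol, not
  the formula.
* **Residual semantics.** The residual update is interpreted as masking
  covered ones (saturating at zero), not signed subtraction: signed residuals
  would leave $\{0,1\}$. Coverage is computed only on unmasked cells.
* **Column renormalization of S.** The raw normalized co-occurrence is
  column-stochastic only when every ego-network activates exactly one atom.
  Since the code may activate several, an explicit per-column renormalization
  enforces the stated stochasticity; nodes with zero co-occurrence get the
  uniform $1/k$ column instead of being dropped (avoiding exactly the
  information loss the method is meant to prevent).
* **Between-layer binarization.** $A'$ is weighted; before the next
  ego-sampling round it is binarized at threshold 0 (any positive weight is
  an edge) with the diagonal zeroed, while the GCN layers and the coarsening
  product keep the weighted matrix. Atoms are recomputed at every pooling
  level on the current coarsened topology.
* **Readout stages.** The protocol feeds "the output of the embedding layer
  and the pooling layers" to the classifier. Read literally that leaves the
  third convolution disconnected from the loss — a dead, untrainable layer —
  while the same protocol mandates three trained GCN layers. This package
  therefore reads out four stages: embedding output, each pooled output, and
  the final convolution output (length $4 \times 3 \times$ `hidden_dim`).
* **Non-differentiable pooling.** Ego sampling + BMF + assignment are
  combinatorial; they are computed once per graph per level on the input
  topology, cached, and treated as constants during training. Gradients flow
  through $SX$ and $SAS^\top$ as fixed linear maps.
* **Early-stopping ties.** Validation-accuracy ties are broken by lower
  validation loss.
* **Identity fallback.** When factorization finds no atoms (e.g. an edgeless
  graph), the layer returns the graph unchanged with $S = I$; the
  pooling-ratio size contract deliberately does not apply to this fallback.

## What the synthetic generator emulates — and what it does not

`generate_two_class_dataset()` plants known motifs (default: 4-cliques for
class 0 vs 5-stars for class 1; a Poisson(3)-truncated-at-1 number of copies
per graph), joins copies with bridges, adds independent spurious edges with
probability 0.02, and one-hot encodes each node's role inside its motif.
This gives planted ground truth for atom recovery and class-discriminative
activation — the properties the acceptance suite checks.

It does **not** emulate real molecular statistics: degree distributions,
label alphabets, graph-size ranges and class overlap of benchmarks such as
NCI1 or D&D are far harsher. A green motif-recovery or learnability test
establishes that the machinery is correct and can exploit planted structure;
it does not establish benchmark-level accuracy. In particular, the role
features alone already separate the default classes — deliberate, since the
end-to-end criterion is a plumbing check, not a difficulty benchmark; the
structural signal is verified separately by the atom-recovery criterion and
by the shared-motif control, which removes both structural and feature
signal and must sit at chance level.

## Numerical notes

* Assignment columns sum to 1 within 1e-9 (checked); coarsened adjacency is
  numerically symmetrized as $(A' + A'^\top)/2$.
* All randomness (generator, initialization, batching, dropout, folds) flows
  from explicit integer seeds; evaluation disables dropout, so identical
  seeds give identical results bit for bit. R's global RNG is the stream;
  top-level entry points take a `seed` argument.
* Gradients of the hand-written backward pass match central finite
  differences to ~1e-8 relative error (tested).
* Degenerate inputs: all-zero sampling matrices yield an empty dictionary
  and the identity fallback; single-node graphs work throughout.

## Known limitations

* The greedy factorization is a heuristic: beyond the first pick it carries
  no optimality guarantee, and candidates are limited to association-matrix
  rows.
* Training is plain dense R linear algebra on one CPU — fine for the
  synthetic scale (hundreds of graphs of tens of nodes), not for
  thousand-graph benchmarks with hundreds of nodes.
* The GAT backbone is a registered-but-unimplemented seam (`model_config`
  rejects it); edge labels/attributes are unsupported.
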