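#' Node / ego-network affiliation matrix
#'
#' `M[j, t] = 1` iff node j is a member of the ego-network centered at node t.
#' Since every center belongs to its own ego-network, the diagonal is all
#' ones, so every node belongs to at least one ego-network.
#'
#' @param egos list of [sample_ego_network()] objects, one per node, in node
#'   order (as kept by [build_sampling_matrix()]).
#' @param N node count.
#' @return binary `N x T` matrix, T = N.
#' @export
build_affiliation_matrix <- function(egos, N) {
  if (inherits(egos, "sampling_matrix")) egos <- egos$egos
  M <- matrix(0, N, length(egos))
  for (t in seq_along(egos)) {
    members <- egos[[t]]$members
    if (any(members < 1 | members > N))
      stop("ego-network member id outside the graph (integrity error)")
    M[members, t] <- 1
  }
  M
}

#' Atom / node co-occurrence counts
#'
#' Entry (i, j) of `C %*% t(M)` counts the ego-networks that both contain node
#' j and activate atom i.
#'
#' @param C binary `k x T` sparse code.
#' @param M binary `N x T` affiliation matrix.
#' @return nonnegative integer `k x N` matrix.
#' @export
cooccurrence_counts <- function(C, M) {
  if (ncol(C) != ncol(M)) stop("C and M must have the same number of columns")
  C %*% t(M)
}

#' Build the column-stochastic pooling assignment matrix
#'
#' Raw weight of node j on atom i is the co-occurrence count divided by the
#' number of ego-networks containing j (`|E(v_j)|`). Because an ego-network
#' may activate several atoms, the raw columns need not sum to one, so each
#' column is explicitly renormalized; nodes whose raw weights are all zero
#' receive the uniform assignment `1/k` rather than being dropped.
#'
#' @param C binary `k x T` sparse code.
#' @param M binary `N x T` affiliation matrix with unit diagonal.
#' @return object of class `assignment_matrix` with `matrix` (column-stochastic
#'   `k x N`), `raw` (the unnormalized weights), `atom_count`.
#' @export
build_assignment_matrix <- function(C, M) {
  k <- nrow(C)
  if (k == 0) {
    stop(structure(class = c("atompool_no_atoms", "error", "condition"),
                   list(message = "factorization produced no atoms",
                        call = sys.call())))
  }
  counts <- cooccurrence_counts(C, M)
  ego_per_node <- rowSums(M)
  if (any(ego_per_node == 0)) stop("node belongs to no ego-network")
  raw <- sweep(counts, 2, ego_per_node, "/")
  S <- raw
  cs <- colSums(S)
  pos <- cs > 0
  S[, pos] <- sweep(S[, pos, drop = FALSE], 2, cs[pos], "/")
  S[, !pos] <- 1 / k
  structure(list(matrix = S, raw = raw, atom_count = k),
            class = "assignment_matrix")
}

#' Coarsen a graph through an assignment matrix
#'
#' Super-node features `X' = S X`; coarsened adjacency `A' = S A t(S)`
#' (numerically symmetrized). With the identity assignment the graph
#' round-trips exactly.
#'
#' @param adjacency `N x N` (possibly weighted) symmetric matrix.
#' @param features `N x d` matrix.
#' @param S `k x N` assignment matrix (an `assignment_matrix` or plain matrix).
#' @param atom_provenance optional `bmf_result` that defined the super-nodes.
#' @return object of class `coarsened_graph` with `features`, `adjacency`,
#'   `node_count`, `atom_provenance`.
#' @export
coarsen <- function(adjacency, features, S, atom_provenance = NULL) {
  if (inherits(S, "assignment_matrix")) S <- S$matrix
  if (ncol(S) != nrow(adjacency) || nrow(adjacency) != ncol(adjacency) ||
      nrow(features) != nrow(adjacency))
    stop("dimension mismatch between S, adjacency and features")
  Xp <- S %*% features
  Ap <- S %*% adjacency %*% t(S)
  Ap <- (Ap + t(Ap)) / 2
  structure(list(features = Xp, adjacency = Ap, node_count = nrow(S),
                 atom_provenance = atom_provenance),
            class = "coarsened_graph")
}

#' One full atomic pooling step
#'
#' Runs the pipeline end to end on an (optionally weighted) graph: binarize
#' the adjacency when it is not already binary (entries above
#' `binarize_threshold` become edges, diagonal zeroed), sample ego-networks,
#' factorize the sampling matrix with the atom budget
#' `k_max = min(max_atoms, max(1, ceiling(pooling_ratio * N)))`, build the
#' assignment matrix and coarsen. If the factorization yields no atoms (e.g.
#' an edgeless graph) the input is returned unchanged with an identity
#' assignment and `fallback = TRUE`.
#'
#' @param adjacency nonnegative symmetric `N x N` matrix.
#' @param features `N x d` matrix.
#' @param config a [pooling_config()].
#' @param verbose log the identity fallback when it happens.
#' @return list with `coarsened` ([coarsen()] result), `assignment`,
#'   `factorization`, `affiliation`, `sampling`, `fallback`.
#' @export
pool_layer <- function(adjacency, features, config,
                       verbose = getOption("atompool.verbose", FALSE)) {
  if (any(adjacency < 0)) stop("adjacency must be nonnegative")
  n <- nrow(adjacency)
  B <- adjacency
  if (any(B != 0 & B != 1)) B <- 1 * (B > config$binarize_threshold)
  diag(B) <- 0
  g <- new_graph(B, features, validate = FALSE)
  sm <- build_sampling_matrix(g, config$ego_size)
  k_max <- min(config$max_atoms, max(1L, ceiling(config$pooling_ratio * n)))
  cfg <- config
  cfg$max_atoms <- k_max
  fact <- factorize_boolean(sm, cfg)
  if (fact$atom_count == 0) {
    if (verbose) message("pool_layer: no atoms found, identity fallback")
    S <- structure(list(matrix = diag(n), raw = diag(n), atom_count = n),
                   class = "assignment_matrix")
    cg <- structure(list(features = features, adjacency = adjacency,
                         node_count = n, atom_provenance = fact),
                    class = "coarsened_graph")
    return(list(coarsened = cg, assignment = S, factorization = fact,
                affiliation = build_affiliation_matrix(sm, n), sampling = sm,
                fallback = TRUE))
  }
  M <- build_affiliation_matrix(sm, n)
  S <- build_assignment_matrix(fact$code, M)
  cg <- coarsen(adjacency, features, S, atom_provenance = fact)
  list(coarsened = cg, assignment = S, factorization = fact,
       affiliation = M, sampling = sm, fallback = FALSE)
}

#' Jaccard similarity between two binary patterns
#'
#' @param a,b binary vectors of equal length.
#' @return `|a & b| / |a | b|` (1 when both are empty).
#' @export
jaccard_binary <- function(a, b) {
  a <- a > 0; b <- b > 0
  un <- sum(a | b)
  if (un == 0) return(1)
  sum(a & b) / un
}

#' Vectorize a motif adjacency on the atom grid
#'
#' Pads a small motif adjacency to `ego_size x ego_size` and vectorizes it
#' row-major, producing the pattern a perfectly recovered atom would equal.
#'
#' @param motif_adjacency binary symmetric matrix of order `<= ego_size`.
#' @param ego_size ego-network order of the dictionary.
#' @return binary vector of length `ego_size^2`.
#' @export
motif_atom_vector <- function(motif_adjacency, ego_size) {
  s <- nrow(motif_adjacency)
  if (s > ego_size) stop("motif larger than ego_size")
  pad <- matrix(0, ego_size, ego_size)
  pad[seq_len(s), seq_len(s)] <- motif_adjacency
  as.vector(t(pad))
}
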