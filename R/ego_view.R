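#' Pooling hyper-parameter bundle
#'
#' Collects every knob of the atomic pooling pipeline. `ego_size` is the
#' maximum ego-network order (center + highest-degree neighbors); the
#' vectorized ego-networks have length `ego_size^2`. `confidence_threshold`
#' (phi) gates the row-association candidates of the Boolean factorization,
#' `coverage_weight` (omega) trades covered ones against overwritten zeros,
#' `max_atoms` caps the dictionary size, `error_tolerance` (tau) stops the
#' greedy loop once the uncovered-ones count falls to or below it.
#' `pooling_ratio` bounds the coarsened node count as a fraction of the input
#' node count; `binarize_threshold` binarizes weighted adjacencies between
#' pooling levels.
#'
#' @param ego_size integer >= 2. The experiments' value is not published;
#'   default 5.
#' @param confidence_threshold numeric in (0, 1].
#' @param coverage_weight positive numeric.
#' @param max_atoms integer >= 1; default `ego_size^2` (never binding, since
#'   at most `ego_size^2` distinct candidates exist).
#' @param error_tolerance numeric >= 0.
#' @param pooling_ratio numeric in (0, 1].
#' @param binarize_threshold numeric >= 0.
#' @return object of class `pooling_config`.
#' @export
pooling_config <- function(ego_size = 5, confidence_threshold = 0.6,
                           coverage_weight = 1.0, max_atoms = NULL,
                           error_tolerance = 0, pooling_ratio = 0.5,
                           binarize_threshold = 0) {
  if (ego_size < 2) stop("ego_size must be >= 2")
  if (confidence_threshold <= 0 || confidence_threshold > 1)
    stop("confidence_threshold must lie in (0, 1]")
  if (coverage_weight <= 0) stop("coverage_weight must be > 0")
  if (is.null(max_atoms)) max_atoms <- ego_size^2
  if (max_atoms < 1) stop("max_atoms must be >= 1")
  if (error_tolerance < 0) stop("error_tolerance must be >= 0")
  if (pooling_ratio <= 0 || pooling_ratio > 1)
    stop("pooling_ratio must lie in (0, 1]")
  structure(list(ego_size = as.integer(ego_size),
                 confidence_threshold = confidence_threshold,
                 coverage_weight = coverage_weight,
                 max_atoms = as.integer(max_atoms),
                 error_tolerance = error_tolerance,
                 pooling_ratio = pooling_ratio,
                 binarize_threshold = binarize_threshold),
            class = "pooling_config")
}

#' Sample a degree-capped ego-network
#'
#' Members are the center plus its `min(deg(center), ego_size - 1)`
#' highest-degree neighbors; "degree" is the degree in the full graph, and
#' ties are broken by ascending node id so the sampling is deterministic.
#' The local adjacency is the induced subgraph in member order (center first),
#' zero-padded to `ego_size x ego_size`.
#'
#' @param graph an [new_graph()] object (binary adjacency).
#' @param center node id (1-based).
#' @param ego_size maximum ego-network order.
#' @return object of class `ego_network` with `center`, `members`,
#'   `local_adjacency`, `ego_size`.
#' @export
sample_ego_network <- function(graph, center, ego_size) {
  A <- graph$adjacency
  n <- nrow(A)
  if (length(center) != 1 || is.na(center) || center < 1 || center > n)
    stop("invalid center node id")
  deg <- rowSums(A)
  nbrs <- which(A[center, ] > 0)
  if (length(nbrs) > 0) {
    nbrs <- nbrs[order(-deg[nbrs], nbrs)]
    nbrs <- nbrs[seq_len(min(length(nbrs), ego_size - 1L))]
  }
  members <- c(center, nbrs)
  local <- matrix(0, ego_size, ego_size)
  k <- length(members)
  local[seq_len(k), seq_len(k)] <- A[members, members, drop = FALSE]
  structure(list(center = center, members = members,
                 local_adjacency = local, ego_size = as.integer(ego_size)),
            class = "ego_network")
}

#' Row-major vectorization of an ego-network adjacency
#'
#' @param ego an [sample_ego_network()] result.
#' @return binary vector of length `ego_size^2`; invertible via
#'   [reshape_atom()].
#' @export
vectorize_ego <- function(ego) as.vector(t(ego$local_adjacency))

#' Reshape a vectorized pattern back to an `ego_size x ego_size` matrix
#'
#' Inverse of [vectorize_ego()]. With `symmetrize = TRUE` the pattern is
#' symmetrized (elementwise max with its transpose) and the diagonal zeroed,
#' which is how dictionary atoms are rendered as subgraphs.
#'
#' @param v binary vector of length `ego_size^2`.
#' @param ego_size ego-network order.
#' @param symmetrize clean the pattern up into a valid adjacency.
#' @return `ego_size x ego_size` matrix.
#' @export
reshape_atom <- function(v, ego_size, symmetrize = FALSE) {
  if (length(v) != ego_size^2) stop("length(v) must equal ego_size^2")
  m <- matrix(v, ego_size, ego_size, byrow = TRUE)
  if (symmetrize) {
    m <- pmax(m, t(m))
    diag(m) <- 0
  }
  m
}

#' Build the sampling matrix Y of a graph
#'
#' Column `t` is the row-major vectorization of the ego-network centered at
#' node `t`; there is one column per node (T = N).
#'
#' @param graph an [new_graph()] object.
#' @param ego_size maximum ego-network order.
#' @return object of class `sampling_matrix` with `matrix`
#'   (`ego_size^2 x N` binary), `column_centers`, `egos` (the list of
#'   ego-networks, kept for the affiliation matrix), `ego_size`.
#' @export
build_sampling_matrix <- function(graph, ego_size) {
  n <- graph$node_count
  egos <- lapply(seq_len(n), function(t) sample_ego_network(graph, t, ego_size))
  Y <- vapply(egos, vectorize_ego, numeric(ego_size^2))
  Y <- matrix(Y, nrow = ego_size^2, ncol = n)
  structure(list(matrix = Y, column_centers = seq_len(n), egos = egos,
                 ego_size = as.integer(ego_size)),
            class = "sampling_matrix")
}
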