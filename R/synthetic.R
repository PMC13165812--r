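#' Define a motif (a small planted subgraph pattern)
#'
#' @param name motif name.
#' @param adjacency binary symmetric zero-diagonal matrix; must be connected.
#' @return object of class `motif_spec`.
#' @export
motif_spec <- function(name, adjacency) {
  adjacency <- as.matrix(adjacency)
  s <- nrow(adjacency)
  if (any(adjacency != t(adjacency)) || any(diag(adjacency) != 0) ||
      any(!adjacency %in% c(0, 1)))
    stop("motif adjacency must be binary, symmetric with zero diagonal")
  # connectivity via reachability from node 1
  reach <- rep(FALSE, s); reach[1] <- TRUE
  for (i in seq_len(s)) reach <- reach | (adjacency %*% reach > 0)
  if (!all(reach)) stop("motif must be connected")
  structure(list(name = name, adjacency = adjacency, size = s),
            class = "motif_spec")
}

#' Built-in motif library
#'
#' Four small patterns echoing the atom morphologies that recur in protein and
#' social graphs: a dense near-clique, a hub-centered star, a chain, and a
#' sparse bipartite block.
#'
#' @return named list of [motif_spec()] objects: `clique4` (4-clique), `star5`
#'   (hub + 4 leaves, hub first), `chain4` (path on 4 nodes), `bipartite22`
#'   (complete 2x2 bipartite block).
#' @export
motif_library <- function() {
  clique4 <- matrix(1, 4, 4); diag(clique4) <- 0
  star5 <- matrix(0, 5, 5); star5[1, 2:5] <- 1; star5[2:5, 1] <- 1
  chain4 <- matrix(0, 4, 4)
  chain4[cbind(1:3, 2:4)] <- 1; chain4[cbind(2:4, 1:3)] <- 1
  bi <- matrix(0, 4, 4); bi[1:2, 3:4] <- 1; bi[3:4, 1:2] <- 1
  list(clique4 = motif_spec("clique4", clique4),
       star5 = motif_spec("star5", star5),
       chain4 = motif_spec("chain4", chain4),
       bipartite22 = motif_spec("bipartite22", bi))
}

#' Plant motif copies into one graph
#'
#' Instantiates disjoint copies of the given motifs, joins them with
#' `bridge_edges` random inter-copy edges, and adds independent noise edges on
#' the remaining non-adjacent pairs with probability `noise_edge_prob` (noise
#' only ever adds edges; planted edges are never removed). Node features are
#' the one-hot encoding of the node's role (its index inside its motif copy)
#' over a `role_dim`-letter alphabet. Randomness is drawn from the session RNG
#' stream; seed it at the call site for reproducibility.
#'
#' @param motifs list of [motif_spec()] objects.
#' @param copies integer vector, copies per motif (recycled to
#'   `length(motifs)`).
#' @param bridge_edges number of random inter-copy edges (silently capped at
#'   the number of available pairs; 0 when there is a single copy).
#' @param noise_edge_prob probability of each spurious extra edge.
#' @param role_dim feature alphabet size; must be >= the largest motif.
#' @return list with `graph` (an [new_graph()], unlabeled) and `membership`
#'   (data.frame node / motif / copy / role).
#' @export
plant_motif_graph <- function(motifs, copies = 1, bridge_edges = 0,
                              noise_edge_prob = 0, role_dim = NULL) {
  if (length(motifs) == 0) stop("at least one motif is required")
  if (inherits(motifs, "motif_spec")) motifs <- list(motifs)
  copies <- rep_len(as.integer(copies), length(motifs))
  if (any(copies < 1)) stop("copies must be >= 1")
  sizes <- vapply(motifs, function(m) m$size, integer(1))
  if (is.null(role_dim)) role_dim <- max(sizes)
  if (role_dim < max(sizes)) stop("role_dim smaller than largest motif")

  blocks <- list(); motif_of <- character(0); copy_of <- integer(0)
  role <- integer(0); copy_id <- 0L
  for (i in seq_along(motifs)) {
    for (cp in seq_len(copies[i])) {
      copy_id <- copy_id + 1L
      blocks[[copy_id]] <- motifs[[i]]$adjacency
      motif_of <- c(motif_of, rep(motifs[[i]]$name, sizes[i]))
      copy_of <- c(copy_of, rep(copy_id, sizes[i]))
      role <- c(role, seq_len(sizes[i]) - 1L)
    }
  }
  n <- length(role)
  A <- matrix(0, n, n)
  at <- 0
  for (b in blocks) {
    idx <- at + seq_len(nrow(b))
    A[idx, idx] <- b
    at <- at + nrow(b)
  }
  # bridges between distinct copies
  if (bridge_edges > 0 && copy_id > 1) {
    pairs <- which(upper.tri(A) & outer(copy_of, copy_of, "!=") & A == 0,
                   arr.ind = TRUE)
    take <- min(bridge_edges, nrow(pairs))
    pick <- pairs[sample.int(nrow(pairs), take), , drop = FALSE]
    A[pick] <- 1
    A[pick[, 2:1, drop = FALSE]] <- 1
  }
  # independent noise edges on the remaining non-edges
  if (noise_edge_prob > 0) {
    free <- which(upper.tri(A) & A == 0, arr.ind = TRUE)
    if (nrow(free) > 0) {
      hit <- stats::runif(nrow(free)) < noise_edge_prob
      add <- free[hit, , drop = FALSE]
      A[add] <- 1
      A[add[, 2:1, drop = FALSE]] <- 1
    }
  }
  g <- new_graph(A, one_hot_features(role, role_dim))
  list(graph = g,
       membership = data.frame(node = seq_len(n), motif = motif_of,
                               copy = copy_of, role = role))
}

#' Configuration for a two-class planted-motif dataset
#'
#' The stated world of the synthetic benchmark: each class is dominated by its
#' own motif, the number of motif copies per graph is Poisson around
#' `copies_mean` (truncated at 1), copies are tied together with
#' `copies - 1` bridges (plus `extra_bridges`), and both classes share the
#' same noise statistics.
#'
#' @param class0,class1 [motif_spec()] for each class (defaults: 4-clique vs
#'   5-star).
#' @param graphs_per_class graphs per class (default 100, i.e. a 200-graph
#'   dataset).
#' @param copies_mean mean motif copies per graph (default 3).
#' @param noise_edge_prob spurious edge probability (default 0.02).
#' @param extra_bridges bridges beyond the `copies - 1` connecting ones.
#' @param seed integer seed; all randomness of the generator flows from it.
#' @return object of class `synthetic_config`.
#' @export
synthetic_config <- function(class0 = motif_library()$clique4,
                             class1 = motif_library()$star5,
                             graphs_per_class = 100, copies_mean = 3,
                             noise_edge_prob = 0.02, extra_bridges = 0,
                             seed = 1) {
  if (noise_edge_prob < 0 || noise_edge_prob >= 1)
    stop("noise_edge_prob must lie in [0, 1)")
  structure(list(class0 = class0, class1 = class1,
                 graphs_per_class = as.integer(graphs_per_class),
                 copies_mean = copies_mean,
                 noise_edge_prob = noise_edge_prob,
                 extra_bridges = as.integer(extra_bridges),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a two-class motif-planted dataset with ground truth
#'
#' @param config a [synthetic_config()].
#' @return list with `dataset` (a shuffled, balanced [graph_dataset()]) and
#'   `ground_truth` (per-graph membership maps plus the class motifs).
#' @export
generate_two_class_dataset <- function(config) {
  set.seed(config$seed)
  specs <- list(config$class0, config$class1)
  role_dim <- max(vapply(motif_library(), function(m) m$size, integer(1)),
                  config$class0$size, config$class1$size)
  graphs <- list(); memberships <- list(); labels <- integer(0)
  for (cls in 0:1) {
    for (i in seq_len(config$graphs_per_class)) {
      copies <- max(1L, stats::rpois(1, config$copies_mean))
      res <- plant_motif_graph(specs[[cls + 1]], copies = copies,
                               bridge_edges = copies - 1 + config$extra_bridges,
                               noise_edge_prob = config$noise_edge_prob,
                               role_dim = role_dim)
      g <- res$graph
      g$label <- cls
      graphs[[length(graphs) + 1]] <- g
      memberships[[length(memberships) + 1]] <- res$membership
      labels <- c(labels, cls)
    }
  }
  ord <- sample.int(length(graphs))
  graphs <- graphs[ord]
  memberships <- memberships[ord]
  for (i in seq_along(graphs)) graphs[[i]]$graph_id <- i
  list(dataset = graph_dataset(graphs, name = "synthetic-two-class"),
       ground_truth = list(memberships = memberships,
                           class_motifs = specs,
                           order = ord, config = config))
}
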