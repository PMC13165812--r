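#' Construct a labeled graph
#'
#' The basic data object used throughout the package: an undirected graph with
#' a binary, symmetric, zero-diagonal adjacency matrix, an `N x d` node feature
#' matrix and an optional graph-level class label.
#'
#' @param adjacency binary symmetric `N x N` matrix with zero diagonal.
#' @param features `N x d` numeric matrix; defaults to an `N x 1` all-ones
#'   matrix when no node information is available.
#' @param label integer class index (0-based) or `NA`.
#' @param graph_id opaque identifier (kept as-is).
#' @param validate set to `FALSE` to skip invariant checks (internal fast path).
#' @return an object of class `atom_graph` with fields `adjacency`, `features`,
#'   `label`, `graph_id`, `node_count`.
#' @export
new_graph <- function(adjacency, features = NULL, label = NA_integer_,
                      graph_id = NULL, validate = TRUE) {
  adjacency <- as.matrix(adjacency)
  n <- nrow(adjacency)
  if (is.null(features)) features <- matrix(1, n, 1)
  features <- as.matrix(features)
  if (validate) {
    if (ncol(adjacency) != n) stop("adjacency must be square")
    if (any(adjacency != 0 & adjacency != 1)) stop("adjacency must be binary")
    if (any(adjacency != t(adjacency))) stop("adjacency must be symmetric")
    if (any(diag(adjacency) != 0)) stop("adjacency must have zero diagonal")
    if (nrow(features) != n) stop("features must have one row per node")
    if (ncol(features) < 1) stop("feature dimension must be >= 1")
  }
  structure(
    list(adjacency = adjacency, features = features,
         label = as.integer(label), graph_id = graph_id, node_count = n),
    class = "atom_graph"
  )
}

#' @export
print.atom_graph <- function(x, ...) {
  cat(sprintf("<atom_graph> %d nodes, %d edges, d=%d, label=%s\n",
              x$node_count, sum(x$adjacency) / 2, ncol(x$features),
              ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

#' Bundle graphs into a dataset
#'
#' All graphs must share a feature dimension; labels must be contiguous
#' 0-based class indices (`NA` labels are rejected).
#'
#' @param graphs list of [new_graph()] objects.
#' @param name optional dataset name.
#' @return object of class `graph_dataset` with `graphs`, `class_count`,
#'   `feature_dim`, `name`.
#' @export
graph_dataset <- function(graphs, name = NULL) {
  if (length(graphs) == 0) stop("empty dataset")
  d <- unique(vapply(graphs, function(g) ncol(g$features), integer(1)))
  if (length(d) != 1) stop("all graphs must share the same feature dimension")
  labels <- vapply(graphs, function(g) g$label, integer(1))
  if (anyNA(labels)) stop("all graphs must carry a class label")
  k <- length(unique(labels))
  if (any(labels < 0) || any(labels >= k))
    stop("labels must be contiguous 0-based class indices")
  structure(list(graphs = graphs, class_count = k, feature_dim = d,
                 name = name),
            class = "graph_dataset")
}

#' @export
print.graph_dataset <- function(x, ...) {
  cat(sprintf("<graph_dataset> %s: %d graphs, %d classes, feature dim %d\n",
              ifelse(is.null(x$name), "(unnamed)", x$name),
              length(x$graphs), x$class_count, x$feature_dim))
  invisible(x)
}

#' @export
length.graph_dataset <- function(x) length(x$graphs)

#' One-hot encode discrete node labels
#'
#' @param node_labels integer vector with values in `[0, alphabet_size)`.
#' @param alphabet_size number of distinct label values.
#' @return binary `length(node_labels) x alphabet_size` matrix with exactly one
#'   1 per row.
#' @export
one_hot_features <- function(node_labels, alphabet_size) {
  node_labels <- as.integer(node_labels)
  if (length(node_labels) > 0 &&
      (min(node_labels) < 0 || max(node_labels) >= alphabet_size))
    stop("node label out of range [0, alphabet_size)")
  out <- matrix(0, length(node_labels), alphabet_size)
  if (length(node_labels) > 0)
    out[cbind(seq_along(node_labels), node_labels + 1L)] <- 1
  out
}

tu_path <- function(directory, name, suffix)
  file.path(directory, paste0(name, "_", suffix, ".txt"))

read_int_column <- function(path) as.integer(scan(path, quiet = TRUE))

#' Read a TU-format flat-file graph dataset
#'
#' Expects the standard benchmark layout: `<name>_A.txt` (comma-separated
#' 1-based edge pairs, each undirected edge usually listed in both
#' orientations), `<name>_graph_indicator.txt` (graph id per node),
#' `<name>_graph_labels.txt`, and optionally `<name>_node_labels.txt` and/or
#' `<name>_node_attributes.txt`.
#'
#' Node labels are one-hot encoded over the dataset-wide alphabet; when
#' attributes are also present they are appended after the one-hot block; with
#' neither file the features fall back to an `N x 1` all-ones matrix. Graph
#' labels are remapped to contiguous 0-based indices. Self-loops and repeated
#' ordered edge pairs are dropped with a warning; an edge joining two different
#' graphs raises an error.
#'
#' @param directory dataset directory.
#' @param name file name prefix.
#' @param verbose log a manifest line on load.
#' @return a [graph_dataset()].
#' @export
read_tu_dataset <- function(directory, name, verbose = FALSE) {
  need <- c("A", "graph_indicator", "graph_labels")
  for (s in need) {
    if (!file.exists(tu_path(directory, name, s)))
      stop(sprintf("missing mandatory TU file: %s", tu_path(directory, name, s)))
  }
  edges <- utils::read.csv(tu_path(directory, name, "A"), header = FALSE,
                           strip.white = TRUE)
  edges <- as.matrix(edges)
  if (ncol(edges) != 2) stop("edge file must have two columns")
  indicator <- read_int_column(tu_path(directory, name, "graph_indicator"))
  glabels_raw <- read_int_column(tu_path(directory, name, "graph_labels"))
  n_nodes <- length(indicator)
  n_graphs <- length(glabels_raw)

  self_loops <- edges[, 1] == edges[, 2]
  if (any(self_loops)) {
    warning(sprintf("dropped %d self-loop edge(s)", sum(self_loops)))
    edges <- edges[!self_loops, , drop = FALSE]
  }
  dup <- duplicated(edges)
  if (any(dup)) {
    warning(sprintf("dropped %d duplicate edge pair(s)", sum(dup)))
    edges <- edges[!dup, , drop = FALSE]
  }
  if (nrow(edges) > 0) {
    if (min(edges) < 1 || max(edges) > n_nodes)
      stop("edge references a node id outside the dataset")
    if (any(indicator[edges[, 1]] != indicator[edges[, 2]]))
      stop("edge joins nodes of two different graphs (integrity error)")
  }

  # node features over the whole dataset, then sliced per graph
  feat <- NULL
  nl_path <- tu_path(directory, name, "node_labels")
  na_path <- tu_path(directory, name, "node_attributes")
  if (file.exists(nl_path)) {
    nl <- read_int_column(nl_path)
    if (length(nl) != n_nodes) stop("node_labels length mismatch")
    alphabet <- sort(unique(nl))
    feat <- one_hot_features(match(nl, alphabet) - 1L, length(alphabet))
  }
  if (file.exists(na_path)) {
    at <- as.matrix(utils::read.csv(na_path, header = FALSE, strip.white = TRUE))
    if (nrow(at) != n_nodes) stop("node_attributes length mismatch")
    feat <- if (is.null(feat)) at else cbind(feat, at)
  }
  if (is.null(feat)) feat <- matrix(1, n_nodes, 1)

  classes <- sort(unique(glabels_raw))
  glabels <- match(glabels_raw, classes) - 1L

  graphs <- vector("list", n_graphs)
  node_of <- split(seq_len(n_nodes), indicator)
  edge_graph <- if (nrow(edges) > 0) indicator[edges[, 1]] else integer(0)
  edge_of <- split(seq_len(nrow(edges)), factor(edge_graph, levels = seq_len(n_graphs)))
  for (g in seq_len(n_graphs)) {
    nodes <- node_of[[as.character(g)]]
    if (is.null(nodes)) stop(sprintf("graph %d has no nodes", g))
    n <- length(nodes)
    local <- integer(n_nodes)
    local[nodes] <- seq_len(n)
    A <- matrix(0, n, n)
    ei <- edge_of[[g]]
    if (length(ei) > 0) {
      u <- local[edges[ei, 1]]
      v <- local[edges[ei, 2]]
      A[cbind(u, v)] <- 1
      A[cbind(v, u)] <- 1
    }
    graphs[[g]] <- new_graph(A, feat[nodes, , drop = FALSE],
                             label = glabels[g], graph_id = g)
  }
  ds <- graph_dataset(graphs, name = name)
  if (verbose)
    message(sprintf("loaded %s: %d graphs, %d classes, feature dim %d",
                    name, n_graphs, ds$class_count, ds$feature_dim))
  ds
}

#' Write a dataset in TU flat-file format
#'
#' Inverse of [read_tu_dataset()]; each undirected edge is written in both
#' orientations as in the public benchmark files. When every graph's feature
#' matrix is one-hot, a `_node_labels.txt` file is emitted; otherwise features
#' go to `_node_attributes.txt`.
#'
#' @param dataset a [graph_dataset()].
#' @param directory output directory (created if absent).
#' @param name file name prefix.
#' @return `directory`, invisibly.
#' @export
write_tu_dataset <- function(dataset, directory, name) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  offsets <- cumsum(c(0, vapply(dataset$graphs, function(g) g$node_count,
                                integer(1))))
  edge_rows <- list()
  indicator <- integer(0)
  feats <- list()
  for (i in seq_along(dataset$graphs)) {
    g <- dataset$graphs[[i]]
    idx <- which(g$adjacency > 0, arr.ind = TRUE)  # both orientations
    if (nrow(idx) > 0) edge_rows[[length(edge_rows) + 1]] <- idx + offsets[i]
    indicator <- c(indicator, rep(i, g$node_count))
    feats[[i]] <- g$features
  }
  edges <- do.call(rbind, edge_rows)
  utils::write.table(edges, tu_path(directory, name, "A"), sep = ", ",
              row.names = FALSE, col.names = FALSE)
  writeLines(as.character(indicator),
             tu_path(directory, name, "graph_indicator"))
  writeLines(as.character(vapply(dataset$graphs, function(g) g$label,
                                 integer(1))),
             tu_path(directory, name, "graph_labels"))
  X <- do.call(rbind, feats)
  is_onehot <- all(X %in% c(0, 1)) && all(rowSums(X) == 1)
  if (is_onehot) {
    writeLines(as.character(max.col(X) - 1L),
               tu_path(directory, name, "node_labels"))
  } else {
    utils::write.table(X, tu_path(directory, name, "node_attributes"), sep = ", ",
                row.names = FALSE, col.names = FALSE)
  }
  invisible(directory)
}
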