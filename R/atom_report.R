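#' Per-class atom activation report
#'
#' The interpretability statistic of atomic pooling: for every distinct
#' first-layer atom found across the dataset (atoms are identified by their
#' exact dictionary-column bit pattern), compute per class the mean over
#' graphs of the fraction of nodes with positive assignment to that atom
#' (graphs whose dictionary lacks the atom contribute 0). Atoms whose
#' activation differs strongly between classes mark class-discriminative
#' substructures.
#'
#' @param dataset a [graph_dataset()].
#' @param pconfig a [pooling_config()].
#' @param pools optional precomputed list of [pool_layer()] results (one per
#'   graph, first level); computed from the raw graphs when missing.
#' @return object of class `atom_report`: `table` (data.frame with one row per
#'   atom: id, support, edge count, one `activation_class<c>` column per
#'   class), `atoms` (list with the symmetrized `ego_size x ego_size`
#'   adjacency and edge list of each atom), `ego_size`.
#' @export
atom_report <- function(dataset, pconfig = pooling_config(), pools = NULL) {
  if (is.null(pools))
    pools <- lapply(dataset$graphs, function(g)
      pool_layer(g$adjacency, g$features, pconfig))
  labels <- vapply(dataset$graphs, function(g) g$label, integer(1))
  classes <- sort(unique(labels))
  keys <- character(0)
  columns <- list()
  act <- list()   # per graph: named numeric vector key -> activation fraction
  for (i in seq_along(pools)) {
    pl <- pools[[i]]
    fr <- numeric(0)
    if (!pl$fallback && pl$factorization$atom_count > 0) {
      D <- pl$factorization$dictionary
      Smat <- pl$assignment$matrix
      for (a in seq_len(ncol(D))) {
        key <- paste(D[, a], collapse = "")
        if (!key %in% keys) {
          keys <- c(keys, key)
          columns[[key]] <- D[, a]
        }
        fr[key] <- max(fr[key], mean(Smat[a, ] > 0), na.rm = TRUE)
      }
    }
    act[[i]] <- fr
  }
  if (length(keys) == 0)
    return(structure(list(table = data.frame(), atoms = list(),
                          ego_size = pconfig$ego_size),
                     class = "atom_report"))
  mat <- matrix(0, length(act), length(keys), dimnames = list(NULL, keys))
  for (i in seq_along(act))
    if (length(act[[i]]) > 0) mat[i, names(act[[i]])] <- act[[i]]
  tab <- data.frame(atom = seq_along(keys), support = colSums(mat > 0))
  for (cl in classes)
    tab[[paste0("activation_class", cl)]] <- colMeans(mat[labels == cl, ,
                                                          drop = FALSE])
  atoms <- lapply(keys, function(k) {
    adj <- reshape_atom(columns[[k]], pconfig$ego_size, symmetrize = TRUE)
    e <- which(upper.tri(adj) & adj > 0, arr.ind = TRUE)
    list(pattern = columns[[k]], adjacency = adj,
         edges = data.frame(from = e[, 1], to = e[, 2]))
  })
  tab$n_edges <- vapply(atoms, function(a) nrow(a$edges), integer(1))
  ord <- order(-tab$support)
  structure(list(table = tab[ord, , drop = FALSE], atoms = atoms[ord],
                 ego_size = pconfig$ego_size),
            class = "atom_report")
}

#' @export
print.atom_report <- function(x, n = 10, ...) {
  cat(sprintf("<atom_report> %d distinct atoms (ego size %d)\n",
              nrow(x$table), x$ego_size))
  print(utils::head(x$table, n), row.names = FALSE)
  invisible(x)
}
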