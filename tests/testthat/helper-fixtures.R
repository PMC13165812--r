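# fixtures are built in code at test time; nothing is stored on disk

# Erdos-Renyi-style random binary graph (uses the session RNG)
random_binary_graph <- function(n, p) {
  A <- matrix(0, n, n)
  up <- which(upper.tri(A))
  A[up[stats::runif(length(up)) < p]] <- 1
  A <- pmax(A, t(A))
  new_graph(A)
}

random_binary_matrix <- function(m, n, p = 0.5) {
  matrix(as.numeric(stats::runif(m * n) < p), m, n)
}

# write a two-triangle TU fixture; non-contiguous graph labels (5, 7) and a
# node-label file by default
write_two_triangle_fixture <- function(dir, name = "TT", node_labels = TRUE) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  edges <- rbind(c(1, 2), c(2, 1), c(1, 3), c(3, 1), c(2, 3), c(3, 2),
                 c(4, 5), c(5, 4), c(4, 6), c(6, 4), c(5, 6), c(6, 5))
  write.table(edges, file.path(dir, paste0(name, "_A.txt")), sep = ", ",
              row.names = FALSE, col.names = FALSE)
  writeLines(as.character(c(1, 1, 1, 2, 2, 2)),
             file.path(dir, paste0(name, "_graph_indicator.txt")))
  writeLines(as.character(c(5, 7)),
             file.path(dir, paste0(name, "_graph_labels.txt")))
  if (node_labels)
    writeLines(as.character(c(0, 1, 2, 0, 1, 2)),
               file.path(dir, paste0(name, "_node_labels.txt")))
  invisible(dir)
}

# brute-force ego-network oracle: neighbors sorted by (degree desc, id asc)
ego_oracle_members <- function(A, center, ego_size) {
  deg <- rowSums(A)
  nbrs <- which(A[center, ] > 0)
  if (length(nbrs) > 0) {
    ord <- order(-deg[nbrs], nbrs)
    nbrs <- nbrs[ord][seq_len(min(length(nbrs), ego_size - 1))]
  }
  c(center, nbrs)
}

# all binary vectors of length n (columns), for enumeration oracles
all_binary_vectors <- function(n) {
  stopifnot(n <= 12)
  m <- matrix(0, n, 2^n)
  for (i in seq_len(2^n))
    m[, i] <- as.integer(intToBits(i - 1)[seq_len(n)])
  m
}

path_graph <- function(n) {
  A <- matrix(0, n, n)
  if (n > 1) {
    A[cbind(seq_len(n - 1), 2:n)] <- 1
    A[cbind(2:n, seq_len(n - 1))] <- 1
  }
  new_graph(A)
}

triangle_graph <- function() {
  A <- matrix(1, 3, 3); diag(A) <- 0
  new_graph(A)
}
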