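#' Boolean matrix product
#'
#' Product over the Boolean semiring: entry (i, t) is the OR over a of
#' `D[i, a] AND C[a, t]`. Equals the thresholded integer product
#' `min(D %*% C, 1)`.
#'
#' @param D binary `m x k` matrix.
#' @param C binary `k x T` matrix.
#' @return binary `m x T` matrix.
#' @export
boolean_product <- function(D, C) {
  D <- as.matrix(D); C <- as.matrix(C)
  if (ncol(D) != nrow(C)) stop("inner dimensions do not agree")
  if (ncol(D) == 0) return(matrix(0, nrow(D), ncol(C)))
  1 * ((D %*% C) > 0)
}

#' Row association (confidence) matrix
#'
#' `R[i, j] = 1` iff `<y_i, y_j> / <y_i, y_i> >= phi`, the confidence that a 1
#' in row i implies a 1 in row j across the columns of Y. All-zero rows of Y
#' yield all-zero rows of R; every nonzero row has `R[i, i] = 1`. The rows of
#' R are the candidate dictionary columns of the greedy factorization (the
#' association-rule construction).
#'
#' @param Y binary `m x T` matrix (or a `sampling_matrix`).
#' @param phi confidence threshold in (0, 1].
#' @return binary `m x m` matrix.
#' @export
row_association_matrix <- function(Y, phi) {
  if (inherits(Y, "sampling_matrix")) Y <- Y$matrix
  if (phi <= 0 || phi > 1) stop("phi must lie in (0, 1]")
  ip <- tcrossprod(Y)               # m x m inner products
  self <- diag(ip)
  R <- 1 * (sweep(ip, 1, pmax(self, 1), "/") >= phi)
  R[self == 0, ] <- 0
  R
}

#' Coverage score of one rank-1 Boolean pattern
#'
#' Score of adding the pattern `candidate_column %o% candidate_row`:
#' `omega * (new 1-entries of Y covered) - (new 0-entries of Y overwritten)`,
#' where cells already covered by previously selected atoms (the
#' `already_covered` mask) contribute nothing.
#'
#' @param Y binary `m x T` matrix.
#' @param candidate_column binary m-vector.
#' @param candidate_row binary T-vector.
#' @param already_covered logical/binary `m x T` mask of cells covered so far.
#' @param omega coverage weight.
#' @return scalar score.
#' @export
coverage_score <- function(Y, candidate_column, candidate_row,
                           already_covered, omega) {
  P <- outer(candidate_column > 0, candidate_row > 0)
  fresh <- P & !already_covered
  omega * sum(fresh & Y == 1) - sum(fresh & Y == 0)
}

#' Greedy-optimal usage row for a candidate dictionary column
#'
#' The coverage score is separable over columns of Y, so the score-maximizing
#' row sets entry t to 1 exactly when column t's marginal contribution
#' `omega * new-ones - new-zeros` is strictly positive.
#'
#' @inheritParams coverage_score
#' @return binary T-vector maximizing [coverage_score()] for the column.
#' @export
best_usage_row <- function(Y, candidate_column, already_covered, omega) {
  d <- candidate_column > 0
  fresh <- !already_covered
  ones <- colSums((Y == 1) & fresh & d)
  zeros <- colSums((Y == 0) & fresh & d)
  as.integer(omega * ones - zeros > 0)
}

#' Greedy Boolean matrix factorization
#'
#' Factorizes a binary matrix `Y ~ D o C` (Boolean product) by repeatedly
#' selecting, among the rows of the association matrix, the candidate
#' dictionary column whose optimal usage row yields the largest coverage
#' score. The loop stops when `max_atoms` columns have been selected, when the
#' number of uncovered ones falls to `error_tolerance` or below, or when no
#' candidate has strictly positive score. Ties are broken toward the lowest
#' candidate row index; candidates identical to an already selected dictionary
#' column are skipped, so the result is deterministic and the dictionary
#' columns are pairwise distinct.
#'
#' @param Y binary `m x T` matrix or a [build_sampling_matrix()] result.
#' @param config a [pooling_config()]; uses `confidence_threshold`,
#'   `coverage_weight`, `max_atoms`, `error_tolerance`.
#' @return object of class `bmf_result` with `dictionary` (`m x k`), `code`
#'   (`k x T`), `atom_count`, `residual_l1` (ones of Y not covered by `D o C`),
#'   `coverage_trace` (per-iteration scores, all strictly positive),
#'   `ego_size` when available.
#' @export
factorize_boolean <- function(Y, config) {
  ego_size <- NA_integer_
  if (inherits(Y, "sampling_matrix")) {
    ego_size <- Y$ego_size
    Y <- Y$matrix
  }
  m <- nrow(Y); tt <- ncol(Y)
  omega <- config$coverage_weight
  D <- matrix(0, m, 0)
  C <- matrix(0, 0, tt)
  trace <- numeric(0)
  resid <- sum(Y == 1)
  if (resid > 0) {
    R <- row_association_matrix(Y, config$confidence_threshold)
    alive <- rowSums(R) > 0
    covered <- matrix(FALSE, m, tt)
    while (ncol(D) < config$max_atoms && resid > config$error_tolerance) {
      fresh_ones <- (Y == 1) & !covered
      fresh_zeros <- (Y == 0) & !covered
      gains <- omega * (R %*% fresh_ones) - (R %*% fresh_zeros)
      use <- gains > 0
      scores <- rowSums(gains * use)
      ok <- alive
      if (ncol(D) > 0) {
        # drop candidates identical to an existing dictionary column
        dup <- vapply(seq_len(m), function(i)
          ok[i] && any(colSums(abs(D - R[i, ])) == 0), logical(1))
        ok <- ok & !dup
      }
      scores[!ok] <- -Inf
      best <- which.max(scores)          # first max = lowest index tie-break
      if (!is.finite(scores[best]) || scores[best] <= 0) break
      d <- R[best, ]
      cl <- as.numeric(use[best, ])
      D <- cbind(D, d, deparse.level = 0)
      C <- rbind(C, cl, deparse.level = 0)
      covered <- covered | outer(d > 0, cl > 0)
      resid <- sum((Y == 1) & !covered)
      trace <- c(trace, scores[best])
    }
  }
  structure(list(dictionary = D, code = C, atom_count = ncol(D),
                 residual_l1 = resid, coverage_trace = trace,
                 ego_size = ego_size),
            class = "bmf_result")
}

#' @export
print.bmf_result <- function(x, ...) {
  cat(sprintf("<bmf_result> k=%d atoms, residual |.|_1 = %d\n",
              x$atom_count, x$residual_l1))
  invisible(x)
}

#' Reconstruction error of a Boolean factorization
#'
#' @param Y binary `m x T` matrix.
#' @param D binary `m x k` dictionary.
#' @param C binary `k x T` code.
#' @return named vector `c(uncovered = ..., overcovered = ...)`: ones of Y
#'   missed by `D o C`, and zeros of Y overwritten by it.
#' @export
reconstruction_error <- function(Y, D, C) {
  if (inherits(Y, "sampling_matrix")) Y <- Y$matrix
  P <- boolean_product(D, C)
  if (!all(dim(P) == dim(Y))) stop("shape mismatch")
  c(uncovered = sum(Y == 1 & P == 0), overcovered = sum(Y == 0 & P == 1))
}

#' Serialize a factorization to a plain-text archive
#'
#' One text file: a JSON header line (ego size, k, residual, dims), then the
#' dictionary rows and code rows as 0/1 strings separated by a blank line.
#'
#' @param x a `bmf_result`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_factorization <- function(x, path) {
  header <- jsonlite::toJSON(list(ego_size = x$ego_size, k = x$atom_count,
                                  residual_l1 = x$residual_l1,
                                  m = nrow(x$dictionary),
                                  t = ncol(x$code)),
                             auto_unbox = TRUE, na = "null")
  rows <- function(M) apply(M, 1, paste, collapse = "")
  lines <- c(as.character(header),
             if (x$atom_count > 0) rows(x$dictionary), "",
             if (x$atom_count > 0) rows(x$code))
  writeLines(lines, path)
  invisible(path)
}

#' Read a factorization written by [write_factorization()]
#'
#' @param path input file.
#' @return a `bmf_result` (without coverage trace).
#' @export
read_factorization <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  parse_block <- function(block, ncol_expect) {
    if (length(block) == 0) return(matrix(0, 0, ncol_expect))
    do.call(rbind, lapply(strsplit(block, ""), as.numeric))
  }
  body <- lines[-1]
  sep <- which(body == "")[1]
  D <- parse_block(body[seq_len(sep - 1)], header$k)
  C <- parse_block(body[-seq_len(sep)], header$t)
  if (header$k == 0) {
    D <- matrix(0, header$m, 0)
    C <- matrix(0, 0, header$t)
  }
  structure(list(dictionary = D, code = C, atom_count = header$k,
                 residual_l1 = header$residual_l1, coverage_trace = numeric(0),
                 ego_size = if (is.null(header$ego_size)) NA_integer_ else header$ego_size),
            class = "bmf_result")
}
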