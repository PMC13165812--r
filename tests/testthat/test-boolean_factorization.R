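# brute-force confidence oracle for the association matrix
assoc_oracle <- function(Y, phi) {
  m <- nrow(Y)
  R <- matrix(0, m, m)
  for (i in seq_len(m)) {
    s <- sum(Y[i, ] * Y[i, ])
    if (s == 0) next
    for (j in seq_len(m))
      R[i, j] <- as.numeric(sum(Y[i, ] * Y[j, ]) / s >= phi)
  }
  R
}

# cell-by-cell coverage oracle
coverage_oracle <- function(Y, d, cl, covered, omega) {
  sc <- 0
  for (i in seq_len(nrow(Y))) for (t in seq_len(ncol(Y))) {
    if (d[i] > 0 && cl[t] > 0 && !covered[i, t])
      sc <- sc + if (Y[i, t] == 1) omega else -1
  }
  sc
}

test_that("boolean_product equals the thresholded integer product", {
  d <- c(1, 0, 1)
  expect_equal(boolean_product(matrix(d), matrix(1, 1, 4)),
               matrix(d, 3, 4))
  expect_equal(boolean_product(matrix(d), matrix(0, 1, 4)), matrix(0, 3, 4))
  expect_error(boolean_product(matrix(0, 2, 3), matrix(0, 2, 3)), "dimension")
  set.seed(1)
  for (rep in 1:10) {
    D <- random_binary_matrix(6, 4); C <- random_binary_matrix(4, 7)
    expect_equal(boolean_product(D, C), 1 * (D %*% C >= 1))
  }
})

test_that("row association matrix matches the double-loop confidence oracle", {
  Y <- rbind(c(1, 1, 0), c(1, 1, 0), c(0, 0, 1), c(0, 0, 0))
  R <- row_association_matrix(Y, 1)
  expect_equal(R[1, 2], 1); expect_equal(R[2, 1], 1)   # identical rows
  expect_equal(R[1, 3], 0); expect_equal(R[3, 1], 0)   # disjoint support
  expect_equal(R[4, ], rep(0, 4))                      # all-zero row
  expect_equal(diag(R)[1:3], rep(1, 3))
  set.seed(2)
  for (rep in 1:10) {
    Y <- random_binary_matrix(8, 8)
    phi <- sample(c(0.3, 0.5, 0.8, 1), 1)
    expect_equal(row_association_matrix(Y, phi), assoc_oracle(Y, phi))
  }
})

test_that("coverage_score matches the exhaustive cell count", {
  # uncovered a x b block of ones with no spill -> omega * a * b
  Y <- matrix(0, 5, 6); Y[2:3, 2:5] <- 1
  d <- as.numeric(seq_len(5) %in% 2:3)
  cl <- as.numeric(seq_len(6) %in% 2:5)
  none <- matrix(FALSE, 5, 6)
  expect_equal(coverage_score(Y, d, cl, none, 2), 2 * 2 * 4)
  # candidate entirely inside the covered mask scores 0
  all_cov <- matrix(TRUE, 5, 6)
  expect_equal(coverage_score(Y, d, cl, all_cov, 2), 0)
  set.seed(3)
  for (rep in 1:15) {
    Y <- random_binary_matrix(6, 7)
    d <- random_binary_matrix(6, 1)[, 1]
    cl <- random_binary_matrix(1, 7)[1, ]
    covered <- random_binary_matrix(6, 7, 0.3) > 0
    omega <- stats::runif(1, 0.5, 2)
    expect_equal(coverage_score(Y, d, cl, covered, omega),
                 coverage_oracle(Y, d, cl, covered, omega))
  }
})

test_that("best_usage_row is the enumeration optimum (separability)", {
  Y <- random_binary_matrix(6, 5)   # deterministic seed below
  set.seed(4)
  for (rep in 1:10) {
    m <- 6; tt <- sample(4:8, 1)
    Y <- random_binary_matrix(m, tt)
    d <- random_binary_matrix(m, 1)[, 1]
    covered <- random_binary_matrix(m, tt, 0.2) > 0
    omega <- sample(c(0.8, 1, 1.5), 1)
    row <- best_usage_row(Y, d, covered, omega)
    sc <- coverage_score(Y, d, row, covered, omega)
    cand <- all_binary_vectors(tt)
    best <- max(apply(cand, 2, function(cl)
      coverage_score(Y, d, cl, covered, omega)))
    expect_equal(sc, best)
  }
  # trivial cases
  Y <- cbind(c(1, 1, 0), c(0, 0, 1))
  none <- matrix(FALSE, 3, 2)
  expect_equal(best_usage_row(Y, c(1, 1, 0), none, 1), c(1L, 0L))
})

test_that("factorize handles degenerate and exact rank-1 inputs", {
  cfg <- pooling_config(ego_size = 3, confidence_threshold = 1,
                        error_tolerance = 0, max_atoms = 5)
  f0 <- factorize_boolean(matrix(0, 4, 5), cfg)
  expect_equal(f0$atom_count, 0)
  expect_equal(f0$residual_l1, 0)

  d <- c(1, 0, 1, 1); cl <- c(1, 1, 0, 1, 1)
  Y <- outer(d, cl)
  f1 <- factorize_boolean(Y, cfg)
  expect_equal(f1$atom_count, 1)
  expect_equal(as.numeric(f1$dictionary), d)
  expect_equal(as.numeric(f1$code), cl)
  expect_equal(f1$residual_l1, 0)
})

test_that("factorize recovers two disjoint-row planted patterns exactly", {
  d1 <- c(1, 1, 1, 0, 0, 0); c1 <- c(1, 1, 1, 1, 0, 0, 0, 0)
  d2 <- c(0, 0, 0, 1, 1, 1); c2 <- c(0, 0, 1, 1, 1, 1, 1, 1)
  Y <- 1 * (outer(d1, c1) + outer(d2, c2) > 0)
  cfg <- pooling_config(ego_size = 3, confidence_threshold = 1,
                        error_tolerance = 0, max_atoms = 4)
  f <- factorize_boolean(Y, cfg)
  expect_equal(f$atom_count, 2)
  expect_equal(f$residual_l1, 0)
  got <- lapply(seq_len(2), function(a) f$dictionary[, a])
  expect_true(all(vapply(list(d1, d2), function(d)
    any(vapply(got, function(g) all(g == d), logical(1))), logical(1))))
  expect_equal(reconstruction_error(Y, f$dictionary, f$code),
               c(uncovered = 0, overcovered = 0))
})

test_that("greedy loop equals the step-wise primitive oracle on random inputs", {
  # dual route: factorize() vs an independent loop made of the exported
  # primitives row_association_matrix / best_usage_row / coverage_score
  set.seed(6)
  for (rep in 1:10) {
    Y <- random_binary_matrix(8, 8, 0.4)
    cfg <- pooling_config(ego_size = 3, confidence_threshold = 0.6,
                          max_atoms = 4)
    f <- factorize_boolean(Y, cfg)
    R <- row_association_matrix(Y, cfg$confidence_threshold)
    covered <- matrix(FALSE, 8, 8)
    D <- matrix(0, 8, 0); C <- matrix(0, 0, 8)
    repeat {
      if (ncol(D) >= cfg$max_atoms || sum(Y == 1 & !covered) == 0) break
      best_sc <- 0; best_i <- NA; best_row <- NULL
      for (i in seq_len(8)) {
        if (sum(R[i, ]) == 0) next
        if (ncol(D) > 0 && any(colSums(abs(D - R[i, ])) == 0)) next
        row_i <- best_usage_row(Y, R[i, ], covered, cfg$coverage_weight)
        sc <- coverage_score(Y, R[i, ], row_i, covered, cfg$coverage_weight)
        if (sc > best_sc) { best_sc <- sc; best_i <- i; best_row <- row_i }
      }
      if (best_sc <= 0) break
      D <- cbind(D, R[best_i, ]); C <- rbind(C, best_row)
      covered <- covered | outer(R[best_i, ] > 0, best_row > 0)
    }
    expect_equal(unname(f$dictionary), unname(D))
    expect_equal(unname(f$code), unname(C))
  }
})

test_that("factorization invariants: monotone residual, positive trace, k cap, determinism", {
  set.seed(7)
  for (rep in 1:10) {
    Y <- random_binary_matrix(10, 12, 0.35)
    cfg <- pooling_config(ego_size = 4, max_atoms = 3)
    f <- factorize_boolean(Y, cfg)
    expect_lte(f$atom_count, 3)
    expect_true(all(f$coverage_trace > 0))
    expect_equal(f$residual_l1,
                 unname(reconstruction_error(Y, f$dictionary, f$code)["uncovered"]))
    # distinct columns
    if (f$atom_count > 1)
      expect_equal(anyDuplicated(t(f$dictionary)), 0)
    f2 <- factorize_boolean(Y, cfg)
    expect_identical(f, f2)
  }
})

test_that("factorization text archive round-trips", {
  set.seed(8)
  Y <- random_binary_matrix(9, 6, 0.4)
  f <- factorize_boolean(Y, pooling_config(ego_size = 3))
  path <- withr::local_tempfile()
  write_factorization(f, path)
  back <- read_factorization(path)
  expect_equal(unname(back$dictionary), unname(f$dictionary))
  expect_equal(unname(back$code), unname(f$code))
  expect_equal(back$residual_l1, f$residual_l1)
  # empty factorization round-trips too
  f0 <- factorize_boolean(matrix(0, 9, 4), pooling_config(ego_size = 3))
  write_factorization(f0, path)
  expect_equal(read_factorization(path)$atom_count, 0)
})
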