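test_that("gcn_propagate matches the dense normalization oracle", {
  # isolated self-looped node: normalization is 1, so H = ReLU(X W)
  X <- matrix(c(2, -3), 1, 2)
  expect_equal(gcn_propagate(X, matrix(0, 1, 1), diag(2)),
               matrix(c(2, 0), 1, 2))
  # zero features stay zero
  expect_equal(gcn_propagate(matrix(0, 3, 2), path_graph(3)$adjacency,
                             diag(2)),
               matrix(0, 3, 2))
  # 3-node path vs explicit D^-1/2 (A+I) D^-1/2 X W
  set.seed(41)
  A <- path_graph(3)$adjacency
  X <- matrix(stats::rnorm(6), 3, 2)
  W <- matrix(stats::rnorm(4), 2, 2)
  At <- A + diag(3)
  Dm <- diag(1 / sqrt(rowSums(At)))
  expect_equal(gcn_propagate(X, A, W), pmax(Dm %*% At %*% Dm %*% X %*% W, 0))
})

test_that("readout concatenates max, mean and sum", {
  f <- matrix(c(1, -2, 3), 1, 3)
  expect_equal(readout(f), c(f, f, f))
  two <- rbind(c(1, 2), c(1, 2))
  expect_equal(readout(two), c(1, 2, 1, 2, 2, 4))
  expect_error(readout(matrix(0, 0, 2)), "at least one node")
  set.seed(42)
  X <- matrix(stats::rnorm(35), 5, 7)
  expect_equal(readout(X),
               c(apply(X, 2, max), apply(X, 2, mean), apply(X, 2, sum)))
})

make_tiny_setup <- function(hidden = 6, dropout = 0, seed = 7,
                            graphs_per_class = 3) {
  res <- generate_two_class_dataset(
    synthetic_config(graphs_per_class = graphs_per_class, seed = seed))
  mc <- model_config(hidden_dim = hidden, mlp_hidden = 4, dropout = dropout)
  pc <- pooling_config(ego_size = 4)
  list(ds = res$dataset, mc = mc, pc = pc,
       caches = apnn_prepare(res$dataset, mc, pc))
}

test_that("forward pass has the right shape and is deterministic in eval mode", {
  su <- make_tiny_setup()
  set.seed(1)
  params <- apnn_init(su$ds$feature_dim, 2, su$mc)
  l1 <- apnn_forward(params, su$caches[[1]], su$mc)
  l2 <- apnn_forward(params, su$caches[[1]], su$mc)
  expect_length(l1, 2)
  expect_identical(l1, l2)
  bad <- su$caches[[1]]; bad$X <- cbind(bad$X, 1)
  expect_error(apnn_forward(params, bad, su$mc), "feature dimension")
})

test_that("identity pooling reduces the network to a plain GCN with the same readout", {
  su <- make_tiny_setup()
  g <- su$ds$graphs[[1]]
  idcache <- apnn_prepare_one_graph(g, su$mc, su$pc, identity_pool = TRUE)
  set.seed(2)
  params <- apnn_init(su$ds$feature_dim, 2, su$mc)
  got <- apnn_forward(params, idcache, su$mc)
  # independent plain-GCN oracle built from gcn_propagate and readout
  A <- g$adjacency
  H0 <- gcn_propagate(g$features, A, params$W_emb, params$b_emb)
  H1 <- gcn_propagate(H0, A, params$W1, params$b1)
  H2 <- gcn_propagate(H1, A, params$W2, params$b2)
  H3 <- gcn_propagate(H2, A, params$W3, params$b3)
  r <- c(readout(H0), readout(H1), readout(H2), readout(H3))
  z1 <- pmax(r %*% params$W_m1 + params$b_m1, 0)
  logits <- as.numeric(z1 %*% params$W_m2 + params$b_m2)
  expect_equal(got, logits, tolerance = 1e-12)
})

test_that("analytic gradients agree with finite differences", {
  su <- make_tiny_setup(hidden = 4)
  set.seed(3)
  params <- apnn_init(su$ds$feature_dim, 2, su$mc)
  cache <- su$caches[[2]]
  lg <- atompool:::apnn_loss_grad(params, cache, su$mc)
  eps <- 1e-6
  for (nm in names(params)) {
    for (i in seq_len(min(3, length(params[[nm]])))) {
      up <- params; up[[nm]][i] <- up[[nm]][i] + eps
      dn <- params; dn[[nm]][i] <- dn[[nm]][i] - eps
      num <- (atompool:::apnn_loss_grad(up, cache, su$mc)$loss -
                atompool:::apnn_loss_grad(dn, cache, su$mc)$loss) / (2 * eps)
      expect_equal(lg$grads[[nm]][i], num, tolerance = 1e-4)
    }
  }
})

test_that("a one-class training set is fit perfectly within a few epochs", {
  su <- make_tiny_setup(graphs_per_class = 4)
  onecls <- Filter(function(cc) cc$label == 0, su$caches)
  tc <- train_config(learning_rate = 0.05, max_epochs = 30, patience = 29,
                     seed = 5, batch_size = 2)
  fit <- train_model(onecls, onecls, su$mc, tc, su$pc)
  expect_equal(apnn_evaluate(fit$params, onecls, su$mc)$accuracy, 1)
  expect_lte(fit$best_epoch, 10)
})

test_that("patience 1 with zero learning rate stops after exactly 2 epochs", {
  su <- make_tiny_setup()
  tc <- train_config(learning_rate = 0, max_epochs = 50, patience = 1,
                     seed = 6, batch_size = 4)
  mc <- su$mc; mc$dropout <- 0   # freeze everything
  fit <- train_model(su$caches, su$caches, mc, tc, su$pc)
  expect_equal(nrow(fit$history), 2)
})

test_that("the network learns a separable synthetic dataset", {
  res <- generate_two_class_dataset(
    synthetic_config(graphs_per_class = 20, noise_edge_prob = 0, seed = 8))
  mc <- model_config(hidden_dim = 16, mlp_hidden = 8)
  pc <- pooling_config()
  tc <- train_config(max_epochs = 30, patience = 29, seed = 9, batch_size = 16)
  caches <- apnn_prepare(res$dataset, mc, pc)
  labs <- vapply(caches, function(cc) cc$label, integer(1))
  folds <- stratified_folds(labs, 4, seed = 9)
  fit <- train_model(caches[folds != 1], caches[folds == 1], mc, tc, pc)
  expect_gte(fit$best_val_accuracy, 0.9)
  # loss trends down over the first epochs
  h <- fit$history$train_loss
  expect_lt(mean(utils::tail(h, 3)), mean(utils::head(h, 3)))
})

test_that("stratified folds partition the data and are seed-deterministic", {
  labels <- rep(c(0L, 1L), c(25, 35))
  f1 <- stratified_folds(labels, 5, seed = 10)
  f2 <- stratified_folds(labels, 5, seed = 10)
  expect_identical(f1, f2)
  expect_setequal(unique(f1), 1:5)
  expect_equal(sort(unlist(lapply(1:5, function(f) which(f1 == f)))),
               seq_along(labels))
  # per-class balance within one graph
  for (f in 1:5) expect_equal(sum(f1 == f & labels == 0), 5)
  # majority-class dummy accuracy on balanced folds is ~ the base rate
  base <- vapply(1:5, function(f) mean(labels[f1 == f] == 1), numeric(1))
  expect_true(all(abs(base - 35 / 60) < 0.1))
})

test_that("cross_validate returns disjoint fold accuracies", {
  res <- generate_two_class_dataset(
    synthetic_config(graphs_per_class = 10, noise_edge_prob = 0, seed = 12))
  mc <- model_config(hidden_dim = 8, mlp_hidden = 4)
  tc <- train_config(max_epochs = 3, patience = 2, seed = 13, folds = 5,
                     batch_size = 8)
  cv <- cross_validate(res$dataset, mc, tc, pooling_config())
  expect_length(cv$per_fold, 5)
  expect_true(all(cv$per_fold >= 0 & cv$per_fold <= 1))
  expect_equal(cv$mean, mean(cv$per_fold))
  expect_setequal(unique(cv$fold_assignment), 1:5)
  expect_error(
    cross_validate(res$dataset, mc, train_config(folds = 11, seed = 1),
                   pooling_config()),
    "fewer folds")
  expect_error(
    cross_validate(res$dataset, mc, train_config(folds = 2, seed = 1),
                   pooling_config()),
    ">= 3 folds")
})

test_that("atom_report computes per-class activation proportions", {
  # triangle graph, single graph of class 0: one clique atom active everywhere
  ds <- graph_dataset(list({
    g <- triangle_graph(); g$label <- 0L; g
  }))
  rep0 <- atom_report(ds, pooling_config(ego_size = 3))
  expect_equal(nrow(rep0$table), 1)
  expect_equal(rep0$table$activation_class0, 1)
  expect_equal(rep0$atoms[[1]]$adjacency,
               {
                 A <- matrix(1, 3, 3); diag(A) <- 0
                 A
               })
  # two-class planted dataset: each motif atom is more active in its own class
  res <- generate_two_class_dataset(
    synthetic_config(graphs_per_class = 10, noise_edge_prob = 0, seed = 14))
  rp <- atom_report(res$dataset, pooling_config(ego_size = 5))
  lib <- motif_library()
  jac <- function(key_atom, motif)
    jaccard_binary(key_atom$pattern, motif_atom_vector(motif$adjacency, 5))
  cl_idx <- which.max(vapply(rp$atoms, jac, numeric(1), motif = lib$clique4))
  st_idx <- which.max(vapply(rp$atoms, jac, numeric(1), motif = lib$star5))
  expect_gt(rp$table$activation_class0[cl_idx],
            rp$table$activation_class1[cl_idx])
  expect_gt(rp$table$activation_class1[st_idx],
            rp$table$activation_class0[st_idx])
})
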