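#' Model architecture configuration
#'
#' Defaults follow the common benchmark protocol: an embedding GCN layer plus
#' `conv_layers` GCN layers of width `hidden_dim` with ReLU, pooling after the
#' layers in `pool_after`, a two-layer MLP head of width `mlp_hidden`, and
#' dropout after every convolutional layer during training. Graph-level
#' readout is the concatenation of column-wise max, mean and sum, collected
#' at the embedding stage, after each pooling stage, and at the final
#' convolution output.
#'
#' @param hidden_dim GCN width (default 128).
#' @param mlp_hidden MLP hidden width (default 64).
#' @param conv_layers number of post-embedding GCN layers (default 3).
#' @param pool_after indices (in `1..conv_layers-1`) after which pooling is
#'   applied (default `c(1, 2)`).
#' @param dropout dropout rate (default 0.5).
#' @param backbone `"gcn"` (implemented) or `"gat"` (registered seam, not
#'   implemented).
#' @return object of class `model_config`.
#' @export
model_config <- function(hidden_dim = 128, mlp_hidden = 64, conv_layers = 3,
                         pool_after = c(1, 2), dropout = 0.5,
                         backbone = c("gcn", "gat")) {
  backbone <- match.arg(backbone)
  if (backbone == "gat")
    stop("the 'gat' backbone is a registered seam and not implemented")
  pool_after <- sort(unique(as.integer(pool_after)))
  if (length(pool_after) > 0 &&
      (min(pool_after) < 1 || max(pool_after) > conv_layers - 1))
    stop("pool_after must be a subset of 1..(conv_layers - 1)")
  if (dropout < 0 || dropout >= 1) stop("dropout must lie in [0, 1)")
  structure(list(hidden_dim = as.integer(hidden_dim),
                 mlp_hidden = as.integer(mlp_hidden),
                 conv_layers = as.integer(conv_layers),
                 pool_after = pool_after, dropout = dropout,
                 backbone = backbone),
            class = "model_config")
}

#' Training protocol configuration
#'
#' Adam with constant learning rate 0.001, weight decay 5e-4, batch size 64,
#' cross-entropy loss, early stopping on validation accuracy (ties broken by
#' lower validation loss) with patience 50, at most 500 epochs, stratified
#' 10-fold cross-validation with an 8/1/1 train/validation/test split per
#' fold.
#'
#' @param learning_rate,weight_decay,batch_size,max_epochs,patience,seed,folds
#'   see description for defaults.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 5e-4,
                         batch_size = 64, max_epochs = 500, patience = 50,
                         seed = 1, folds = 10) {
  if (patience >= max_epochs) stop("patience must be < max_epochs")
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed),
                 folds = as.integer(folds)),
            class = "train_config")
}

# symmetric normalization with self-loops: D^-1/2 (A + I) D^-1/2
norm_adj <- function(A) {
  At <- A + diag(nrow(A))
  dd <- 1 / sqrt(rowSums(At))
  At * outer(dd, dd)
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

colmax <- function(X) X[cbind(max.col(t(X), ties.method = "first"),
                              seq_len(ncol(X)))]

#' One GCN propagation step
#'
#' `H = ReLU(D^-1/2 (A + I) D^-1/2 X W + b)` with degree matrix D of `A + I`.
#' Weighted adjacencies (from coarsened layers) are supported.
#'
#' @param X `N x d_in` features.
#' @param A nonnegative symmetric `N x N` adjacency.
#' @param W `d_in x d_out` weights.
#' @param b optional length-`d_out` bias.
#' @return `N x d_out` hidden features.
#' @export
gcn_propagate <- function(X, A, W, b = NULL) {
  H <- norm_adj(A) %*% X %*% W
  if (!is.null(b)) H <- H + rep(b, each = nrow(H))
  relu(H)
}

#' Max / mean / sum readout
#'
#' @param X `N x d` node feature matrix, `N >= 1`.
#' @return numeric vector of length `3 d`: column-wise max, mean and sum
#'   concatenated in that order.
#' @export
readout <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) < 1) stop("readout requires at least one node")
  cs <- colSums(X)
  c(colmax(X), cs / nrow(X), cs)
}

# gradient of readout wrt X, given the gradient on the 3d-length output
readout_bwd <- function(X, dr) {
  n <- nrow(X); h <- ncol(X)
  dmax <- dr[seq_len(h)]
  dmean <- dr[h + seq_len(h)]
  dsum <- dr[2 * h + seq_len(h)]
  dX <- matrix(rep(dmean / n + dsum, each = n), n, h)
  am <- max.col(t(X), ties.method = "first")
  dX[cbind(am, seq_len(h))] <- dX[cbind(am, seq_len(h))] + dmax
  dX
}

n_readout_stages <- function(mconfig) 2L + length(mconfig$pool_after)

#' Initialize APNN parameters (Glorot uniform)
#'
#' Consumes the session RNG stream; seed before calling for reproducibility.
#'
#' @param feature_dim input feature dimension.
#' @param class_count number of classes.
#' @param mconfig a [model_config()].
#' @return named list of weight matrices and bias vectors.
#' @export
apnn_init <- function(feature_dim, class_count, mconfig) {
  glorot <- function(fin, fout) {
    s <- sqrt(6 / (fin + fout))
    matrix(stats::runif(fin * fout, -s, s), fin, fout)
  }
  h <- mconfig$hidden_dim
  params <- list(W_emb = glorot(feature_dim, h), b_emb = numeric(h))
  for (j in seq_len(mconfig$conv_layers)) {
    params[[paste0("W", j)]] <- glorot(h, h)
    params[[paste0("b", j)]] <- numeric(h)
  }
  rdim <- 3L * h * n_readout_stages(mconfig)
  params$W_m1 <- glorot(rdim, mconfig$mlp_hidden)
  params$b_m1 <- numeric(mconfig$mlp_hidden)
  params$W_m2 <- glorot(mconfig$mlp_hidden, class_count)
  params$b_m2 <- numeric(class_count)
  params
}

# Precompute the per-graph combinatorial pipeline: normalized adjacencies for
# every convolution and the assignment matrices of each pooling stage. The
# pooling is computed once on the topology and treated as a constant during
# training; gradients flow through S X and S A S' as fixed linear maps.
# Conv layer j sees the adjacency *before* pool j; pooling after conv j
# updates the adjacency used from conv j+1 onward.
apnn_prepare_one <- function(graph, mconfig, pconfig, identity_pool = FALSE) {
  L <- mconfig$conv_layers
  A <- graph$adjacency
  Ahat <- vector("list", L + 1)
  S <- vector("list", L)
  pools <- vector("list", L)
  Ahat[[1]] <- norm_adj(A)          # embedding conv
  for (j in seq_len(L)) {
    Ahat[[j + 1]] <- norm_adj(A)    # conv layer j
    if (j %in% mconfig$pool_after) {
      if (identity_pool) {
        S[[j]] <- diag(nrow(A))
      } else {
        pl <- pool_layer(A, matrix(1, nrow(A), 1), pconfig)
        S[[j]] <- pl$assignment$matrix
        A <- pl$coarsened$adjacency
        pools[[j]] <- pl
      }
    }
  }
  list(X = graph$features, label = graph$label, Ahat = Ahat, S = S,
       pools = pools, n = graph$node_count)
}

#' Precompute pooling caches for a dataset
#'
#' The combinatorial pooling pipeline (ego sampling, Boolean factorization,
#' assignment) depends only on each graph's topology, so it is computed once
#' per graph and reused across epochs and cross-validation folds.
#'
#' @param dataset a [graph_dataset()].
#' @param mconfig a [model_config()].
#' @param pconfig a [pooling_config()].
#' @param identity_pool replace every assignment by the identity (diagnostic
#'   path; turns the network into a plain GCN).
#' @return list of per-graph caches.
#' @export
apnn_prepare <- function(dataset, mconfig, pconfig, identity_pool = FALSE) {
  lapply(dataset$graphs, apnn_prepare_one, mconfig = mconfig,
         pconfig = pconfig, identity_pool = identity_pool)
}

# forward pass; when train = TRUE applies inverted dropout and records the
# trace needed for backprop
apnn_forward_cache <- function(params, cache, mconfig, train = FALSE) {
  p <- mconfig$dropout
  L <- mconfig$conv_layers
  steps <- list()
  reads <- list()
  conv <- function(H_in, Ahat, W, b) {
    AX <- Ahat %*% H_in
    Z <- AX %*% W + rep(b, each = nrow(AX))
    Hr <- relu(Z)
    mask <- NULL
    H <- Hr
    if (train && p > 0) {
      mask <- (stats::runif(length(Hr)) >= p) / (1 - p)
      dim(mask) <- dim(Hr)
      H <- Hr * mask
    }
    list(AX = AX, pos = Z > 0, mask = mask, H = H)
  }
  st <- conv(cache$X, cache$Ahat[[1]], params$W_emb, params$b_emb)
  st$type <- "conv"; st$wname <- "W_emb"; st$bname <- "b_emb"
  st$Ahat <- cache$Ahat[[1]]; st$read <- 1L
  steps[[1]] <- st
  reads[[1]] <- readout(st$H)
  H <- st$H
  nread <- 1L
  for (j in seq_len(L)) {
    st <- conv(H, cache$Ahat[[j + 1]], params[[paste0("W", j)]],
               params[[paste0("b", j)]])
    st$type <- "conv"; st$wname <- paste0("W", j); st$bname <- paste0("b", j)
    st$Ahat <- cache$Ahat[[j + 1]]; st$read <- NA_integer_
    steps[[length(steps) + 1]] <- st
    H <- st$H
    if (!is.null(cache$S[[j]])) {
      P <- cache$S[[j]] %*% H
      nread <- nread + 1L
      steps[[length(steps) + 1]] <- list(type = "pool", S = cache$S[[j]],
                                         P = P, read = nread)
      reads[[nread]] <- readout(P)
      H <- P
    }
  }
  nread <- nread + 1L
  steps[[length(steps)]]$read <- nread   # final conv output is read out
  reads[[nread]] <- readout(H)
  r <- matrix(unlist(reads), nrow = 1)
  z1 <- relu(r %*% params$W_m1 + rep(params$b_m1, each = 1))
  logits <- z1 %*% params$W_m2 + rep(params$b_m2, each = 1)
  list(logits = as.numeric(logits), steps = steps, reads = reads, r = r,
       z1 = z1, final_H = H)
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

# forward + backward for one graph; returns loss and gradient list
apnn_loss_grad <- function(params, cache, mconfig) {
  fw <- apnn_forward_cache(params, cache, mconfig, train = TRUE)
  probs <- softmax(fw$logits)
  y <- cache$label + 1L
  loss <- -log(max(probs[y], 1e-12))
  grads <- list()
  dlogit <- matrix(probs, nrow = 1)
  dlogit[1, y] <- dlogit[1, y] - 1
  grads$W_m2 <- crossprod(fw$z1, dlogit)
  grads$b_m2 <- as.numeric(dlogit)
  dz1 <- tcrossprod(dlogit, params$W_m2) * (fw$z1 > 0)
  grads$W_m1 <- crossprod(fw$r, dz1)
  grads$b_m1 <- as.numeric(dz1)
  dr <- as.numeric(tcrossprod(dz1, params$W_m1))
  h3 <- vapply(fw$reads, length, integer(1))
  seg_end <- cumsum(h3)
  seg <- function(i) dr[(seg_end[i] - h3[i] + 1):seg_end[i]]

  steps <- fw$steps
  last <- steps[[length(steps)]]
  # dH wrt the output of the last step
  out_H <- if (last$type == "pool") last$P else last$H
  dH <- matrix(0, nrow(out_H), ncol(out_H))
  for (i in rev(seq_along(steps))) {
    st <- steps[[i]]
    if (!is.null(st$read) && !is.na(st$read)) {
      src <- if (st$type == "pool") st$P else st$H
      dH <- dH + readout_bwd(src, seg(st$read))
    }
    if (st$type == "pool") {
      dH <- crossprod(st$S, dH)
    } else {
      dZ <- dH
      if (!is.null(st$mask)) dZ <- dZ * st$mask
      dZ <- dZ * st$pos
      # each conv's weights appear in exactly one step: direct assignment
      grads[[st$wname]] <- crossprod(st$AX, dZ)
      grads[[st$bname]] <- colSums(dZ)
      # Ahat is symmetric, so t(Ahat) %*% x == Ahat %*% x
      dH <- st$Ahat %*% tcrossprod(dZ, params[[st$wname]])
    }
  }
  list(loss = loss, grads = grads)
}

#' Forward pass of the APNN
#'
#' Deterministic when `train = FALSE` (dropout disabled).
#'
#' @param params parameter list from [apnn_init()] or [train_model()].
#' @param cache per-graph cache from [apnn_prepare()] (or a graph plus
#'   configs via [apnn_prepare_one_graph()]).
#' @param mconfig a [model_config()].
#' @param train apply dropout and record internals.
#' @return numeric vector of class logits.
#' @export
apnn_forward <- function(params, cache, mconfig, train = FALSE) {
  if (ncol(cache$X) != nrow(params$W_emb))
    stop("feature dimension does not match the model")
  apnn_forward_cache(params, cache, mconfig, train = train)$logits
}

#' Cache a single graph for [apnn_forward()]
#'
#' @param graph an [new_graph()] object.
#' @param mconfig a [model_config()].
#' @param pconfig a [pooling_config()].
#' @param identity_pool replace assignments by the identity.
#' @return a per-graph cache.
#' @export
apnn_prepare_one_graph <- function(graph, mconfig, pconfig,
                                   identity_pool = FALSE) {
  apnn_prepare_one(graph, mconfig, pconfig, identity_pool = identity_pool)
}

#' Evaluate parameters on cached graphs
#'
#' @param params parameter list.
#' @param caches list of per-graph caches.
#' @param mconfig a [model_config()].
#' @return list with `accuracy`, `loss` (mean cross-entropy), `predicted`
#'   (0-based classes).
#' @export
apnn_evaluate <- function(params, caches, mconfig) {
  losses <- numeric(length(caches))
  pred <- integer(length(caches))
  truth <- integer(length(caches))
  for (i in seq_along(caches)) {
    logits <- apnn_forward(params, caches[[i]], mconfig, train = FALSE)
    pr <- softmax(logits)
    truth[i] <- caches[[i]]$label
    losses[i] <- -log(max(pr[truth[i] + 1L], 1e-12))
    pred[i] <- which.max(logits) - 1L
  }
  list(accuracy = mean(pred == truth), loss = mean(losses), predicted = pred)
}

adam_init <- function(params)
  list(m = lapply(params, function(x) x * 0),
       v = lapply(params, function(x) x * 0), t = 0)

adam_step <- function(params, grads, state, lr, weight_decay,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (weight_decay > 0 && startsWith(nm, "W")) g <- g + weight_decay * params[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

as_caches <- function(x, mconfig, pconfig) {
  if (inherits(x, "graph_dataset")) apnn_prepare(x, mconfig, pconfig) else x
}

#' Train the APNN with Adam and early stopping
#'
#' Minimizes cross-entropy on the training split; validation accuracy is
#' tracked every epoch, the best parameters (accuracy ties broken by lower
#' validation loss) are restored at the end, and training stops after
#' `patience` epochs without improvement or at `max_epochs`.
#'
#' @param train,valid [graph_dataset()] objects or prepared cache lists.
#' @param mconfig a [model_config()].
#' @param tconfig a [train_config()].
#' @param pconfig a [pooling_config()].
#' @return object of class `apnn_model` with `params`, `history` (per-epoch
#'   data.frame), `best_epoch`, `mconfig`, `pconfig`.
#' @export
train_model <- function(train, valid, mconfig = model_config(),
                        tconfig = train_config(),
                        pconfig = pooling_config()) {
  train_caches <- as_caches(train, mconfig, pconfig)
  valid_caches <- as_caches(valid, mconfig, pconfig)
  if (length(train_caches) == 0 || length(valid_caches) == 0)
    stop("training and validation splits must be non-empty")
  d <- ncol(train_caches[[1]]$X)
  classes <- max(vapply(c(train_caches, valid_caches),
                        function(cc) cc$label, integer(1))) + 1L
  classes <- max(classes, 2L)
  set.seed(tconfig$seed)
  params <- apnn_init(d, classes, mconfig)
  opt <- adam_init(params)
  best <- list(acc = -Inf, loss = Inf, params = params, epoch = 0L)
  since <- 0L
  hist <- list()
  n <- length(train_caches)
  for (epoch in seq_len(tconfig$max_epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    for (start in seq(1, n, by = tconfig$batch_size)) {
      idx <- ord[start:min(start + tconfig$batch_size - 1, n)]
      acc_grads <- NULL
      for (i in idx) {
        lg <- apnn_loss_grad(params, train_caches[[i]], mconfig)
        ep_loss <- ep_loss + lg$loss
        acc_grads <- if (is.null(acc_grads)) lg$grads else
          mapply(`+`, acc_grads, lg$grads, SIMPLIFY = FALSE)
      }
      acc_grads <- lapply(acc_grads, function(g) g / length(idx))
      upd <- adam_step(params, acc_grads, opt, tconfig$learning_rate,
                       tconfig$weight_decay)
      params <- upd$params
      opt <- upd$state
    }
    val <- apnn_evaluate(params, valid_caches, mconfig)
    # patience counts epochs without an *accuracy* improvement; the loss
    # tie-break only decides which parameters are kept
    if (val$accuracy > best$acc) {
      best <- list(acc = val$accuracy, loss = val$loss, params = params,
                   epoch = epoch)
      since <- 0L
    } else {
      if (val$accuracy == best$acc && val$loss < best$loss - 1e-12)
        best <- list(acc = val$accuracy, loss = val$loss, params = params,
                     epoch = epoch)
      since <- since + 1L
    }
    hist[[epoch]] <- data.frame(epoch = epoch, train_loss = ep_loss / n,
                                val_accuracy = val$accuracy,
                                val_loss = val$loss)
    if (since >= tconfig$patience) break
  }
  structure(list(params = best$params, history = do.call(rbind, hist),
                 best_epoch = best$epoch, best_val_accuracy = best$acc,
                 mconfig = mconfig, pconfig = pconfig,
                 class_count = classes, feature_dim = d),
            class = "apnn_model")
}

#' @export
print.apnn_model <- function(x, ...) {
  cat(sprintf("<apnn_model> best epoch %d, val accuracy %.3f (%d epochs run)\n",
              x$best_epoch, x$best_val_accuracy, nrow(x$history)))
  invisible(x)
}

#' Deterministic stratified fold assignment
#'
#' @param labels integer class labels.
#' @param folds number of folds.
#' @param seed RNG seed.
#' @return integer vector of fold ids in `1..folds`.
#' @export
stratified_folds <- function(labels, folds, seed) {
  set.seed(seed)
  assign <- integer(length(labels))
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Stratified k-fold cross-validated evaluation
#'
#' Per fold f: fold f is the test split, the next fold is the validation
#' split, the remaining folds train (an 8/1/1 split at 10 folds). Each fold
#' trains with seed `tconfig$seed + fold` so the whole procedure is
#' reproducible from one seed.
#'
#' @param dataset a [graph_dataset()] with at least `folds` graphs per class.
#' @param mconfig a [model_config()].
#' @param tconfig a [train_config()].
#' @param pconfig a [pooling_config()].
#' @return object of class `apnn_cv` with `mean`, `sd`, `per_fold`,
#'   `fold_assignment`.
#' @export
cross_validate <- function(dataset, mconfig = model_config(),
                           tconfig = train_config(),
                           pconfig = pooling_config()) {
  if (tconfig$folds < 3)
    stop("cross_validate needs >= 3 folds (one test, one validation, rest train)")
  labels <- vapply(dataset$graphs, function(g) g$label, integer(1))
  counts <- table(labels)
  if (any(counts < tconfig$folds))
    stop(sprintf("class %s has only %d graphs; use fewer folds",
                 names(counts)[which.min(counts)], min(counts)))
  fold_assign <- stratified_folds(labels, tconfig$folds, tconfig$seed)
  caches <- apnn_prepare(dataset, mconfig, pconfig)
  accs <- numeric(tconfig$folds)
  for (f in seq_len(tconfig$folds)) {
    val_f <- (f %% tconfig$folds) + 1L
    test_idx <- fold_assign == f
    val_idx <- fold_assign == val_f
    train_idx <- !test_idx & !val_idx
    tcf <- tconfig
    tcf$seed <- tconfig$seed + f
    fit <- train_model(caches[train_idx], caches[val_idx], mconfig, tcf,
                       pconfig)
    accs[f] <- apnn_evaluate(fit$params, caches[test_idx], mconfig)$accuracy
  }
  structure(list(mean = mean(accs), sd = stats::sd(accs), per_fold = accs,
                 fold_assignment = fold_assign),
            class = "apnn_cv")
}

#' @export
print.apnn_cv <- function(x, ...) {
  cat(sprintf("<apnn_cv> test accuracy %.3f +/- %.3f over %d folds\n",
              x$mean, x$sd, length(x$per_fold)))
  invisible(x)
}
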