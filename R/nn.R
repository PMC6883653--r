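# Internal feed-forward / 1-D convolution engine.
#
# Conventions: samples live in columns. Dense activations are d x n
# matrices; convolutional activations are F x (P*n) matrices whose columns
# are position-fastest within each sample (see src/conv.cpp for the patch
# layout). All parameters are plain numeric matrices in a flat named list,
# so the Adam update and serialization stay trivial.

.he_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(2 / fan_in)), nrow, ncol)
}

.xavier_init <- function(nrow, ncol, fan_in) {
  matrix(stats::rnorm(nrow * ncol, sd = sqrt(1 / fan_in)), nrow, ncol)
}

.adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

.adam_step <- function(params, grads, state, lr,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / c1) / (sqrt(state$v[[nm]] / c2) + eps)
  }
  list(params = params, state = state)
}

.sigmoid <- function(z) 1 / (1 + exp(-z))

.softmax_cols <- function(z) {
  z <- sweep(z, 2L, apply(z, 2L, max), "-")
  e <- exp(z)
  sweep(e, 2L, colSums(e), "/")
}

# ---- MLP --------------------------------------------------------------

mlp_init_params <- function(n_in, hidden) {
  sizes <- c(n_in, hidden, 1L)
  params <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    params[[paste0("W", i)]] <- .he_init(sizes[i + 1L], sizes[i], sizes[i])
    params[[paste0("b", i)]] <- matrix(0, sizes[i + 1L], 1L)
  }
  params
}

mlp_forward <- function(params, X, dropout = 0, training = FALSE) {
  n_layers <- length(params) / 2L
  A <- X
  cache <- vector("list", n_layers)
  for (i in seq_len(n_layers)) {
    Z <- params[[paste0("W", i)]] %*% A + params[[paste0("b", i)]][, 1L]
    if (i < n_layers) {
      A_out <- pmax(Z, 0)
      mask <- NULL
      if (training && dropout > 0) {
        mask <- matrix(stats::runif(length(A_out)) >= dropout,
                       nrow(A_out), ncol(A_out)) / (1 - dropout)
        A_out <- A_out * mask
      }
      cache[[i]] <- list(A_in = A, Z = Z, mask = mask)
      A <- A_out
    } else {
      cache[[i]] <- list(A_in = A)
      A <- .sigmoid(Z)
    }
  }
  list(p = as.vector(A), cache = cache)
}

mlp_grad <- function(params, X, y, dropout = 0) {
  n <- ncol(X)
  fw <- mlp_forward(params, X, dropout = dropout, training = TRUE)
  p <- fw$p
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  n_layers <- length(params) / 2L
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  dZ <- matrix((p - y) / n, 1L, n)
  for (i in rev(seq_len(n_layers))) {
    A_in <- fw$cache[[i]]$A_in
    grads[[paste0("W", i)]] <- tcrossprod(dZ, A_in)
    grads[[paste0("b", i)]] <- matrix(rowSums(dZ), ncol = 1L)
    if (i > 1L) {
      dA <- crossprod(params[[paste0("W", i)]], dZ)
      mask <- fw$cache[[i - 1L]]$mask
      if (!is.null(mask)) dA <- dA * mask
      dZ <- dA * (fw$cache[[i - 1L]]$Z > 0)
    }
  }
  list(loss = loss, grads = grads)
}

mlp_eval <- function(params, X, y) {
  p <- mlp_forward(params, X)$p
  eps <- 1e-12
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  acc <- mean((p > 0.5) == (y == 1))
  list(loss = loss, acc = acc)
}

# ---- CNN --------------------------------------------------------------

# Architecture bookkeeping: chain of (conv relu, max-pool) blocks followed by
# dense layers and a softmax head over the two orientations.
cnn_arch <- function(window, conv_filters, conv_widths, pool, dense,
                     n_classes = 2L) {
  stopifnot(length(conv_filters) == length(conv_widths),
            length(conv_filters) == length(pool))
  C <- 4L
  L <- as.integer(window)
  layers <- list()
  for (i in seq_along(conv_filters)) {
    P <- L - conv_widths[i] + 1L
    if (P < 1L) stop("conv layer ", i, ": filter wider than its input")
    P2 <- P %/% pool[i]
    if (P2 < 1L) stop("conv layer ", i, ": pooling leaves no positions")
    layers[[i]] <- list(C = C, L = L, w = conv_widths[i], F = conv_filters[i],
                        P = P, pool = pool[i], P2 = P2)
    C <- conv_filters[i]
    L <- P2
  }
  list(conv = layers, flat = C * L, dense = as.integer(dense),
       n_classes = as.integer(n_classes), window = as.integer(window))
}

cnn_init_params <- function(arch) {
  params <- list()
  for (i in seq_along(arch$conv)) {
    ly <- arch$conv[[i]]
    fan_in <- ly$C * ly$w
    params[[paste0("Wc", i)]] <- .he_init(fan_in, ly$F, fan_in)
    params[[paste0("bc", i)]] <- matrix(0, ly$F, 1L)
  }
  sizes <- c(arch$flat, arch$dense, arch$n_classes)
  n_dense <- length(sizes) - 1L
  for (j in seq_len(n_dense)) {
    # Xavier on the dense stack; the ReLU/max-pool conv blocks accumulate
    # positive means, so He scaling here inflates the initial logits. The
    # softmax head starts at zero (uniform posterior).
    params[[paste0("Wd", j)]] <- if (j == n_dense) {
      matrix(0, sizes[j + 1L], sizes[j])
    } else {
      .xavier_init(sizes[j + 1L], sizes[j], sizes[j])
    }
    params[[paste0("bd", j)]] <- matrix(0, sizes[j + 1L], 1L)
  }
  params
}

.pool_keep_idx <- function(P, pool, P2, n) {
  # column indices (in an F x (P*n) matrix) kept by truncating each sample
  # to P2*pool positions
  as.vector(outer(seq_len(pool * P2), (seq_len(n) - 1L) * P, "+"))
}

cnn_forward <- function(params, arch, X, dropout = 0, training = FALSE,
                        keep_cache = FALSE, conv_only = 0L) {
  n <- ncol(X)
  cache <- list(n = n, conv = list(), dense = list())
  A <- X
  for (i in seq_along(arch$conv)) {
    ly <- arch$conv[[i]]
    dim(A) <- c(ly$C * ly$L, n)   # channel-fastest layout is reshape-compatible
    PM <- im2col_t(A, ly$C, ly$L, ly$w)
    Z <- crossprod(params[[paste0("Wc", i)]], PM) + params[[paste0("bc", i)]][, 1L]
    if (conv_only == i) return(list(Z = Z, P = ly$P))
    R <- pmax(Z, 0)
    keep <- .pool_keep_idx(ly$P, ly$pool, ly$P2, n)
    B <- matrix(R[, keep], ly$F * ly$pool, ly$P2 * n)
    M <- B[seq_len(ly$F), , drop = FALSE]
    amax <- matrix(1L, nrow(M), ncol(M))
    for (r in 2:ly$pool) {
      Br <- B[(r - 1L) * ly$F + seq_len(ly$F), , drop = FALSE]
      upd <- Br > M
      M[upd] <- Br[upd]
      amax[upd] <- r
    }
    if (keep_cache) {
      cache$conv[[i]] <- list(PM = PM, Z = Z, keep = keep, amax = amax)
    }
    A <- M
  }
  A <- matrix(A, arch$flat, n)
  n_dense <- length(arch$dense) + 1L
  for (j in seq_len(n_dense)) {
    Z <- params[[paste0("Wd", j)]] %*% A + params[[paste0("bd", j)]][, 1L]
    if (j < n_dense) {
      A_out <- pmax(Z, 0)
      mask <- NULL
      if (training && dropout > 0) {
        mask <- matrix(stats::runif(length(A_out)) >= dropout,
                       nrow(A_out), ncol(A_out)) / (1 - dropout)
        A_out <- A_out * mask
      }
      if (keep_cache) cache$dense[[j]] <- list(A_in = A, Z = Z, mask = mask)
      A <- A_out
    } else {
      if (keep_cache) cache$dense[[j]] <- list(A_in = A)
      A <- .softmax_cols(Z)
    }
  }
  list(S = A, cache = cache)
}

cnn_grad <- function(params, arch, X, y, dropout = 0) {
  # y: integer vector in {0, 1}; class 2 (row 2) is "reverse"
  n <- ncol(X)
  fw <- cnn_forward(params, arch, X, dropout = dropout, training = TRUE,
                    keep_cache = TRUE)
  S <- fw$S
  Y <- rbind(1 - y, y)
  eps <- 1e-12
  loss <- -mean(colSums(Y * log(S + eps)))
  grads <- vector("list", length(params))
  names(grads) <- names(params)

  n_dense <- length(arch$dense) + 1L
  dZ <- (S - Y) / n
  for (j in rev(seq_len(n_dense))) {
    A_in <- fw$cache$dense[[j]]$A_in
    grads[[paste0("Wd", j)]] <- tcrossprod(dZ, A_in)
    grads[[paste0("bd", j)]] <- matrix(rowSums(dZ), ncol = 1L)
    if (j > 1L) {
      dA <- crossprod(params[[paste0("Wd", j)]], dZ)
      mask <- fw$cache$dense[[j - 1L]]$mask
      if (!is.null(mask)) dA <- dA * mask
      dZ <- dA * (fw$cache$dense[[j - 1L]]$Z > 0)
    }
  }
  dA <- crossprod(params[["Wd1"]], dZ)     # arch$flat x n
  # unflatten to F x (P2*n) of the last conv block
  last <- arch$conv[[length(arch$conv)]]
  dM <- matrix(dA, last$F, last$P2 * n)
  for (i in rev(seq_along(arch$conv))) {
    ly <- arch$conv[[i]]
    cc <- fw$cache$conv[[i]]
    # max-pool backward: route gradient to the argmax slot
    dB <- matrix(0, ly$F * ly$pool, ly$P2 * n)
    for (r in seq_len(ly$pool)) {
      rows <- (r - 1L) * ly$F + seq_len(ly$F)
      sel <- cc$amax == r
      blk <- matrix(0, ly$F, ly$P2 * n)
      blk[sel] <- dM[sel]
      dB[rows, ] <- blk
    }
    dR <- matrix(0, ly$F, ly$P * n)
    dR[, cc$keep] <- matrix(dB, ly$F, ly$pool * ly$P2 * n)
    dZc <- dR * (cc$Z > 0)
    grads[[paste0("Wc", i)]] <- tcrossprod(cc$PM, dZc)
    grads[[paste0("bc", i)]] <- matrix(rowSums(dZc), ncol = 1L)
    if (i > 1L) {
      dPM <- params[[paste0("Wc", i)]] %*% dZc
      prev <- arch$conv[[i - 1L]]
      dM <- col2im_t(dPM, ly$C, ly$L, ly$w, n)  # C x (L) per sample = F_{i-1} x (P2_{i-1} * n)
      dM <- matrix(dM, prev$F, prev$P2 * n)
    }
  }
  list(loss = loss, grads = grads)
}

cnn_eval <- function(params, arch, X, y, batch_size = 512L) {
  S <- cnn_predict(params, arch, X, batch_size = batch_size)
  eps <- 1e-12
  Y <- rbind(1 - y, y)
  loss <- -mean(colSums(Y * log(S + eps)))
  acc <- mean((S[2L, ] > S[1L, ]) == (y == 1))
  list(loss = loss, acc = acc)
}

cnn_predict <- function(params, arch, X, batch_size = 512L) {
  n <- ncol(X)
  out <- matrix(0, arch$n_classes, n)
  i <- 1L
  while (i <= n) {
    j <- min(i + batch_size - 1L, n)
    out[, i:j] <- cnn_forward(params, arch, X[, i:j, drop = FALSE])$S
    i <- j + 1L
  }
  out
}

# K-mer-seeded initialization of the first convolutional layer: filters
# start as detectors of the k-mers whose frequencies differ most between
# the two orientation classes of the training set (computed from training
# sequences only). Each seeded filter is a one-hot template centered in the
# filter window with a bias that fires on a near-exact match; backprop then
# selects and refines them. This gives gradient motif discovery a usable
# starting point at desk-scale data sizes, where fully random filters leave
# the optimization on a long plateau.
cnn_seed_filters <- function(params, arch, seqs, y, seed_k = 6L) {
  ly <- arch$conv[[1L]]
  k <- min(seed_k, ly$w)
  counts <- Biostrings::oligonucleotideFrequency(Biostrings::DNAStringSet(seqs),
                                                 width = k)
  freq <- counts / pmax(rowSums(counts), 1L)
  diff <- colMeans(freq[y == 0, , drop = FALSE]) -
    colMeans(freq[y == 1, , drop = FALSE])
  top <- names(sort(abs(diff), decreasing = TRUE))[seq_len(min(ly$F, length(diff)))]
  W <- matrix(0, ly$C * ly$w, ly$F)
  off <- (ly$w - k) %/% 2L
  for (f in seq_along(top)) {
    bases <- match(strsplit(top[f], "")[[1]], c("A", "C", "G", "T"))
    W[cbind(4L * (off + seq_len(k) - 1L) + bases, f)] <- 1
  }
  if (length(top) < ly$F) {
    rest <- (length(top) + 1L):ly$F
    W[, rest] <- .he_init(ly$C * ly$w, length(rest), ly$C * ly$w)
  }
  params$Wc1 <- W
  params$bc1 <- matrix(c(rep(-(k - 1.5), length(top)),
                         rep(0, ly$F - length(top))), ly$F, 1L)
  params
}

# ---- Shared minibatch training loop -----------------------------------

# grad_fun(params, idx) -> list(loss, grads); eval_fun(params, idx) ->
# list(loss, acc). Early stopping on validation loss with best-weight
# restore.
nn_train_loop <- function(params, grad_fun, eval_fun, n, epochs, batch_size,
                          learning_rate, validation_split = 0.1, patience = 5L,
                          seed = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(n)
  n_val <- max(if (validation_split > 0) as.integer(round(validation_split * n)) else 0L, 0L)
  val_idx <- if (n_val > 0L) idx[seq_len(n_val)] else integer(0)
  train_idx <- if (n_val > 0L) idx[-seq_len(n_val)] else idx
  n_train <- length(train_idx)
  state <- .adam_init(params)
  best <- list(loss = Inf, params = params, epoch = 0L)
  bad_epochs <- 0L
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0), val_acc = numeric(0))
  for (ep in seq_len(epochs)) {
    ord <- sample(train_idx)
    losses <- c()
    i <- 1L
    while (i <= n_train) {
      j <- min(i + batch_size - 1L, n_train)
      g <- grad_fun(params, ord[i:j])
      losses <- c(losses, g$loss)
      upd <- .adam_step(params, g$grads, state, learning_rate)
      params <- upd$params
      state <- upd$state
      i <- j + 1L
    }
    if (n_val > 0L) {
      ev <- eval_fun(params, val_idx)
    } else {
      ev <- list(loss = mean(losses), acc = NA_real_)
    }
    history <- rbind(history, data.frame(epoch = ep, train_loss = mean(losses),
                                         val_loss = ev$loss, val_acc = ev$acc))
    if (verbose) {
      message(sprintf("epoch %3d  train loss %.4f  val loss %.4f  val acc %s",
                      ep, mean(losses), ev$loss,
                      ifelse(is.na(ev$acc), "-", sprintf("%.3f", ev$acc))))
    }
    if (!is.finite(mean(losses))) {
      stop("training diverged (non-finite loss) at epoch ", ep,
           "; try a smaller learning rate")
    }
    if (ev$loss < best$loss - 1e-6) {
      best <- list(loss = ev$loss, params = params, epoch = ep)
      bad_epochs <- 0L
    } else {
      bad_epochs <- bad_epochs + 1L
      if (bad_epochs >= patience) break
    }
  }
  list(params = best$params, history = history, best_epoch = best$epoch)
}
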