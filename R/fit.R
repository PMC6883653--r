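#' Build a balanced orientation training set
#'
#' Training sources provide sequences of known orientation. After
#' canonicalizing every record to forward (records labeled `REVERSE` are
#' reverse-complemented first), a balanced two-class set is created:
#' with `double = FALSE`, a seeded random half of the sequences (exactly
#' `floor(n/2)`) is reverse-complemented and labeled 1 ("not 5'-to-3'"),
#' the rest keep label 0; with `double = TRUE`, all n originals (label 0)
#' plus all n reverse complements (label 1) are used, 2n examples in total.
#' The output order is shuffled with the seed.
#'
#' @param records a labeled read table, or a character vector of sequences
#'   (then assumed forward).
#' @param double reverse-complement every sequence in addition to keeping it,
#'   doubling the training input.
#' @param seed integer seed driving the selection and the shuffle.
#' @return a `data.frame` with columns `read_id`, `seq`, `y` (0 = forward,
#'   1 = reverse complement).
#' @export
make_balanced_training_set <- function(records, double = FALSE, seed = NULL) {
  if (is.character(records)) {
    ids <- if (is.null(names(records))) paste0("seq", seq_along(records)) else names(records)
    records <- seq_records(ids, records, label = .FWD)
  }
  n <- nrow(records)
  if (!n) stop("empty input: no sequences to build a training set from")
  seqs <- records$seq
  lab <- records$label
  if (anyNA(lab)) stop("all records must be labeled to build a training set")
  rev_in <- lab == .REV
  if (any(rev_in)) seqs[rev_in] <- reverse_complement(seqs[rev_in])
  if (!is.null(seed)) set.seed(seed)
  if (double) {
    out <- data.frame(read_id = c(records$read_id, paste0(records$read_id, "_rc")),
                      seq = c(seqs, reverse_complement(seqs)),
                      y = rep(c(0L, 1L), each = n),
                      stringsAsFactors = FALSE)
  } else {
    flip <- sample.int(n, n %/% 2L)
    y <- integer(n)
    y[flip] <- 1L
    seqs[flip] <- reverse_complement(seqs[flip])
    out <- data.frame(read_id = records$read_id, seq = seqs, y = y,
                      stringsAsFactors = FALSE)
  }
  out <- out[sample.int(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Fit a read-orientation classifier
#'
#' Trains one of the two orientation models on sequences of known
#' orientation. The `"mlp"` model is a multilayer perceptron with five
#' ReLU hidden layers and a single sigmoid output unit, fed the normalized
#' k-mer frequency vector of the whole read ([kmer_features()]); its score
#' approximates the probability that a read is *not* in 5'-to-3'
#' orientation. The `"cnn"` model is a LeNet-style convolutional network
#' (three convolution + max-pooling blocks, three dense layers, softmax
#' head over the two orientations) fed one-hot encoded 500-nt sliding
#' windows ([seq_windows()]); every window of a training sequence inherits
#' the sequence label, and at prediction time per-window posteriors are
#' averaged per read.
#'
#' When `y` is omitted, a balanced training set is constructed with
#' [make_balanced_training_set()] (half the sequences reverse-complemented,
#' or all of them when `double = TRUE`). Training uses Adam with
#' mini-batches, an internal validation split and early stopping with
#' best-weight restore.
#'
#' @param x labeled read table, or character vector of sequences. When `y`
#'   is supplied, `x` is taken as-is (no balancing) and `y` gives the class
#'   of each sequence.
#' @param y optional labels: 0/1 (1 = reverse complement) or
#'   `"FORWARD"`/`"REVERSE"`.
#' @param model `"mlp"` or `"cnn"`.
#' @param k_max largest k-mer order for the MLP features (default 5).
#' @param window,stride sliding-window geometry for the CNN (defaults 500/250).
#' @param double passed to [make_balanced_training_set()].
#' @param hidden MLP hidden layer sizes (five layers).
#' @param conv_filters,conv_widths,pool CNN convolution block sizes; the
#'   first entry of `conv_filters` (default 32) is the number of first-layer
#'   filters available for motif extraction.
#' @param filter_init first-layer initialization: `"kmer"` (default) seeds
#'   the filters as detectors of the hexamers whose frequencies differ most
#'   between the two orientation classes of the training set, which makes
#'   gradient motif discovery tractable at small training sizes; `"random"`
#'   uses He initialization throughout.
#' @param dense CNN dense layer sizes before the 2-unit softmax.
#' @param dropout dropout rate on hidden/dense layers.
#' @param epochs,batch_size,learning_rate,validation_split,patience
#'   optimization settings.
#' @param seed integer seed driving balancing, weight initialization,
#'   shuffling and dropout.
#' @param verbose print per-epoch progress.
#' @return an object of class `c("orient_mlp"|"orient_cnn", "orient_fit")`
#'   with components `params` (weights), `history` (per-epoch losses),
#'   `config`, and the featurization spec. The label convention is fixed:
#'   the score is the probability that the input is not in 5'-to-3'
#'   orientation, and a read with score strictly greater than 0.5 is
#'   predicted to be in the wrong orientation.
#' @seealso [predict.orient_fit()], [evaluate_orientation()],
#'   [save_model()]
#' @examples
#' set.seed(1)
#' tx <- simulate_transcripts(60, length_range = c(300, 600),
#'                            motif_density = 0.02, seed = 1)
#' fit <- orient_fit(tx, model = "mlp", k_max = 3, epochs = 10, seed = 1)
#' predict(fit, tx$seq[1:3])
#' @export
orient_fit <- function(x, y = NULL,
                       model = c("mlp", "cnn"),
                       k_max = 5L, window = 500L, stride = 250L,
                       double = FALSE,
                       hidden = c(512L, 256L, 128L, 64L, 32L),
                       conv_filters = c(32L, 64L, 128L),
                       conv_widths = c(19L, 11L, 7L),
                       pool = c(4L, 4L, 4L),
                       dense = c(256L, 64L),
                       filter_init = c("kmer", "random"),
                       dropout = 0.2,
                       epochs = if (match.arg(model) == "mlp") 100L else 15L,
                       batch_size = 128L, learning_rate = 1e-3,
                       validation_split = 0.1, patience = 5L,
                       seed = 1L, verbose = FALSE) {
  model <- match.arg(model)
  filter_init <- match.arg(filter_init)
  cl <- match.call()
  if (is.null(y)) {
    ts <- make_balanced_training_set(x, double = double, seed = seed)
    seqs <- ts$seq
    y <- ts$y
  } else {
    seqs <- if (is.data.frame(x)) x$seq else x
    if (is.character(y)) {
      if (!all(y %in% c(.FWD, .REV))) stop("labels must be FORWARD or REVERSE")
      y <- as.integer(y == .REV)
    }
    y <- as.integer(y)
    if (length(y) != length(seqs)) stop("x and y lengths differ")
  }
  if (length(unique(y)) < 2L || min(table(y)) < 2L) {
    stop("need at least 2 training examples in each orientation class")
  }
  config <- list(model = model, k_max = as.integer(k_max),
                 window = as.integer(window), stride = as.integer(stride),
                 double = double, hidden = as.integer(hidden),
                 conv_filters = as.integer(conv_filters),
                 conv_widths = as.integer(conv_widths),
                 pool = as.integer(pool), dense = as.integer(dense),
                 filter_init = filter_init,
                 dropout = dropout, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 validation_split = validation_split,
                 patience = as.integer(patience), seed = as.integer(seed))

  if (model == "mlp") {
    if (length(hidden) != 5L) stop("the MLP has exactly 5 hidden layers")
    X <- t(kmer_features(seqs, k_max = k_max))   # d x n
    set.seed(seed)
    params <- mlp_init_params(nrow(X), hidden)
    fit <- nn_train_loop(
      params,
      grad_fun = function(p, idx) mlp_grad(p, X[, idx, drop = FALSE], y[idx],
                                           dropout = dropout),
      eval_fun = function(p, idx) mlp_eval(p, X[, idx, drop = FALSE], y[idx]),
      n = length(y), epochs = epochs, batch_size = batch_size,
      learning_rate = learning_rate, validation_split = validation_split,
      patience = patience, seed = seed, verbose = verbose)
    obj <- list(params = fit$params, arch = list(n_in = nrow(X), hidden = hidden),
                history = fit$history, config = config,
                n_train = length(y), call = cl,
                label_convention = "score = P(read not in 5'-to-3' orientation); flip iff score > 0.5")
    class(obj) <- c("orient_mlp", "orient_fit")
    return(obj)
  }

  # CNN: expand sequences to windows, windows inherit the sequence label
  if (length(conv_filters) != 3L || length(pool) != 3L || length(dense) != 2L) {
    stop("the CNN has 3 convolutional, 3 pooling and 3 dense layers")
  }
  win_list <- lapply(seqs, seq_windows, window = window, stride = stride)
  wy <- rep(y, lengths(win_list))
  Xw <- one_hot_batch(unlist(win_list), window = window)
  arch <- cnn_arch(window, conv_filters, conv_widths, pool, dense)
  set.seed(seed)
  params <- cnn_init_params(arch)
  if (identical(filter_init, "kmer")) {
    params <- cnn_seed_filters(params, arch, seqs, y)
  }
  fit <- nn_train_loop(
    params,
    grad_fun = function(p, idx) cnn_grad(p, arch, Xw[, idx, drop = FALSE],
                                         wy[idx], dropout = dropout),
    eval_fun = function(p, idx) cnn_eval(p, arch, Xw[, idx, drop = FALSE], wy[idx]),
    n = length(wy), epochs = epochs, batch_size = batch_size,
    learning_rate = learning_rate, validation_split = validation_split,
    patience = patience, seed = seed, verbose = verbose)
  obj <- list(params = fit$params, arch = arch, history = fit$history,
              config = config, n_train = length(y), n_windows = length(wy),
              call = cl,
              label_convention = "score = P(read not in 5'-to-3' orientation); flip iff score > 0.5")
  class(obj) <- c("orient_cnn", "orient_fit")
  obj
}

#' Predict read orientation
#'
#' Scores reads with a fitted orientation model. The score is the
#' probability that a read is *not* in 5'-to-3' orientation; a read is
#' called `REVERSE` iff its score is strictly greater than `threshold`
#' (a score exactly at the threshold is called `FORWARD`). For the CNN,
#' every 500-nt window of a read is scored and the per-window posteriors
#' are averaged independently for each orientation; the read score is the
#' mean reverse posterior. Reads that cannot be featurized (MLP: shorter
#' than `k_max` or containing non-ACGT symbols) get an `NA` score
#' (undecided).
#'
#' @param object a fitted model from [orient_fit()] or [load_model()].
#' @param newdata a read table, a character vector of sequences, or (MLP
#'   only) a precomputed k-mer feature matrix with the exact expected number
#'   of columns.
#' @param type `"score"` (numeric vector), `"label"`
#'   (`FORWARD`/`REVERSE`, `NA` when undecided), or `"posterior"`
#'   (n x 2 matrix with columns `forward`, `reverse`; for the CNN these are
#'   the window-averaged posteriors).
#' @param threshold decision threshold (default 0.5, strict inequality).
#' @param batch_size prediction batch size (CNN).
#' @param ... unused.
#' @return see `type`.
#' @export
predict.orient_fit <- function(object, newdata,
                               type = c("score", "label", "posterior"),
                               threshold = 0.5, batch_size = 512L, ...) {
  type <- match.arg(type)
  scores <- orient_scores(object, newdata, batch_size = batch_size)
  post <- attr(scores, "posterior")
  attr(scores, "posterior") <- NULL
  switch(type,
         score = scores,
         label = {
           lab <- ifelse(scores > threshold, .REV, .FWD)
           names(lab) <- names(scores)
           lab
         },
         posterior = post)
}

# internal: per-read scores; attribute "posterior" holds the n x 2 matrix
orient_scores <- function(object, newdata, batch_size = 512L) {
  UseMethod("orient_scores")
}

#' @export
orient_scores.orient_mlp <- function(object, newdata, batch_size = 512L) {
  if (is.matrix(newdata) && is.numeric(newdata)) {
    if (ncol(newdata) != object$arch$n_in) {
      stop("feature matrix has ", ncol(newdata), " columns but the model was ",
           "fit with k_max = ", object$config$k_max, " (", object$arch$n_in,
           " features)")
    }
    p <- mlp_forward(object$params, t(newdata))$p
    names(p) <- rownames(newdata)
    attr(p, "posterior") <- cbind(forward = 1 - p, reverse = p)
    return(p)
  }
  seqs <- if (is.data.frame(newdata)) newdata$seq else newdata
  ids <- if (is.data.frame(newdata)) newdata$read_id else names(seqs)
  ok <- nchar(seqs) >= object$config$k_max & !grepl("[^ACGT]", seqs)
  p <- rep(NA_real_, length(seqs))
  if (any(ok)) {
    X <- kmer_features(seqs[ok], k_max = object$config$k_max)
    p[ok] <- mlp_forward(object$params, t(X))$p
  }
  names(p) <- ids
  attr(p, "posterior") <- cbind(forward = 1 - p, reverse = p)
  p
}

#' @export
orient_scores.orient_cnn <- function(object, newdata, batch_size = 512L) {
  seqs <- if (is.data.frame(newdata)) newdata$seq else newdata
  ids <- if (is.data.frame(newdata)) newdata$read_id else names(seqs)
  ok <- nzchar(seqs) & !grepl("[^ACGTN]", seqs)
  post <- matrix(NA_real_, length(seqs), 2L,
                 dimnames = list(ids, c("forward", "reverse")))
  if (any(ok)) {
    win_list <- lapply(seqs[ok], seq_windows, window = object$config$window,
                       stride = object$config$stride)
    Xw <- one_hot_batch(unlist(win_list), window = object$config$window)
    S <- cnn_predict(object$params, object$arch, Xw, batch_size = batch_size)
    grp <- rep(seq_along(win_list), lengths(win_list))
    post[ok, 1L] <- as.vector(tapply(S[1L, ], grp, mean))
    post[ok, 2L] <- as.vector(tapply(S[2L, ], grp, mean))
  }
  p <- post[, 2L]
  names(p) <- ids
  attr(p, "posterior") <- post
  p
}

#' @export
print.orient_fit <- function(x, ...) {
  kind <- if (inherits(x, "orient_mlp")) "multilayer perceptron" else
    "convolutional network"
  cat("Read-orientation model (", kind, ")\n", sep = "")
  if (inherits(x, "orient_mlp")) {
    cat("  features: k-mer frequencies, k = 1..", x$config$k_max,
        " (", x$arch$n_in, " features)\n", sep = "")
    cat("  hidden layers:", paste(x$config$hidden, collapse = ", "), "\n")
  } else {
    cat("  features: one-hot ", x$config$window, "-nt windows, stride ",
        x$config$stride, "\n", sep = "")
    cat("  conv filters:", paste(x$config$conv_filters, collapse = ", "),
        " widths:", paste(x$config$conv_widths, collapse = ", "), "\n")
  }
  cat("  trained on", x$n_train, "sequences")
  if (!is.null(x$n_windows)) cat(" (", x$n_windows, " windows)", sep = "")
  cat("\n  ", x$label_convention, "\n", sep = "")
  invisible(x)
}

#' @export
summary.orient_fit <- function(object, ...) {
  h <- object$history
  out <- list(model = class(object)[1], config = object$config,
              n_train = object$n_train,
              epochs_run = nrow(h),
              final_val_loss = h$val_loss[nrow(h)],
              final_val_acc = h$val_acc[nrow(h)],
              n_params = sum(vapply(object$params, length, 0L)))
  class(out) <- "summary.orient_fit"
  out
}

#' @export
print.summary.orient_fit <- function(x, ...) {
  cat("Model:", x$model, "| parameters:", x$n_params,
      "| training sequences:", x$n_train, "\n")
  cat(sprintf("Epochs run: %d; final validation loss %.4f, accuracy %.3f\n",
              x$epochs_run, x$final_val_loss, x$final_val_acc))
  invisible(x)
}

#' @export
coef.orient_fit <- function(object, ...) object$params

#' Plot training history
#'
#' @param x a fitted orientation model.
#' @param ... passed to [plot()].
#' @export
plot.orient_fit <- function(x, ...) {
  h <- x$history
  plot(h$epoch, h$train_loss, type = "l", xlab = "epoch", ylab = "loss",
       ylim = range(c(h$train_loss, h$val_loss), finite = TRUE), ...)
  lines(h$epoch, h$val_loss, lty = 2)
  legend("topright", c("training", "validation"), lty = c(1, 2), bty = "n")
  invisible(x)
}

#' Save / load a fitted orientation model
#'
#' A model is saved as a directory holding `weights.rds` (the fitted object,
#' R-native serialization) and `model.json`, a plain-text sidecar recording
#' the model kind, featurization spec, configuration, label convention and
#' package version. [load_model()] refuses directories whose sidecar and
#' weights disagree (e.g. MLP weights declared as a CNN).
#'
#' @param object a fitted model.
#' @param path directory to create/read.
#' @return `load_model()` returns the fitted model; `save_model()` returns
#'   `path` invisibly.
#' @export
save_model <- function(object, path) {
  stopifnot(inherits(object, "orient_fit"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  saveRDS(object, file.path(path, "weights.rds"))
  kind <- if (inherits(object, "orient_mlp")) "mlp" else "cnn"
  sidecar <- list(kind = kind, config = object$config,
                  label_convention = object$label_convention,
                  n_train = object$n_train,
                  package = "readorient",
                  package_version = as.character(utils::packageVersion("readorient")),
                  r_version = as.character(getRversion()))
  jsonlite::write_json(sidecar, file.path(path, "model.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  wfile <- file.path(path, "weights.rds")
  jfile <- file.path(path, "model.json")
  if (!file.exists(wfile) || !file.exists(jfile)) {
    stop("'", path, "' is not a saved model directory (weights.rds/model.json missing)")
  }
  sidecar <- jsonlite::read_json(jfile, simplifyVector = TRUE)
  object <- readRDS(wfile)
  if (!inherits(object, "orient_fit")) stop("weights.rds does not hold a fitted model")
  kind <- if (inherits(object, "orient_mlp")) "mlp" else "cnn"
  if (!identical(sidecar$kind, kind)) {
    stop("model kind mismatch: sidecar says '", sidecar$kind,
         "' but weights are a ", kind, " model")
  }
  want <- if (kind == "mlp") "W1" else "Wc1"
  if (!want %in% names(object$params)) {
    stop("weights do not match the declared '", kind, "' architecture")
  }
  object
}
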