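test_that("balanced training sets have exact class counts and seeded determinism", {
  set.seed(51)
  recs <- seq_records(paste0("r", 1:10), replicate(10, random_seq(60)),
                      label = "FORWARD")
  ts <- make_balanced_training_set(recs, double = FALSE, seed = 3)
  expect_equal(nrow(ts), 10L)
  expect_equal(sum(ts$y == 1), 5L)
  expect_equal(sum(ts$y == 0), 5L)
  # label-1 entries are exact reverse complements of their originals
  for (i in which(ts$y == 1)) {
    orig <- recs$seq[match(ts$read_id[i], recs$read_id)]
    expect_identical(ts$seq[i], reverse_complement(orig))
  }
  # no sequence appears with both labels when double = FALSE
  expect_false(any(duplicated(ts$read_id)))

  ts2 <- make_balanced_training_set(recs, double = FALSE, seed = 3)
  expect_identical(ts, ts2)

  dbl <- make_balanced_training_set(recs, double = TRUE, seed = 3)
  expect_equal(nrow(dbl), 20L)
  expect_equal(sum(dbl$y == 1), 10L)

  # REVERSE-labeled inputs are canonicalized to forward before balancing
  rev_recs <- recs
  rev_recs$label <- "REVERSE"
  tsr <- make_balanced_training_set(rev_recs, double = TRUE, seed = 3)
  fwd <- tsr$seq[tsr$y == 0]
  expect_setequal(fwd, reverse_complement(recs$seq))

  expect_error(make_balanced_training_set(recs[0, ]), "empty")
})

test_that("training requires two classes and a minimum of examples", {
  seqs <- replicate(6, random_seq(60))
  expect_error(orient_fit(seqs, y = rep(0, 6), model = "mlp", k_max = 2),
               "each orientation class")
  expect_error(orient_fit(seqs, y = c(1, 0, 0, 0, 0, 0), model = "mlp",
                          k_max = 2),
               "each orientation class")
})

test_that("MLP training learns a planted-motif signal and scores are probabilities", {
  tx <- simulate_transcripts(150, length_range = c(300, 600),
                             motif_density = 0.02, seed = 52)
  fit <- orient_fit(tx, model = "mlp", k_max = 3,
                    hidden = c(64, 32, 16, 8, 8), epochs = 40,
                    batch_size = 32, patience = 15, seed = 1)
  reads <- simulate_reads(simulate_transcripts(60, length_range = c(300, 600),
                                               motif_density = 0.02, seed = 53),
                          revcomp_prob = 0.5, seed = 54)
  s <- predict(fit, reads)
  expect_true(all(s >= 0 & s <= 1))
  m <- evaluate_orientation(fit, reads)
  expect_gt(m$accuracy, 0.7)
  # anti-symmetry: reverse-complemented reads score higher on average
  expect_gt(mean(s[reads$label == "REVERSE"]),
            mean(s[reads$label == "FORWARD"]))
  # no trivial collapse: mean training score near 1/2 on balanced input
  ts <- make_balanced_training_set(tx, seed = 1)
  expect_gt(mean(predict(fit, ts$seq)), 0.35)
  expect_lt(mean(predict(fit, ts$seq)), 0.65)
})

test_that("MLP architecture is fixed at five hidden layers", {
  seqs <- replicate(8, random_seq(60))
  expect_error(orient_fit(seqs, y = rep(0:1, 4), model = "mlp", k_max = 2,
                          hidden = c(8, 8)),
               "5 hidden layers")
})

test_that("CNN posteriors sum to one for any input", {
  tx <- simulate_transcripts(30, length_range = c(250, 600),
                             motif_density = 0.02, seed = 55)
  fit <- orient_fit(tx, model = "cnn", epochs = 2, batch_size = 32, seed = 1)
  post <- predict(fit, tx, type = "posterior")
  expect_equal(unname(rowSums(post)), rep(1, nrow(post)), tolerance = 1e-6)
  # window posterior averaging: read score equals mean over its windows
  s <- predict(fit, tx$seq[1])
  expect_equal(unname(s), unname(post[1, "reverse"]))
})

test_that("models round-trip through save/load with bitwise-equal scores", {
  tx <- simulate_transcripts(40, length_range = c(250, 400),
                             motif_density = 0.02, seed = 56)
  fit <- orient_fit(tx, model = "mlp", k_max = 2, hidden = c(16, 8, 8, 4, 4),
                    epochs = 5, seed = 1)
  dir <- withr::local_tempdir()
  save_model(fit, file.path(dir, "m"))
  expect_true(file.exists(file.path(dir, "m", "model.json")))
  loaded <- load_model(file.path(dir, "m"))
  probes <- replicate(100, random_seq(80))
  expect_identical(predict(fit, probes), predict(loaded, probes))

  # sidecar/weights kind mismatch is an explicit error
  side <- jsonlite::read_json(file.path(dir, "m", "model.json"))
  side$kind <- "cnn"
  jsonlite::write_json(side, file.path(dir, "m", "model.json"),
                       auto_unbox = TRUE)
  expect_error(load_model(file.path(dir, "m")), "mismatch")

  # feature-dimension guard: k_max=2 model refuses k_max=1 features
  X_wrong <- kmer_features(probes[1:3], k_max = 1)
  expect_error(predict(fit, X_wrong), "k_max")
  expect_error(load_model(file.path(dir, "missing")), "not a saved model")
})

test_that("backprop gradients match numerical differentiation", {
  ns <- asNamespace("readorient")
  set.seed(57)
  # biases set away from zero to avoid the ReLU kink in the finite difference
  arch <- ns$cnn_arch(40L, c(3L, 4L, 5L), c(5L, 3L, 3L), c(2L, 2L, 2L),
                      c(8L, 4L))
  params <- ns$cnn_init_params(arch)
  params <- lapply(params, function(p) p + stats::rnorm(length(p), sd = 0.05))
  n <- 6
  X <- matrix(0, 160, n)
  for (j in seq_len(n)) {
    idx <- sample(1:4, 40, replace = TRUE)
    X[cbind(4 * (0:39) + idx, j)] <- 1
  }
  y <- sample(0:1, n, replace = TRUE)
  g <- ns$cnn_grad(params, arch, X, y)
  eps <- 1e-6
  for (nm in names(params)) {
    for (k in sample(seq_along(params[[nm]]), min(3, length(params[[nm]])))) {
      p2 <- params; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- params; p3[[nm]][k] <- p3[[nm]][k] - eps
      num <- (ns$cnn_grad(p2, arch, X, y)$loss -
                ns$cnn_grad(p3, arch, X, y)$loss) / (2 * eps)
      expect_equal(g$grads[[nm]][k], num, tolerance = 1e-4)
    }
  }

  pm <- ns$mlp_init_params(10L, c(6L, 5L, 4L, 3L, 3L))
  pm <- lapply(pm, function(p) p + stats::rnorm(length(p), sd = 0.05))
  Xm <- matrix(runif(10 * 8), 10, 8)
  ym <- sample(0:1, 8, replace = TRUE)
  gm <- ns$mlp_grad(pm, Xm, ym)
  for (nm in names(pm)) {
    for (k in sample(seq_along(pm[[nm]]), min(3, length(pm[[nm]])))) {
      p2 <- pm; p2[[nm]][k] <- p2[[nm]][k] + eps
      p3 <- pm; p3[[nm]][k] <- p3[[nm]][k] - eps
      num <- (ns$mlp_grad(p2, Xm, ym)$loss -
                ns$mlp_grad(p3, Xm, ym)$loss) / (2 * eps)
      expect_equal(gm$grads[[nm]][k], num, tolerance = 1e-4)
    }
  }
})
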