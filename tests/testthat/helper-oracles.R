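# Independent brute-force oracles used to check the package implementations.

# naive reverse complement via explicit character map
naive_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# naive sliding-window k-mer frequency vector for one sequence
naive_kmer_vector <- function(s, k_max) {
  L <- nchar(s)
  unlist(lapply(seq_len(k_max), function(k) {
    kmers <- kmer_names(k)
    obs <- substring(s, seq_len(L - k + 1), seq_len(L - k + 1) + k - 1)
    counts <- table(factor(obs, levels = kmers))
    as.numeric(counts) / (L - k + 1)
  }))
}

# brute-force window start enumeration: start at 0, step by stride, emit a
# start iff it is 0 or strictly before L - stride; right-pad with N
naive_windows <- function(s, window = 500L, stride = 250L) {
  L <- nchar(s)
  starts <- 0L
  st <- stride
  while (st < L - stride) {
    starts <- c(starts, st)
    st <- st + stride
  }
  vapply(starts, function(a) {
    w <- substr(s, a + 1L, min(a + window, L))
    paste0(w, strrep("N", window - nchar(w)))
  }, "")
}

# brute-force confusion-matrix metrics, REVERSE = positive class
naive_metrics <- function(truth, pred) {
  tp <- sum(truth == "REVERSE" & pred == "REVERSE")
  fp <- sum(truth == "FORWARD" & pred == "REVERSE")
  fn <- sum(truth == "REVERSE" & pred == "FORWARD")
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f,
       accuracy = mean(truth == pred))
}

# brute-force majority vote: > 50% forward keeps/sets forward, else reverse
naive_vote <- function(labels) {
  if (mean(labels == "FORWARD") > 0.5) rep("FORWARD", length(labels))
  else rep("REVERSE", length(labels))
}

# random ACGT sequence
random_seq <- function(L) paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
                                collapse = "")
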