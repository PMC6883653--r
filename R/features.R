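#' Reverse complement
#'
#' Vectorized reverse complement over the alphabet A, C, G, T, N (N maps to
#' N). Any other symbol is an error.
#'
#' @param x character vector of sequences.
#' @return character vector of reverse complements.
#' @export
reverse_complement <- function(x) {
  if (!length(x)) return(character(0))
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop("unknown symbol in sequence ", which(bad)[1],
         "; expected only A, C, G, T, N")
  }
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' All k-mers of order k in feature (lexicographic) order
#'
#' @param k k-mer length.
#' @return character vector of the 4^k k-mers over A < C < G < T.
#' @export
kmer_names <- function(k) {
  stopifnot(k >= 1)
  do.call(paste0, expand.grid(rep(list(c("A", "C", "G", "T")), k))[
    , k:1, drop = FALSE])
}

#' Normalized k-mer frequency vectors
#'
#' Featurizes sequences as the concatenation, over k = 1..`k_max`, of
#' normalized overlapping k-mer counts: for a sequence of length L, each
#' k-mer count is divided by the total number of k-mers of that order,
#' L - k + 1, so every order-k block of the vector sums to 1. With
#' `k_max = 5` the vector has 4 + 16 + ... + 1024 = 1364 entries. This gives
#' a fixed-size input for reads of any length and keeps values in [0, 1].
#'
#' @param seqs character vector of sequences over A, C, G, T (preprocess
#'   first: no N allowed).
#' @param k_max largest k-mer order (default 5).
#' @return numeric matrix, one row per sequence, columns named by k-mer in
#'   lexicographic order within each k block.
#' @export
kmer_features <- function(seqs, k_max = 5L) {
  stopifnot(k_max >= 1)
  if (!length(seqs)) stop("no sequences to featurize")
  len <- nchar(seqs)
  if (any(len < k_max)) {
    stop(sum(len < k_max), " sequence(s) shorter than k_max = ", k_max,
         "; filter them out (see preprocess_reads) before featurizing")
  }
  if (any(grepl("[^ACGT]", seqs))) {
    stop("sequences must contain only A, C, G, T; run preprocess_reads first")
  }
  dss <- Biostrings::DNAStringSet(seqs)
  blocks <- lapply(seq_len(k_max), function(k) {
    counts <- Biostrings::oligonucleotideFrequency(dss, width = k)
    counts / (len - k + 1)
  })
  out <- do.call(cbind, blocks)
  colnames(out) <- unlist(lapply(seq_len(k_max), kmer_names))
  rownames(out) <- names(seqs)
  out
}

#' Sliding windows for the convolutional model
#'
#' Splits a sequence into overlapping windows of `window` nt starting every
#' `stride` nt (defaults 500 and 250, i.e. 250 nt overlap). Any window
#' extending past the end of the sequence -- including the single window of a
#' sequence shorter than `window` -- is right-padded with N to full width. A
#' start position s > 0 is emitted only while s < L - stride, so no window
#' consists solely of already-covered bases.
#'
#' @param seq a single sequence string.
#' @param window window width in nt.
#' @param stride distance between window starts in nt.
#' @return character vector of windows, each exactly `window` characters.
#' @export
seq_windows <- function(seq, window = 500L, stride = 250L) {
  stopifnot(length(seq) == 1L, nzchar(seq), stride >= 1, window > stride)
  L <- nchar(seq)
  n_win <- if (L <= window) 1L else 1L + as.integer(ceiling((L - window) / stride))
  starts <- stride * (seq_len(n_win) - 1L)
  w <- substring(seq, starts + 1L, pmin(starts + window, L))
  short <- nchar(w) < window
  w[short] <- paste0(w[short], strrep("N", window - nchar(w[short])))
  w
}

#' One-hot encode a window
#'
#' @param window sequence string over A, C, G, T, N.
#' @return a 4 x nchar(window) binary matrix with rows A, C, G, T; N columns
#'   are all zero.
#' @export
one_hot <- function(window) {
  stopifnot(length(window) == 1L)
  chars <- strsplit(window, "", fixed = TRUE)[[1]]
  idx <- match(chars, c("A", "C", "G", "T"))
  if (any(is.na(idx) & chars != "N")) {
    stop("unexpected symbol '", chars[which(is.na(idx) & chars != "N")[1]],
         "' in window")
  }
  m <- matrix(0, 4L, length(chars), dimnames = list(c("A", "C", "G", "T"), NULL))
  ok <- !is.na(idx)
  m[cbind(idx[ok], which(ok))] <- 1
  m
}

# Batch one-hot encoding in the transposed layout used by the network:
# (4 * window) x n_windows, base-fastest within position.
one_hot_batch <- function(windows, window = 500L) {
  n <- length(windows)
  m <- matrix(0, 4L * window, n)
  if (!n) return(m)
  codes <- vapply(windows, utf8ToInt, integer(window), USE.NAMES = FALSE)
  # codes: window x n matrix of char codes
  lut <- integer(128)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  base <- lut[codes]                      # 0 for N/anything else
  ok <- which(base > 0L)
  pos <- (ok - 1L) %% window              # 0-based position within window
  col <- (ok - 1L) %/% window             # 0-based window index
  m[cbind(4L * pos + base[ok], col + 1L)] <- 1
  m
}
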