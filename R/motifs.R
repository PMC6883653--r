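#' Collect filter-activating subsequences from a CNN model
#'
#' Scans probe sequences with the first convolutional layer of a fitted CNN
#' and, for every filter, collects the input subsequence aligned with each
#' strictly positive pre-pooling activation (after the bias, before pooling
#' -- the only stage where per-position alignment to the input exists).
#' Subsequences overlapping N padding are skipped.
#'
#' @param object a fitted CNN model ([orient_fit()] with `model = "cnn"`).
#' @param seqs character vector of probe sequences (or a read table).
#' @param batch_size windows scored per batch.
#' @return a named list, one character vector of filter-width subsequences
#'   per first-layer filter (`filter_1`, `filter_2`, ...).
#' @export
collect_activated_subsequences <- function(object, seqs, batch_size = 256L) {
  if (!inherits(object, "orient_cnn")) {
    stop("motif extraction requires a CNN model (no convolutional filters in an MLP)")
  }
  if (is.data.frame(seqs)) seqs <- seqs$seq
  window <- object$config$window
  w <- object$arch$conv[[1L]]$w
  n_filters <- object$arch$conv[[1L]]$F
  windows <- unlist(lapply(seqs, seq_windows, window = window,
                           stride = object$config$stride))
  sites <- rep(list(character(0)), n_filters)
  names(sites) <- paste0("filter_", seq_len(n_filters))
  i <- 1L
  while (i <= length(windows)) {
    j <- min(i + batch_size - 1L, length(windows))
    batch <- windows[i:j]
    Xw <- one_hot_batch(batch, window = window)
    act <- cnn_forward(object$params, object$arch, Xw, conv_only = 1L)
    P <- act$P
    Z <- act$Z                         # n_filters x (P * n_batch)
    hits <- which(Z > 0, arr.ind = TRUE)
    if (nrow(hits)) {
      f <- hits[, 1L]
      win <- (hits[, 2L] - 1L) %/% P + 1L
      pos <- (hits[, 2L] - 1L) %% P + 1L
      sub <- substr(batch[win], pos, pos + w - 1L)
      clean <- !grepl("N", sub, fixed = TRUE)
      if (any(clean)) {
        f <- f[clean]; sub <- sub[clean]
        for (k in unique(f)) {
          sites[[k]] <- c(sites[[k]], sub[f == k])
        }
      }
    }
    i <- j + 1L
  }
  sites
}

#' Convert collected subsequences to position weight matrices
#'
#' For each filter, the aligned activating subsequences are stacked and the
#' per-position base frequencies form a position weight matrix:
#' `column_j = (counts_j + pseudocount) / (n_sites + 4 * pseudocount)`.
#' Filters with no contributing subsequence are dropped (with a message).
#'
#' @param sites a named list of equal-length subsequences per filter, as
#'   returned by [collect_activated_subsequences()].
#' @param pseudocount nonnegative pseudocount added to every cell (default
#'   0, i.e. raw conversion).
#' @return an object of class `pwm_set`: a list of elements with `id`,
#'   `matrix` (4 x width, rows A, C, G, T, columns summing to 1) and
#'   `nsites`.
#' @export
filters_to_pwms <- function(sites, pseudocount = 0) {
  stopifnot(pseudocount >= 0)
  empty <- lengths(sites) == 0L
  if (any(empty)) {
    message(sum(empty), " filter(s) with no positive activation dropped: ",
            paste(names(sites)[empty], collapse = ", "))
  }
  sites <- sites[!empty]
  if (!length(sites)) stop("no filter produced any activating subsequence")
  pwms <- lapply(seq_along(sites), function(i) {
    s <- sites[[i]]
    w <- nchar(s[1])
    stopifnot(all(nchar(s) == w))
    m <- matrix(0, 4L, w, dimnames = list(c("A", "C", "G", "T"), NULL))
    chars <- matrix(unlist(strsplit(s, "", fixed = TRUE), use.names = FALSE),
                    nrow = length(s), byrow = TRUE)
    for (j in seq_len(w)) {
      cnt <- table(factor(chars[, j], levels = c("A", "C", "G", "T")))
      m[, j] <- (as.numeric(cnt) + pseudocount) /
        (length(s) + 4 * pseudocount)
    }
    list(id = names(sites)[i], matrix = m, nsites = length(s))
  })
  names(pwms) <- names(sites)
  class(pwms) <- "pwm_set"
  pwms
}

#' @export
print.pwm_set <- function(x, ...) {
  cat("Set of", length(x), "position weight matrices\n")
  for (p in x) {
    consensus <- paste(rownames(p$matrix)[apply(p$matrix, 2L, which.max)],
                       collapse = "")
    cat(sprintf("  %-12s width %2d  nsites %6d  consensus %s\n",
                p$id, ncol(p$matrix), p$nsites, consensus))
  }
  invisible(x)
}

#' Write motifs in MEME minimal format
#'
#' Writes a `pwm_set` as a MEME minimal motif file (version line, ACGT
#' alphabet, background frequencies, one MOTIF block per PWM with its
#' letter-probability matrix, width and nsites), consumable by motif
#' comparison tools such as TOMTOM.
#'
#' @param pwms a `pwm_set` ([filters_to_pwms()]).
#' @param path output file path.
#' @param background background base frequencies (A, C, G, T); default
#'   uniform.
#' @return `path`, invisibly.
#' @export
write_meme <- function(pwms, path, background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25)) {
  stopifnot(inherits(pwms, "pwm_set"), length(pwms) > 0,
            length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               sprintf("A %.5f C %.5f G %.5f T %.5f",
                       background[1], background[2], background[3], background[4]),
               ""), con)
  for (p in pwms) {
    writeLines(sprintf("MOTIF %s", p$id), con)
    writeLines(sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d E= 0",
                       ncol(p$matrix), p$nsites), con)
    writeLines(apply(p$matrix, 2L, function(col)
      paste(sprintf("%.8f", col), collapse = " ")), con)
    writeLines("", con)
  }
  invisible(path)
}

#' Read motifs from a MEME minimal format file
#'
#' Parses the subset of the MEME minimal motif format written by
#' [write_meme()] back into a `pwm_set`.
#'
#' @param path path to a MEME motif file.
#' @return a `pwm_set`.
#' @export
read_meme <- function(path) {
  lines <- readLines(path)
  motif_at <- grep("^MOTIF\\s", lines)
  if (!length(motif_at)) stop("no MOTIF blocks found in ", path)
  pwms <- lapply(motif_at, function(i) {
    id <- sub("^MOTIF\\s+(\\S+).*$", "\\1", lines[i])
    hdr <- lines[i + 1L]
    if (!grepl("^letter-probability matrix:", hdr)) {
      stop("MOTIF ", id, ": missing letter-probability matrix header")
    }
    w <- as.integer(sub(".*w=\\s*(\\d+).*", "\\1", hdr))
    nsites <- if (grepl("nsites=", hdr)) {
      as.integer(sub(".*nsites=\\s*(\\d+).*", "\\1", hdr))
    } else NA_integer_
    rows <- lines[(i + 2L):(i + 1L + w)]
    vals <- lapply(strsplit(trimws(rows), "\\s+"), as.numeric)
    m <- t(do.call(rbind, vals))
    rownames(m) <- c("A", "C", "G", "T")
    list(id = id, matrix = m, nsites = nsites)
  })
  names(pwms) <- vapply(pwms, `[[`, "", "id")
  class(pwms) <- "pwm_set"
  pwms
}
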