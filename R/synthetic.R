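#' Default planted motif set
#'
#' Ten fixed hexamers used as the default strand-asymmetric signal in the
#' synthetic transcript generator. None is palindromic and no motif's
#' reverse complement is in the set, so forward and reverse-complement
#' strands are statistically distinguishable. `AATAAA` (the canonical
#' polyadenylation signal) is included for domain flavor.
#'
#' @return character vector of 10 hexamers.
#' @export
orient_default_motifs <- function() {
  c("GAGGAG", "TTGTGT", "CCAGCA", "AATAAA", "TGGACT",
    "CACCCA", "GTTGCA", "AGGTAA", "TCCGAT", "GATGAG")
}

#' Simulate forward-strand transcripts with planted motifs
#'
#' Generates synthetic "transcripts": random background sequence with
#' strand-specific motifs planted on the forward strand at a configurable
#' density, and an optional poly-A tail. All records are labeled `FORWARD`.
#' Motif insertions overwrite background bases (length stays exact) and
#' overlapping insertions are rejected by resampling. Deterministic given
#' the seed.
#'
#' @param n number of transcripts.
#' @param length_range c(min, max) transcript length in nt (uniform);
#'   minimum 250.
#' @param composition background base probabilities (A, C, G, T), summing
#'   to 1.
#' @param motifs character vector of motifs (k-mers, k 4-8) planted on the
#'   forward strand; [orient_default_motifs()] by default.
#' @param motif_density expected insertions per nt (default 0.01, i.e. one
#'   per 100 nt); the count per transcript is Poisson(`motif_density * L`).
#'   Set 0 to disable (null data).
#' @param polya_mean mean length of the geometric poly-A tail appended at
#'   the 3' end; 0 (default) disables the tail.
#' @param seed integer seed.
#' @return a read table (all labels `FORWARD`) with a `cluster_id` column
#'   equal to the transcript id; the `"motif_positions"` attribute lists
#'   planted (start, end) pairs per transcript.
#' @export
simulate_transcripts <- function(n, length_range = c(500L, 2000L),
                                 composition = c(A = 0.25, C = 0.25,
                                                 G = 0.25, T = 0.25),
                                 motifs = orient_default_motifs(),
                                 motif_density = 0.01, polya_mean = 0,
                                 seed = NULL) {
  stopifnot(n >= 1, length(length_range) == 2L, length_range[1] >= 250,
            length_range[1] <= length_range[2], length(composition) == 4L,
            all(composition >= 0), abs(sum(composition) - 1) < 1e-8,
            motif_density >= 0, polya_mean >= 0)
  if (motif_density > 0 && !length(motifs)) {
    stop("motif_density > 0 requires a non-empty motif set")
  }
  if (length(motifs) && any(nchar(motifs) < 4 | nchar(motifs) > 8)) {
    stop("planted motifs must be k-mers with k in 4..8")
  }
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  seqs <- character(n)
  positions <- vector("list", n)
  for (i in seq_len(n)) {
    L <- sample(length_range[1]:length_range[2], 1L)
    s <- sample(bases, L, replace = TRUE, prob = composition)
    placed <- matrix(integer(0), ncol = 2L)
    if (motif_density > 0) {
      n_mot <- rpois(1L, motif_density * L)
      attempts <- 0L
      while (nrow(placed) < n_mot && attempts < 50L * max(n_mot, 1L)) {
        attempts <- attempts + 1L
        m <- motifs[sample.int(length(motifs), 1L)]
        k <- nchar(m)
        start <- sample.int(L - k + 1L, 1L)
        if (nrow(placed) == 0L ||
            all(start > placed[, 2L] | (start + k - 1L) < placed[, 1L])) {
          s[start:(start + k - 1L)] <- strsplit(m, "")[[1]]
          placed <- rbind(placed, c(start, start + k - 1L))
        }
      }
    }
    seq_i <- paste(s, collapse = "")
    if (polya_mean > 0) {
      tail_len <- rgeom(1L, 1 / (1 + polya_mean))
      if (tail_len > 0) seq_i <- paste0(seq_i, strrep("A", tail_len))
    }
    seqs[i] <- seq_i
    positions[[i]] <- placed
  }
  ids <- sprintf("tx_%05d", seq_len(n))
  out <- seq_records(ids, seqs, label = .FWD)
  out$cluster_id <- ids
  names(positions) <- ids
  attr(out, "motif_positions") <- positions
  out
}

#' Simulate sequencing reads from transcripts
#'
#' Turns transcripts into noisy reads: each read is optionally 5'-truncated
#' (mimicking internal priming), passed through a substitution /
#' single-base insertion / single-base deletion error channel, and finally
#' reverse-complemented with probability `revcomp_prob`. The truth label of
#' the emitted read is `FORWARD` if it was not flipped, else `REVERSE`.
#' `transcript_id` records the source molecule; `cluster_id` groups reads of
#' one molecule *and* one emitted strand, mimicking strand-specific
#' similarity clustering of unoriented reads (reads of opposite strands do
#' not co-cluster, so a cluster shares one true orientation). Deterministic
#' given the seed.
#'
#' @param transcripts a read table from [simulate_transcripts()].
#' @param reads_per_transcript a single count, or c(min, max) to sample a
#'   cluster size uniformly per transcript.
#' @param sub_rate,ins_rate,del_rate per-base event probabilities;
#'   substitutions draw uniformly from the 3 alternative bases, indels have
#'   length 1.
#' @param truncate_prob probability that a read is 5'-truncated.
#' @param truncate_mean mean of the geometric truncation length.
#' @param revcomp_prob probability a read is emitted as the reverse
#'   complement (default 0.5).
#' @param seed integer seed.
#' @return a read table with truth `label`, `cluster_id`, and an
#'   `"events"` attribute (`data.frame` of per-read substitution /
#'   insertion / deletion counts and pre-error length).
#' @export
simulate_reads <- function(transcripts, reads_per_transcript = 1L,
                           sub_rate = 0, ins_rate = 0, del_rate = 0,
                           truncate_prob = 0, truncate_mean = 200,
                           revcomp_prob = 0.5, seed = NULL) {
  stopifnot(sub_rate >= 0, ins_rate >= 0, del_rate >= 0,
            sub_rate + ins_rate + del_rate < 1,
            truncate_prob >= 0, truncate_prob <= 1,
            revcomp_prob >= 0, revcomp_prob <= 1)
  if (!is.null(seed)) set.seed(seed)
  n_tx <- nrow(transcripts)
  n_per <- if (length(reads_per_transcript) == 2L) {
    sample(reads_per_transcript[1]:reads_per_transcript[2], n_tx, replace = TRUE)
  } else rep_len(as.integer(reads_per_transcript), n_tx)
  src <- rep(seq_len(n_tx), n_per)
  n_reads <- length(src)
  bases <- c("A", "C", "G", "T")
  seqs <- character(n_reads)
  ev <- matrix(0L, n_reads, 4L,
               dimnames = list(NULL, c("sub", "ins", "del", "base_len")))
  for (r in seq_len(n_reads)) {
    s <- transcripts$seq[src[r]]
    if (truncate_prob > 0 && runif(1) < truncate_prob) {
      cut <- min(rgeom(1L, 1 / (1 + truncate_mean)), nchar(s) - 50L)
      if (cut > 0) s <- substr(s, cut + 1L, nchar(s))
    }
    b <- strsplit(s, "", fixed = TRUE)[[1]]
    L <- length(b)
    ev[r, "base_len"] <- L
    if (sub_rate + ins_rate + del_rate > 0) {
      u <- runif(L)
      is_sub <- u < sub_rate
      is_del <- !is_sub & u < sub_rate + del_rate
      is_ins <- !is_sub & !is_del & u < sub_rate + del_rate + ins_rate
      ev[r, "sub"] <- sum(is_sub)
      ev[r, "del"] <- sum(is_del)
      ev[r, "ins"] <- sum(is_ins)
      if (any(is_sub)) {
        alt <- vapply(b[is_sub],
                      function(x) sample(setdiff(bases, x), 1L), "",
                      USE.NAMES = FALSE)
        b[is_sub] <- alt
      }
      if (any(is_ins)) {
        b[is_ins] <- paste0(b[is_ins],
                            sample(bases, sum(is_ins), replace = TRUE))
      }
      if (any(is_del)) b[is_del] <- ""
      s <- paste(b, collapse = "")
    }
    seqs[r] <- s
  }
  flip <- runif(n_reads) < revcomp_prob
  seqs[flip] <- reverse_complement(seqs[flip])
  ids <- sprintf("read_%06d", seq_len(n_reads))
  out <- seq_records(ids, seqs, label = ifelse(flip, .REV, .FWD))
  out$transcript_id <- transcripts$read_id[src]
  # similarity clustering of unoriented reads is strand-specific: reads of
  # the same molecule but opposite emitted strands do not co-cluster, so a
  # cluster is (molecule, emitted strand) and shares one true orientation
  out$cluster_id <- paste0(out$transcript_id, ifelse(flip, "_r", "_f"))
  attr(out, "events") <- data.frame(read_id = ids, ev)
  out
}

#' Write the truth table for simulated reads
#'
#' Writes a tab-separated table `read_id`, `label`, `cluster_id` (with
#' header) consumable by [orientation_metrics()] and the cluster-vote
#' functions.
#'
#' @param records a read table carrying `label` (and optionally
#'   `cluster_id`).
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_truth <- function(records, path) {
  stopifnot(all(records$label %in% c(.FWD, .REV)))
  cl <- if ("cluster_id" %in% names(records)) records$cluster_id else NA_character_
  df <- data.frame(read_id = records$read_id, label = records$label,
                   cluster_id = cl, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a cluster assignment table
#'
#' Writes `cluster_id <tab> read_id` lines (no header), the format read
#' back by [parse_clusters()].
#'
#' @param records a read table with a `cluster_id` column.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_clusters <- function(records, path) {
  stopifnot("cluster_id" %in% names(records))
  writeLines(paste(records$cluster_id, records$read_id, sep = "\t"), path)
  invisible(path)
}
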