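#' Construct a read table
#'
#' The package represents reads and transcripts as a plain `data.frame` with
#' columns `read_id`, `seq`, `qual` (NA when absent), `desc` (header text
#' after the id token, NA when absent) and `label` (orientation,
#' `"FORWARD"`/`"REVERSE"`, NA when unknown).
#'
#' @param read_id character vector of identifiers (first header token).
#' @param seq character vector of nucleotide sequences.
#' @param qual optional character vector of per-base quality strings.
#' @param desc optional character vector of header descriptions.
#' @param label optional orientation labels (`"FORWARD"`/`"REVERSE"`).
#' @return a `data.frame` with one row per read.
#' @export
seq_records <- function(read_id, seq, qual = NA_character_, desc = NA_character_,
                        label = NA_character_) {
  n <- length(seq)
  stopifnot(length(read_id) == n)
  qual <- rep_len(as.character(qual), n)
  desc <- rep_len(as.character(desc), n)
  label <- rep_len(as.character(label), n)
  bad <- !is.na(label) & !label %in% c(.FWD, .REV)
  if (any(bad)) stop("labels must be FORWARD or REVERSE")
  qlen_bad <- !is.na(qual) & nchar(qual) != nchar(seq)
  if (any(qlen_bad)) {
    stop("quality string length differs from sequence length for record '",
         read_id[which(qlen_bad)[1]], "'")
  }
  data.frame(read_id = as.character(read_id), seq = as.character(seq),
             qual = qual, desc = desc, label = label,
             stringsAsFactors = FALSE)
}

#' Read sequences from FASTA or FASTQ
#'
#' Reads a FASTA or FASTQ file into a read table. Sequences are uppercased
#' and uracil (U) is converted to thymine (T) unconditionally, so direct-RNA
#' reads and DNA reads come out on the same alphabet. File order is
#' preserved. Malformed FASTQ records (quality string length differing from
#' the sequence length) raise an error naming the record.
#'
#' @param path path to a FASTA or FASTQ file.
#' @param format `"auto"` (detect from the first byte, `>` vs `@`),
#'   `"fasta"`, or `"fastq"`.
#' @return a read table as produced by [seq_records()]; FASTQ input fills the
#'   `qual` column.
#' @seealso [preprocess_reads()], [write_oriented()]
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    first <- readChar(path, 1L, useBytes = TRUE)
    format <- switch(first, ">" = "fasta", "@" = "fastq",
                     stop("cannot auto-detect format of '", path,
                          "': first byte is not '>' or '@'"))
  }
  parsed <- tryCatch({
    x <- Biostrings::readBStringSet(path, format = format,
                                    with.qualities = (format == "fastq"))
    qual <- if (format == "fastq") {
      as.character(S4Vectors::mcols(x)$qualities)
    } else NA_character_
    list(seqs = as.character(x), headers = names(x), qual = qual)
  }, error = function(e) {
    if (format == "fastq") .diagnose_fastq(path)
    stop("failed to parse ", format, " file '", path,
         "': ", conditionMessage(e), call. = FALSE)
  })
  headers <- parsed$headers
  if (is.null(headers)) headers <- paste0("seq", seq_along(parsed$seqs))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers),
                 NA_character_)
  seqs <- toupper(chartr("uU", "tT", parsed$seqs))
  qual <- parsed$qual
  if (format == "fastq") {
    qbad <- nchar(qual) != nchar(seqs)
    if (any(qbad)) {
      stop("malformed FASTQ record '", ids[which(qbad)[1]],
           "': quality length ", nchar(qual)[which(qbad)[1]],
           " != sequence length ", nchar(seqs)[which(qbad)[1]])
    }
  }
  seq_records(ids, seqs, qual = qual, desc = desc)
}

#' Filter and trim reads before featurization
#'
#' Drops reads containing any base other than A, C, G or T (in particular
#' any N), then removes `trim` bases from both ends of each surviving
#' sequence, then drops reads shorter than `min_len`. Discard counts are
#' attached as the `"discards"` attribute.
#'
#' @param records a read table ([seq_records()]).
#' @param trim number of bases removed from each end (same on both sides).
#' @param min_len minimum post-trim length kept. The default 50 avoids
#'   degenerate k-mer feature vectors.
#' @return the filtered read table, with attribute `discards`, a named
#'   integer vector with elements `input`, `ambiguous`, `too_short`, `kept`.
#' @export
preprocess_reads <- function(records, trim = 0L, min_len = 50L) {
  stopifnot(trim >= 0, min_len >= 1)
  n_in <- nrow(records)
  clean <- !grepl("[^ACGT]", records$seq)
  n_amb <- sum(!clean)
  out <- records[clean, , drop = FALSE]
  if (trim > 0 && nrow(out)) {
    len <- nchar(out$seq)
    out$seq <- substr(out$seq, trim + 1L, pmax(len - trim, 0L))
    has_q <- !is.na(out$qual)
    out$qual[has_q] <- substr(out$qual[has_q], trim + 1L,
                              pmax(len[has_q] - trim, 0L))
  }
  long_enough <- nchar(out$seq) >= min_len
  n_short <- sum(!long_enough)
  out <- out[long_enough, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "discards") <- c(input = n_in, ambiguous = n_amb,
                             too_short = n_short, kept = nrow(out))
  out
}

#' Derive orientation labels from a PAF alignment
#'
#' Parses a minimap2-style PAF file (>= 12 tab-separated columns; query name
#' in column 1, strand in column 5, MAPQ in column 12) and labels each read
#' from the strand of its transcript match: `+` means the read is already in
#' the transcript's 5'-to-3' orientation (`FORWARD`), `-` means it is the
#' reverse complement (`REVERSE`). A read is labeled only if it has exactly
#' one PAF record (when `require_unique`) and MAPQ >= `min_mapq`.
#'
#' @param paf_path path to a PAF file.
#' @param min_mapq minimum mapping quality kept; the default 60 is
#'   minimap2's maximum, selecting unambiguous assignments.
#' @param require_unique drop reads with more than one alignment record.
#'   When `FALSE`, the first record passing the MAPQ filter is used.
#' @return a named character vector (`read_id` -> label) with attribute
#'   `excluded`: a named integer vector with counts `multimapping` and
#'   `low_mapq`.
#' @export
parse_paf_labels <- function(paf_path, min_mapq = 60L, require_unique = TRUE) {
  stopifnot(min_mapq >= 0, min_mapq <= 60)
  lines <- readLines(paf_path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    out <- character(0)
    attr(out, "excluded") <- c(multimapping = 0L, low_mapq = 0L)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 12L)) {
    stop("PAF line ", which(nf < 12L)[1], " has ", nf[nf < 12L][1],
         " fields; at least 12 required")
  }
  qname <- vapply(fields, `[[`, "", 1L)
  strand <- vapply(fields, `[[`, "", 5L)
  ok_strand <- strand %in% c("+", "-")
  if (!all(ok_strand)) {
    stop("PAF line ", which(!ok_strand)[1], ": unknown strand symbol '",
         strand[!ok_strand][1], "'")
  }
  mapq <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 12L)))
  if (anyNA(mapq)) stop("PAF line ", which(is.na(mapq))[1], ": MAPQ not an integer")

  counts <- table(qname)
  multi <- names(counts)[counts > 1L]
  n_multi <- 0L
  if (require_unique) {
    n_multi <- length(multi)
    keep <- !(qname %in% multi)
  } else {
    keep <- !duplicated(qname)   # primary (first) record per read
  }
  pass_mapq <- mapq >= min_mapq
  n_low <- length(unique(qname[keep & !pass_mapq]))
  sel <- keep & pass_mapq
  labels <- ifelse(strand[sel] == "+", .FWD, .REV)
  names(labels) <- qname[sel]
  attr(labels, "excluded") <- c(multimapping = n_multi, low_mapq = n_low)
  labels
}

#' Build a labeled dataset from one of the three source kinds
#'
#' Training and test sets come from three kinds of sources: `annotation`
#' (reference transcript sequences, by definition in 5'-to-3' orientation),
#' `experimental` (reads whose protocol guarantees orientation, e.g.
#' direct-RNA sequencing, also 5'-to-3'), and `mapped` (reads whose
#' orientation was determined independently by mapping; requires the PAF
#' file of that mapping, labels derived with [parse_paf_labels()], unlabeled
#' reads dropped).
#'
#' @param seq_path FASTA/FASTQ file of sequences.
#' @param source one of `"annotation"`, `"experimental"`, `"mapped"`.
#' @param paf_path PAF file; required when `source = "mapped"`.
#' @param min_mapq,require_unique passed to [parse_paf_labels()].
#' @return a labeled read table; attribute `labeling` carries counts of
#'   dropped (unlabeled) reads for mapped sources.
#' @export
build_labeled_dataset <- function(seq_path,
                                  source = c("annotation", "experimental", "mapped"),
                                  paf_path = NULL, min_mapq = 60L,
                                  require_unique = TRUE) {
  source <- match.arg(source)
  records <- read_sequences(seq_path)
  if (source %in% c("annotation", "experimental")) {
    records$label <- .FWD
    attr(records, "labeling") <- c(labeled = nrow(records), dropped = 0L)
    return(records)
  }
  if (is.null(paf_path)) {
    stop("source = \"mapped\" requires a PAF file (paf_path)")
  }
  labels <- parse_paf_labels(paf_path, min_mapq = min_mapq,
                             require_unique = require_unique)
  hit <- match(records$read_id, names(labels))
  keep <- !is.na(hit)
  out <- records[keep, , drop = FALSE]
  out$label <- unname(labels[hit[keep]])
  rownames(out) <- NULL
  attr(out, "labeling") <- c(labeled = nrow(out), dropped = sum(!keep))
  attr(out, "excluded") <- attr(labels, "excluded")
  out
}

#' Write reads in their predicted orientation
#'
#' Reads scored above the decision threshold (the score is the probability
#' that a read is *not* in 5'-to-3' orientation) are written
#' reverse-complemented, with the quality string reversed when present.
#' Headers gain `ro_score=<s> ro_flipped=<0|1>` after the id token; the id
#' token itself is preserved.
#'
#' @param records a read table.
#' @param scores numeric vector, one score per record; `NA` scores are
#'   treated as undecided and written unchanged with `ro_flipped=0`.
#' @param out_path output file path.
#' @param format `"auto"` (FASTQ iff all records carry qualities),
#'   `"fasta"`, or `"fastq"`.
#' @param threshold decision threshold; a read is flipped iff
#'   `score > threshold` (strict).
#' @return invisibly, a logical vector saying which records were flipped.
#' @export
write_oriented <- function(records, scores, out_path,
                           format = c("auto", "fasta", "fastq"),
                           threshold = 0.5) {
  format <- match.arg(format)
  if (length(scores) != nrow(records)) {
    stop("need exactly one score per record")
  }
  if (format == "auto") {
    format <- if (nrow(records) > 0 && !anyNA(records$qual)) "fastq" else "fasta"
  }
  flip <- !is.na(scores) & scores > threshold
  seqs <- records$seq
  seqs[flip] <- reverse_complement(seqs[flip])
  quals <- records$qual
  if (any(flip)) {
    quals[flip & !is.na(quals)] <- .reverse_string(quals[flip & !is.na(quals)])
  }
  score_txt <- ifelse(is.na(scores), "NA", format(scores, digits = 6, trim = TRUE))
  hdr <- paste0(records$read_id, " ro_score=", score_txt,
                " ro_flipped=", as.integer(flip),
                ifelse(is.na(records$desc), "", paste0(" ", records$desc)))
  con <- file(out_path, "w")
  on.exit(close(con))
  if (format == "fasta") {
    writeLines(paste0(">", hdr, "\n", seqs), con, sep = "\n")
  } else {
    if (anyNA(quals)) {
      quals[is.na(quals)] <- strrep("I", nchar(seqs[is.na(quals)]))
    }
    writeLines(paste0("@", hdr, "\n", seqs, "\n+\n", quals), con, sep = "\n")
  }
  invisible(flip)
}

#' Write a read table as FASTA or FASTQ
#'
#' Plain sequence writer (no orientation annotation); see [write_oriented()]
#' for writing prediction results.
#'
#' @param records a read table.
#' @param path output file path.
#' @param format `"auto"` (FASTQ iff all records carry qualities),
#'   `"fasta"`, or `"fastq"`.
#' @return `path`, invisibly.
#' @export
write_sequences <- function(records, path, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (nrow(records) > 0 && !anyNA(records$qual)) "fastq" else "fasta"
  }
  hdr <- paste0(records$read_id,
                ifelse(is.na(records$desc), "", paste0(" ", records$desc)))
  if (format == "fasta") {
    writeLines(paste0(">", hdr, "\n", records$seq), path)
  } else {
    quals <- records$qual
    quals[is.na(quals)] <- strrep("I", nchar(records$seq[is.na(quals)]))
    writeLines(paste0("@", hdr, "\n", records$seq, "\n+\n", quals), path)
  }
  invisible(path)
}

# Pinpoints the offending record when the FASTQ reader fails, so parse
# errors can name the record instead of surfacing a low-level message.
.diagnose_fastq <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n_rec <- length(lines) %/% 4L
  for (i in seq_len(n_rec)) {
    blk <- lines[(4L * (i - 1L) + 1L):(4L * i)]
    id <- sub("^@", "", sub("\\s.*$", "", blk[1]))
    if (!startsWith(blk[1], "@") || !startsWith(blk[3], "+")) {
      stop("malformed FASTQ record '", id, "' (record ", i,
           "): missing '@' or '+' line", call. = FALSE)
    }
    if (nchar(blk[4]) != nchar(blk[2])) {
      stop("malformed FASTQ record '", id, "': quality length ",
           nchar(blk[4]), " != sequence length ", nchar(blk[2]),
           call. = FALSE)
    }
  }
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ file '", path, "': truncated final record",
         call. = FALSE)
  }
  invisible(NULL)
}

.reverse_string <- function(x) {
  vapply(x, function(s) intToUtf8(rev(utf8ToInt(s))), "", USE.NAMES = FALSE)
}
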