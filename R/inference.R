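#' Precision, recall and F1 for orientation calls
#'
#' Computes the confusion matrix of predicted vs true orientation labels and
#' the derived metrics, treating `REVERSE` as the positive class (the event
#' the model scores). Macro-averaged precision/recall/F1 over the two
#' classes are also reported. Degenerate cases (no positive prediction, no
#' positive label) yield 0 with a flag rather than NaN.
#'
#' @param truth character vector of true labels (`FORWARD`/`REVERSE`).
#' @param predicted character vector of predicted labels; `NA` entries
#'   (undecided reads) are excluded from the metrics and counted.
#' @return an object of class `orient_metrics`: a list with `precision`,
#'   `recall`, `f1`, `accuracy`, `macro_precision`, `macro_recall`,
#'   `macro_f1`, `n_reads`, `n_undecided`, `confusion` (2x2 table) and
#'   `degenerate` (logical).
#' @export
orientation_metrics <- function(truth, predicted) {
  stopifnot(length(truth) == length(predicted))
  if (!length(truth)) stop("no labeled records to evaluate")
  ok <- !is.na(predicted) & !is.na(truth)
  n_und <- sum(!ok)
  truth <- truth[ok]
  predicted <- predicted[ok]
  if (!length(truth)) stop("no decided predictions to evaluate")
  stopifnot(all(truth %in% c(.FWD, .REV)), all(predicted %in% c(.FWD, .REV)))
  tp <- sum(predicted == .REV & truth == .REV)
  fp <- sum(predicted == .REV & truth == .FWD)
  fn <- sum(predicted == .FWD & truth == .REV)
  tn <- sum(predicted == .FWD & truth == .FWD)
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) tp / (tp + fp) else 0
    r <- if (tp + fn > 0) tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p, r, f)
  }
  pos <- prf(tp, fp, fn)
  neg <- prf(tn, fn, fp)   # FORWARD as positive: swaps fp/fn roles
  conf <- matrix(c(tp, fn, fp, tn), 2L, 2L,
                 dimnames = list(predicted = c(.REV, .FWD),
                                 truth = c(.REV, .FWD)))
  out <- list(precision = pos[1], recall = pos[2], f1 = pos[3],
              accuracy = (tp + tn) / length(truth),
              macro_precision = mean(c(pos[1], neg[1])),
              macro_recall = mean(c(pos[2], neg[2])),
              macro_f1 = mean(c(pos[3], neg[3])),
              n_reads = length(truth), n_undecided = n_und,
              confusion = conf,
              degenerate = (tp + fp == 0) || (tp + fn == 0))
  class(out) <- "orient_metrics"
  out
}

#' @export
print.orient_metrics <- function(x, ...) {
  cat(sprintf("Orientation metrics on %d reads (positive class: REVERSE)\n",
              x$n_reads))
  cat(sprintf("  precision %.4f  recall %.4f  F1 %.4f  accuracy %.4f\n",
              x$precision, x$recall, x$f1, x$accuracy))
  cat(sprintf("  macro: precision %.4f  recall %.4f  F1 %.4f\n",
              x$macro_precision, x$macro_recall, x$macro_f1))
  if (x$n_undecided > 0) cat("  undecided (excluded):", x$n_undecided, "\n")
  if (x$degenerate) cat("  note: degenerate confusion matrix; undefined ratios reported as 0\n")
  print(x$confusion)
  invisible(x)
}

#' Evaluate a model on labeled reads (test mode)
#'
#' Predicts the orientation of labeled reads and compares predictions with
#' the labels, returning precision (proportion of the predictions that are
#' correct), recall (true positive rate), the F1 score (harmonic mean of
#' the two), and the total number of input reads.
#'
#' @param object a fitted orientation model.
#' @param records a labeled read table.
#' @param threshold decision threshold (strict inequality).
#' @return an [orientation_metrics()] object.
#' @export
evaluate_orientation <- function(object, records, threshold = 0.5) {
  if (!nrow(records)) stop("no records to evaluate")
  if (anyNA(records$label)) stop("all records must be labeled in test mode")
  pred <- predict(object, records, type = "label", threshold = threshold)
  orientation_metrics(records$label, pred)
}

#' Per-group prediction accuracy
#'
#' Tabulates the fraction of correct orientation calls within groups of
#' reads (e.g. transcript types from an annotation, or read clusters).
#' Reads not covered by `groups` are reported under `"ungrouped"`. Groups
#' with `n <= min_n` reads are suppressed from the main table (returned in
#' the `"suppressed"` attribute); the default `min_n = 10` keeps only
#' groups with more than 10 reads.
#'
#' @param truth,predicted label vectors, aligned; names or `read_ids` give
#'   read identifiers.
#' @param groups named character vector `read_id -> group`.
#' @param read_ids read identifiers (defaults to `names(truth)`).
#' @param min_n suppression threshold.
#' @return a `data.frame` with columns `group`, `n`, `accuracy`, ordered by
#'   decreasing n.
#' @export
metrics_by_group <- function(truth, predicted, groups = character(0),
                             read_ids = names(truth), min_n = 10L) {
  stopifnot(length(truth) == length(predicted))
  if (is.null(read_ids)) read_ids <- as.character(seq_along(truth))
  g <- unname(groups[match(read_ids, names(groups))])
  g[is.na(g)] <- "ungrouped"
  correct <- !is.na(predicted) & predicted == truth
  tab <- data.frame(group = unique(g), stringsAsFactors = FALSE)
  tab$n <- vapply(tab$group, function(x) sum(g == x), 0L)
  tab$accuracy <- vapply(tab$group, function(x) mean(correct[g == x]), 0)
  tab <- tab[order(-tab$n, tab$group), , drop = FALSE]
  rownames(tab) <- NULL
  small <- tab$n <= min_n
  out <- tab[!small, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "suppressed") <- tab[small, , drop = FALSE]
  out
}

#' Predict and write oriented reads (predict mode)
#'
#' Scores unlabeled reads, applies the decision rule (flip iff score
#' strictly greater than `threshold`), optionally writes the oriented
#' sequences ([write_oriented()]) and a predictions TSV
#' (`read_id`, `score`, `predicted_label`, `flipped`).
#'
#' @param object a fitted orientation model.
#' @param records a read table.
#' @param out_path optional path for the oriented FASTA/FASTQ.
#' @param tsv_path optional path for the predictions TSV.
#' @param threshold decision threshold.
#' @param format output sequence format, see [write_oriented()].
#' @return a `data.frame` (`read_id`, `score`, `predicted_label`,
#'   `flipped`) with attribute `counts` = c(flipped, kept, undecided).
#' @export
predict_orientations <- function(object, records, out_path = NULL,
                                 tsv_path = NULL, threshold = 0.5,
                                 format = "auto") {
  if (!nrow(records)) {
    warning("empty input: no reads to orient")
    res <- data.frame(read_id = character(0), score = numeric(0),
                      predicted_label = character(0), flipped = integer(0))
    if (!is.null(out_path)) file.create(out_path)
    if (!is.null(tsv_path)) {
      write.table(res, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    attr(res, "counts") <- c(flipped = 0L, kept = 0L, undecided = 0L)
    return(res)
  }
  scores <- predict(object, records, type = "score", threshold = threshold)
  flip <- !is.na(scores) & scores > threshold
  label <- ifelse(flip, .REV, .FWD)
  res <- data.frame(read_id = records$read_id, score = unname(scores),
                    predicted_label = label, flipped = as.integer(flip),
                    stringsAsFactors = FALSE)
  if (!is.null(out_path)) {
    write_oriented(records, scores, out_path, format = format,
                   threshold = threshold)
  }
  if (!is.null(tsv_path)) {
    write.table(res, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  attr(res, "counts") <- c(flipped = sum(flip),
                           kept = sum(!flip & !is.na(scores)),
                           undecided = sum(is.na(scores)))
  res
}
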