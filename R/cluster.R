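#' Parse a read-to-cluster assignment table
#'
#' Reads a two-column tab-separated table of cluster assignments, in the
#' style emitted by long-read clustering tools: `cluster_id <tab> read_id`
#' by default, or `read_id <tab> cluster_id` with `read_id_first = TRUE`.
#' Each read may belong to at most one cluster.
#'
#' @param path path to the TSV file (no header).
#' @param read_id_first column order flag.
#' @return a named character vector `read_id -> cluster_id`.
#' @export
parse_clusters <- function(path, read_id_first = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (!length(lines)) {
    warning("empty cluster file: ", path)
    return(setNames(character(0), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 2L
  if (any(bad)) {
    stop("malformed cluster line ", which(bad)[1], ": expected 2 tab-separated columns")
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  reads <- if (read_id_first) a else b
  clusters <- if (read_id_first) b else a
  dup <- duplicated(reads)
  if (any(dup)) {
    stop("read '", reads[dup][1], "' assigned to more than one cluster")
  }
  setNames(clusters, reads)
}

#' Majority-vote correction of orientation calls within clusters
#'
#' Within each cluster, if the majority (strictly more than 50%) of reads
#' are predicted to be already in 5'-to-3' orientation (`FORWARD`), all
#' reads of the cluster are set to `FORWARD`; otherwise -- including an
#' exact 50/50 tie -- all reads are set to `REVERSE` (i.e. all are
#' reverse-complemented). Reads absent from the cluster assignment are
#' passed through unchanged; singleton clusters are unchanged by
#' construction.
#'
#' @param predicted character vector of per-read predicted labels
#'   (`FORWARD`/`REVERSE`), named by read id (or supply `read_ids`).
#' @param clusters named character vector `read_id -> cluster_id`
#'   ([parse_clusters()]).
#' @param read_ids read identifiers aligned with `predicted`.
#' @return corrected label vector, same order and names as `predicted`.
#' @export
majority_vote <- function(predicted, clusters, read_ids = names(predicted)) {
  if (is.null(read_ids)) stop("predicted labels must be named by read id")
  stopifnot(length(read_ids) == length(predicted),
            all(predicted %in% c(.FWD, .REV)))
  cl <- unname(clusters[match(read_ids, names(clusters))])
  out <- predicted
  in_cluster <- !is.na(cl)
  if (any(in_cluster)) {
    frac_fwd <- tapply(predicted[in_cluster] == .FWD, cl[in_cluster], mean)
    decision <- ifelse(frac_fwd > 0.5, .FWD, .REV)
    out[in_cluster] <- unname(decision[cl[in_cluster]])
  }
  names(out) <- read_ids
  out
}

#' Per-cluster accuracy profile
#'
#' For each cluster, the proportion of reads whose (raw or vote-corrected)
#' predicted orientation matches the true orientation. Clusters below the
#' size filter are dropped; the default keeps clusters with more than 2
#' reads.
#'
#' @param predicted,truth label vectors aligned with `read_ids`.
#' @param clusters named character vector `read_id -> cluster_id`.
#' @param read_ids read identifiers (default `names(predicted)`).
#' @param min_size smallest cluster size kept (default 3, i.e. > 2 reads).
#' @return a `data.frame` (`cluster`, `n`, `prop_correct`); the
#'   `"histogram"` attribute tabulates clusters by proportion correct.
#' @export
cluster_accuracy_profile <- function(predicted, truth, clusters,
                                     read_ids = names(predicted),
                                     min_size = 3L) {
  if (is.null(read_ids)) stop("predicted labels must be named by read id")
  cl <- unname(clusters[match(read_ids, names(clusters))])
  keep <- !is.na(cl)
  if (anyNA(truth[keep])) stop("true labels required for all clustered reads")
  correct <- predicted[keep] == truth[keep]
  n <- tapply(correct, cl[keep], length)
  prop <- tapply(correct, cl[keep], mean)
  out <- data.frame(cluster = names(n), n = as.integer(n),
                    prop_correct = as.numeric(prop), stringsAsFactors = FALSE)
  out <- out[out$n >= min_size, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "histogram") <- table(out$prop_correct)
  out
}
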