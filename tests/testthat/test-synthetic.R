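test_that("transcript generation is deterministic and respects the config", {
  a <- simulate_transcripts(20, length_range = c(250, 500), seed = 5)
  b <- simulate_transcripts(20, length_range = c(250, 500), seed = 5)
  expect_identical(a, b)
  expect_true(all(a$label == "FORWARD"))
  expect_true(all(nchar(a$seq) >= 250 & nchar(a$seq) <= 500))
  expect_error(simulate_transcripts(5, length_range = c(100, 200)),
               "length_range")
  expect_error(simulate_transcripts(5, motif_density = 0.01, motifs = character(0)),
               "non-empty motif set")
})

test_that("planted motif counts follow the Poisson density", {
  tx <- simulate_transcripts(200, length_range = c(1000, 1001),
                             motif_density = 0.01, seed = 6)
  counts <- vapply(attr(tx, "motif_positions"), nrow, 0L)
  expect_gt(mean(counts), 8)    # ~Poisson(10)
  expect_lt(mean(counts), 12)
  # planted positions actually carry a motif from the set
  motifs <- orient_default_motifs()
  pos <- attr(tx, "motif_positions")[[1]]
  for (r in seq_len(nrow(pos))) {
    planted <- substr(tx$seq[1], pos[r, 1], pos[r, 2])
    expect_true(planted %in% motifs)
  }
  # non-overlap of planted instances
  for (i in seq_len(20)) {
    p <- attr(tx, "motif_positions")[[i]]
    if (nrow(p) > 1) {
      p <- p[order(p[, 1]), , drop = FALSE]
      expect_true(all(p[-1, 1] > p[-nrow(p), 2]))
    }
  }
})

test_that("default motif set is strand-asymmetric", {
  m <- orient_default_motifs()
  rc <- reverse_complement(m)
  expect_false(any(rc %in% m))   # includes non-palindromicity
})

test_that("without planted motifs the two strands are indistinguishable", {
  tx <- simulate_transcripts(150, length_range = c(500, 800),
                             motif_density = 0, seed = 19)
  counts_f <- colSums(Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(tx$seq)))
  counts_r <- colSums(Biostrings::trinucleotideFrequency(
    Biostrings::DNAStringSet(reverse_complement(tx$seq))))
  p <- suppressWarnings(chisq.test(rbind(counts_f, counts_r))$p.value)
  expect_gt(p, 0.01)
})

test_that("poly-A tails are appended when enabled", {
  tx <- simulate_transcripts(50, length_range = c(250, 300), motif_density = 0,
                             polya_mean = 30, seed = 7)
  tails <- vapply(tx$seq, function(s) {
    m <- regmatches(s, regexpr("A+$", s))
    if (length(m)) nchar(m) else 0L
  }, 0L, USE.NAMES = FALSE)
  expect_gt(mean(tails), 15)
})

test_that("noise-free reads are transcripts or their exact reverse complements", {
  tx <- simulate_transcripts(30, length_range = c(250, 400), seed = 8)
  reads <- simulate_reads(tx, revcomp_prob = 0.5, seed = 9)
  for (i in seq_len(nrow(reads))) {
    src <- tx$seq[match(reads$transcript_id[i], tx$read_id)]
    if (reads$label[i] == "FORWARD") {
      expect_identical(reads$seq[i], src)
    } else {
      expect_identical(reads$seq[i], reverse_complement(src))
    }
  }
})

test_that("the error channel hits the requested per-base rate", {
  tx <- simulate_transcripts(100, length_range = c(500, 1000), seed = 10)
  reads <- simulate_reads(tx, sub_rate = 0.05, ins_rate = 0.025,
                          del_rate = 0.025, revcomp_prob = 0.5, seed = 11)
  ev <- attr(reads, "events")
  rate <- sum(ev$sub + ev$ins + ev$del) / sum(ev$base_len)
  expect_gt(rate, 0.08)
  expect_lt(rate, 0.12)
})

test_that("reverse-complement probability yields balanced labels", {
  tx <- simulate_transcripts(250, length_range = c(250, 300), seed = 12)
  reads <- simulate_reads(tx, reads_per_transcript = 4, revcomp_prob = 0.5,
                          seed = 13)
  expect_equal(nrow(reads), 1000L)
  bal <- mean(reads$label == "REVERSE")
  expect_gt(bal, 0.45)
  expect_lt(bal, 0.55)
})

test_that("clusters are orientation-homogeneous and follow the source molecule", {
  tx <- simulate_transcripts(30, length_range = c(250, 300), seed = 20)
  reads <- simulate_reads(tx, reads_per_transcript = 8, revcomp_prob = 0.5,
                          seed = 21)
  # one true orientation per cluster
  per_cluster <- tapply(reads$label, reads$cluster_id,
                        function(x) length(unique(x)))
  expect_true(all(per_cluster == 1L))
  # all reads of a cluster come from the same transcript
  per_tx <- tapply(reads$transcript_id, reads$cluster_id,
                   function(x) length(unique(x)))
  expect_true(all(per_tx == 1L))
})

test_that("truth and cluster tables round-trip", {
  tx <- simulate_transcripts(10, length_range = c(250, 300), seed = 14)
  reads <- simulate_reads(tx, reads_per_transcript = c(2, 5), seed = 15)
  truth_f <- withr::local_tempfile(fileext = ".tsv")
  write_truth(reads, truth_f)
  back <- read.delim(truth_f, stringsAsFactors = FALSE)
  expect_equal(nrow(back), nrow(reads))
  expect_identical(back$label, reads$label)
  expect_true(all(back$label %in% c("FORWARD", "REVERSE")))

  cl_f <- withr::local_tempfile(fileext = ".tsv")
  write_clusters(reads, cl_f)
  cl <- parse_clusters(cl_f)
  expect_identical(unname(cl[reads$read_id]), reads$cluster_id)
})

test_that("5' truncation shortens reads from the 5' end", {
  tx <- simulate_transcripts(40, length_range = c(800, 1000), seed = 16)
  reads <- simulate_reads(tx, truncate_prob = 1, truncate_mean = 200,
                          revcomp_prob = 0, seed = 17)
  src_len <- nchar(tx$seq[match(reads$transcript_id, tx$read_id)])
  expect_true(all(nchar(reads$seq) <= src_len))
  expect_gt(mean(src_len - nchar(reads$seq)), 80)
  # truncated reads are suffixes of their transcript (3' end kept)
  keep <- nchar(reads$seq) < src_len
  i <- which(keep)[1]
  src <- tx$seq[match(reads$transcript_id[i], tx$read_id)]
  expect_identical(substr(src, nchar(src) - nchar(reads$seq[i]) + 1, nchar(src)),
                   reads$seq[i])
})
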