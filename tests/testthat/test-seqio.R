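test_that("FASTA and FASTQ parsing uppercases and converts U to T", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">r1 some desc", "acgu", ">r2", "ACGT"), fa)
  recs <- read_sequences(fa)
  expect_equal(recs$read_id, c("r1", "r2"))
  expect_equal(recs$seq, c("ACGT", "ACGT"))
  expect_equal(recs$desc, c("some desc", NA))
  expect_true(all(is.na(recs$qual)))

  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGU", "+", "IIB!"), fq)
  recs <- read_sequences(fq)
  expect_equal(recs$seq, "ACGT")
  expect_equal(recs$qual, "IIB!")
})

test_that("format auto-detection uses the first byte", {
  fa <- withr::local_tempfile(fileext = ".txt")
  writeLines(c(">x", "AAAA"), fa)
  expect_equal(read_sequences(fa)$read_id, "x")
  bad <- withr::local_tempfile()
  writeLines("#comment", bad)
  expect_error(read_sequences(bad), "auto-detect")
})

test_that("malformed FASTQ (quality shorter than sequence) errors naming the record", {
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@ok", "ACGT", "+", "IIII", "@broken", "ACGT", "+", "II"), fq)
  expect_error(read_sequences(fq), "broken")
})

test_that("preprocessing drops N reads, trims symmetrically, enforces min length", {
  recs <- seq_records(c("a", "b"), c("ACGTN", "ACGT"))
  out <- preprocess_reads(recs, trim = 0, min_len = 1)
  expect_equal(out$seq, "ACGT")
  expect_equal(unname(attr(out, "discards")["ambiguous"]), 1L)

  out <- preprocess_reads(seq_records("a", "ACGTACGT"), trim = 2, min_len = 1)
  expect_equal(out$seq, "GTAC")

  out <- preprocess_reads(seq_records("a", "ACGT"), trim = 2, min_len = 1)
  expect_equal(nrow(out), 0L)
  expect_equal(unname(attr(out, "discards")["too_short"]), 1L)

  # never increases length; counts are exact
  set.seed(11)
  recs <- seq_records(paste0("r", 1:30),
                      replicate(30, random_seq(sample(10:80, 1))))
  recs$seq[c(3, 7)] <- paste0(recs$seq[c(3, 7)], "N")
  out <- preprocess_reads(recs, trim = 5, min_len = 20)
  expect_true(all(nchar(out$seq) <= nchar(recs$seq[match(out$read_id, recs$read_id)])))
  d <- attr(out, "discards")
  expect_equal(unname(d["input"]), 30L)
  expect_equal(unname(d["ambiguous"]), 2L)
  expect_equal(unname(d["kept"] + d["ambiguous"] + d["too_short"]), 30L)
  # quality trimmed in step with sequence
  fqrec <- seq_records("q", "ACGTACGT", qual = "ABCDEFGH")
  out <- preprocess_reads(fqrec, trim = 2, min_len = 1)
  expect_equal(out$qual, "CDEF")
})

paf_line <- function(id, strand, mapq) {
  paste(id, 1000, 0, 900, strand, "tx1", 1200, 10, 910, 850, 900, mapq,
        sep = "\t")
}

test_that("PAF labeling keeps unique high-MAPQ reads and logs exclusions", {
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(paf_line("r1", "+", 60),
               paf_line("r2", "-", 30),
               paf_line("r3", "+", 60),
               paf_line("r3", "-", 60),
               paf_line("r4", "-", 60)), paf)
  labels <- parse_paf_labels(paf)
  expect_equal(labels[["r1"]], "FORWARD")
  expect_equal(labels[["r4"]], "REVERSE")
  expect_false("r2" %in% names(labels))
  expect_false("r3" %in% names(labels))
  exc <- attr(labels, "excluded")
  expect_equal(unname(exc["multimapping"]), 1L)
  expect_equal(unname(exc["low_mapq"]), 1L)
  # kept + excluded covers all distinct read ids
  expect_equal(length(labels) + sum(exc), 4L)
})

test_that("PAF parse errors carry the line number", {
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(paf_line("r1", "+", 60), "short\tline"), paf)
  expect_error(parse_paf_labels(paf), "line 2")
  writeLines(paf_line("r1", "?", 60), paf)
  expect_error(parse_paf_labels(paf), "strand")
})

test_that("labeled datasets follow the source kind", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">t1", "ACGTACGT", ">t2", "GGGGCCCC", ">t3", "ATATATAT"), fa)
  ann <- build_labeled_dataset(fa, source = "annotation")
  expect_true(all(ann$label == "FORWARD"))
  expect_equal(nrow(ann), 3L)

  # mapped: only labeled reads survive
  paf <- withr::local_tempfile(fileext = ".paf")
  writeLines(c(paf_line("t1", "+", 60), paf_line("t3", "-", 60)), paf)
  mp <- build_labeled_dataset(fa, source = "mapped", paf_path = paf)
  expect_equal(mp$read_id, c("t1", "t3"))
  expect_equal(mp$label, c("FORWARD", "REVERSE"))
  expect_error(build_labeled_dataset(fa, source = "mapped"), "PAF")

  # experimental direct-RNA input gets U converted and all-forward labels
  fq <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@d1", "ACGU", "+", "IIII"), fq)
  drs <- build_labeled_dataset(fq, source = "experimental")
  expect_equal(drs$seq, "ACGT")
  expect_equal(drs$label, "FORWARD")
})

test_that("oriented output flips high-scoring reads and round-trips", {
  recs <- seq_records(c("a", "b"), c("AACG", "ACGT"))
  out <- withr::local_tempfile(fileext = ".fa")
  write_oriented(recs, c(0.9, 0.1), out)
  back <- read_sequences(out)
  expect_equal(back$seq, c("CGTT", "ACGT"))   # a flipped, b unchanged
  expect_match(back$desc[1], "ro_flipped=1")
  expect_match(back$desc[2], "ro_flipped=0")

  # score exactly at threshold is NOT flipped (strict inequality)
  write_oriented(recs, c(0.5, 0.5), out)
  expect_equal(read_sequences(out)$seq, recs$seq)

  # FASTQ: quality string reversed on flip
  fqrec <- seq_records("q", "AACG", qual = "ABCD")
  outq <- withr::local_tempfile(fileext = ".fq")
  write_oriented(fqrec, 0.99, outq)
  bq <- read_sequences(outq)
  expect_equal(bq$seq, "CGTT")
  expect_equal(bq$qual, "DCBA")

  # round-trip with all-forward scores reproduces sequences exactly
  set.seed(5)
  many <- seq_records(paste0("r", 1:25), replicate(25, random_seq(60)))
  write_oriented(many, rep(0, 25), out)
  expect_equal(read_sequences(out)$seq, many$seq)
})
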