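test_that("FASTQ parsing handles minimal, compressed and malformed input", {
  tmp <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII"), tmp)
  rec <- read_fastq(tmp)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$id, "r1")
  expect_equal(rec$seq, "ACGT")
  expect_equal(rec$qual, "IIII")

  gz <- withr::local_tempfile(fileext = ".fq.gz")
  con <- gzfile(gz, "wb")
  writeLines(c("@r1", "ACGT", "+", "IIII"), con)
  close(con)
  expect_equal(read_fastq(gz), rec)

  bad <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2", "ACGT", "+"), bad)
  expect_error(read_fastq(bad), "line 5")

  mism <- withr::local_tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "+", "III"), mism)
  expect_error(read_fastq(mism), "mismatch")
})

test_that("FASTQ write/read round-trip is the identity and preserves counts", {
  set.seed(42)
  for (gzipped in c(FALSE, TRUE)) {
    n <- 25L
    recs <- seq_records(sprintf("read_%02d", 1:n),
                        vapply(1:n, function(i) rand_dna(sample(30:80, 1)),
                               character(1)))
    recs$qual <- vapply(nchar(recs$seq), function(k)
      paste(sample(c("I", "F", "#", "5"), k, TRUE), collapse = ""),
      character(1))
    tmp <- withr::local_tempfile(fileext = if (gzipped) ".fq.gz" else ".fq")
    write_fastq(recs, tmp)
    back <- read_fastq(tmp)
    expect_equal(back, recs)
    expect_equal(nrow(back), length(readLines(tmp)) / 4L)
  }
})

test_that("FASTA reading concatenates, preserves order and rejects duplicates", {
  tmp <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a some description", "ACGT", "ACGT"), tmp)
  rec <- read_fasta(tmp)
  expect_equal(rec$id, "a")
  expect_equal(nchar(rec$seq), 8L)

  two <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">b", "AAAA", ">a", "CCCC"), two)
  expect_equal(read_fasta(two)$id, c("b", "a"))

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "AAAA", ">a", "CCCC"), dup)
  expect_error(read_fasta(dup), "duplicate.*a")

  empty <- withr::local_tempfile(fileext = ".fa")
  writeLines(character(), empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("sequence normalisation maps to the DNA alphabet", {
  expect_equal(normalise_dna("acgu"), "ACGT")
  expect_equal(normalise_dna("ACGUxR-3"), "ACGTNNNN")
})

test_that("transcript models validate exon and CDS invariants", {
  seq30 <- strrep("ACGTA", 6)
  m <- transcript_model("t1", seq30, c(10, 20, 30))
  expect_s3_class(m, "transcript_model")
  expect_equal(length(m$exon_ends), 3L)
  expect_equal(exon_starts(m), c(1L, 11L, 21L))
  expect_error(transcript_model("t1", seq30, c(10, 30, 20)), "increasing")
  expect_error(transcript_model("t1", seq30, c(10, 20, 29)),
               "does not equal sequence length")
  expect_error(transcript_model("t1", seq30, c(10, 20, 30),
                                cds_start = 2, cds_end = 9),
               "not a multiple of 3")
})

test_that("transcript models load from FASTA plus exon table", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">tx1", strrep("ACGTA", 6)), fa)
  tab <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\texon_index\texon_end",
               "tx1\t1\t10", "tx1\t2\t20", "tx1\t3\t30"), tab)
  m <- load_transcript_model(fa, tab)
  expect_equal(m$transcript_id, "tx1")
  expect_equal(m$exon_ends, c(10L, 20L, 30L))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\texon_index\texon_end",
               "tx1\t1\t10", "tx1\t2\t20", "tx1\t3\t29"), bad)
  expect_error(load_transcript_model(fa, bad), "sequence length")
})

test_that("GTF-subset exon reader projects genomic exons to transcript coordinates", {
  gtf <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", "101", "200", ".", "+", ".",
          'gene_id "g1"; transcript_id "tx1";', sep = "\t"),
    paste("chr1", "src", "exon", "301", "350", ".", "+", ".",
          'gene_id "g1"; transcript_id "tx1";', sep = "\t")), gtf)
  tab <- read_gtf_exons(gtf, "tx1")
  expect_equal(tab$exon_end, c(100L, 150L))

  minus <- withr::local_tempfile(fileext = ".gtf")
  writeLines(c(
    paste("chr1", "src", "exon", "101", "200", ".", "-", ".",
          'gene_id "g1"; transcript_id "tx2";', sep = "\t"),
    paste("chr1", "src", "exon", "301", "350", ".", "-", ".",
          'gene_id "g1"; transcript_id "tx2";', sep = "\t")), minus)
  tab2 <- read_gtf_exons(minus, "tx2")
  expect_equal(tab2$exon_end, c(50L, 150L))  # 5' exon first on minus strand
})
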