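# The published KAT6B-KANSL1 worked example: the t(10;17)(q22;q21)
# retroperitoneal leiomyoma fusion discovered by exact search of raw FASTQ
# with an exon-boundary 20-mer. All sequences below are the published ones.

#' The KAT6B-KANSL1 worked example
#'
#' Returns the published components of the KAT6B-KANSL1 fusion discovery:
#' the 20-nt search term (the last 20 nucleotides of KAT6B exon 3, nt
#' 1303-1322 of NM_012330.3), the 101 bp chimeric read it extracted from the
#' tumour RNA-seq FASTQ, the KAT6B-matching fragment (read bases 1-43, nt
#' 1280-1322 of NM_012330.3), the KANSL1-matching fragment (read bases
#' 44-101, nt 2715-2772 of NM_015443.3), the canonical junction coordinates
#' (KAT6B nt 1322 / KANSL1 nt 2715), and the verification primer sets
#' (four KAT6B-forward/KANSL1-reverse fusion pairs, the nested reciprocal
#' KANSL1-forward/KAT6B-reverse pairs, and the MED12 expression pair whose
#' product is 163 bp).
#'
#' @return a list with elements `search_term`, `chimeric_read`,
#'   `donor_fragment`, `acceptor_fragment`, `donor_break`, `acceptor_break`,
#'   `fusion_length`, `orf_length`, `protein_length`, `fusion_primers`,
#'   `reciprocal_primers`, `med12_primers`.
#' @export
kat6b_kansl1_example <- function() {
  list(
    search_term = "TACCCCATGAGAAAGACCAG",
    chimeric_read = paste0(
      "CTCGCTCCCACCTGTCAGCCTTCTACCCCATGAGAAAGACCAG",
      "CAGCAGCCAGTAAGGAGGTGAAGGGGAGAGAGCTCATTCGATATTAACAACATTGTCA"),
    donor_fragment = "CTCGCTCCCACCTGTCAGCCTTCTACCCCATGAGAAAGACCAG",
    acceptor_fragment =
      "CAGCAGCCAGTAAGGAGGTGAAGGGGAGAGAGCTCATTCGATATTAACAACATTGTCA",
    donor_break = 1322L,
    acceptor_break = 2715L,
    fusion_length = 3667L,
    orf_length = 1398L,
    protein_length = 466L,
    fusion_primers = list(
      primer_pair("MORF-1234F/KANSL1-2969R1",
                  "GCTTAGATGGCAAAGGGGCACCTC", "GTGGCACACTCGTGGTCCACAGC"),
      primer_pair("MORF-1234F/KANSL1-2900R1",
                  "GCTTAGATGGCAAAGGGGCACCTC", "AGGCTGCGTCGGATAGGTCCTCA"),
      primer_pair("MORF-1261F/KANSL1-2969R1",
                  "ATCCCAGTGCATTCCCATCCTCG", "GTGGCACACTCGTGGTCCACAGC"),
      primer_pair("MORF-1261F/KANSL1-2900R1",
                  "ATCCCAGTGCATTCCCATCCTCG", "AGGCTGCGTCGGATAGGTCCTCA")),
    reciprocal_primers = list(
      outer = primer_pair("KANSL1-2341F1/MORF-1591R1",
                          "GGCACAAATTGGTCAGCTCCTTCCT",
                          "GAAAGTGGTGGGTCACAGCATTCCA"),
      nested = primer_pair("KANSL1-2407F1/MORF-1483R1",
                           "GGACCCACAGGCAGCACTTAGACG",
                           "CATTCGATGCACTGCCACCTTAAGG")),
    med12_primers = primer_pair("MED12-Ex1-F/MED12-Ex3-R",
                                "TTACCCTCAGGACCCCAAACAG",
                                "TGCAATAATGCTGCTGAAGTTGG"))
}

#' Mini split-alignment references for the worked example
#'
#' Builds desk-scale donor and acceptor references by embedding the two
#' published junction fragments in fixed non-extending flanks: the donor
#' reference carries the 43-nt KAT6B-matching fragment (read bases 1-43) as
#' the end of its first exon; the acceptor reference carries the 61-nt
#' chromosome-17 context (read bases 41-101 — the 58-nt KANSL1 transcript
#' fragment preceded by the 3 shared junction bases, which is what the
#' genomic locus presents). Split-aligning the 101 bp chimeric read against
#' these references places the donor-matching prefix end at read position 43
#' and the acceptor-maximal start at read position 41, i.e. a 3-base
#' junction microhomology. The flank bases adjacent to the embedded
#' fragments are chosen so exact extension stops exactly at the fragment
#' edges.
#'
#' @return list with `donor` (a [transcript_model()], boundary at the
#'   fragment end) and `partners` (a [seq_records()] with the
#'   chromosome-17-context acceptor).
#' @export
worked_example_refs <- function() {
  ex <- kat6b_kansl1_example()
  flank_l <- "GATTACAGATTACAGATTACAGATTACAGA"   # 30 nt
  flank_r <- "TTGACCTTGACCTTGACCTTGACCTTGACC"   # 30 nt, starts T != read[44]
  donor_seq <- paste0(flank_l, ex$donor_fragment, flank_r)
  donor <- transcript_model(
    "KAT6B_mini", donor_seq,
    exon_ends = c(nchar(flank_l) + nchar(ex$donor_fragment),
                  nchar(donor_seq)),
    gene = "KAT6B")
  flank_a <- "ACCTTGACCTTGACCTTGACCTTGACCTTG"   # 30 nt, ends G != read[40]
  flank_b <- "AGGTCAAGGTCAAGGTCAAGGTCAAGGTCA"   # 30 nt
  chr17_context <- substr(ex$chimeric_read, 41L, 101L)
  partners <- seq_records("chr17_region_mini",
                          paste0(flank_a, chr17_context, flank_b))
  list(donor = donor, partners = partners)
}

#' Build a worked-example FASTQ fixture
#'
#' A read set containing the published 101 bp chimeric read among random
#' decoy reads guaranteed not to contain the 20-nt search term in either
#' orientation — the desk-scale stand-in for scanning a full RNA-seq run.
#'
#' @param n_decoys number of decoy reads (default 100).
#' @param seed integer seed for decoy generation.
#' @param path optional FASTQ output path.
#' @return a [seq_records()] data frame (chimeric read inserted mid-file),
#'   written to `path` when given.
#' @export
example_fixture_reads <- function(n_decoys = 100L, seed = 1L, path = NULL) {
  ex <- kat6b_kansl1_example()
  set.seed(as.integer(seed))
  term <- ex$search_term
  term_rc <- reverse_complement(term)
  decoys <- character(n_decoys)
  i <- 0L
  while (i < n_decoys) {
    s <- paste(sample(BASES, 101L, replace = TRUE), collapse = "")
    if (grepl(term, s, fixed = TRUE) || grepl(term_rc, s, fixed = TRUE))
      next
    i <- i + 1L
    decoys[i] <- s
  }
  pos <- n_decoys %/% 2L
  ids <- c(sprintf("decoy%03d", seq_len(pos)), "chimeric_101",
           sprintf("decoy%03d", seq(pos + 1L, length.out = n_decoys - pos)))
  seqs <- c(decoys[seq_len(pos)], ex$chimeric_read,
            decoys[seq(pos + 1L, length.out = n_decoys - pos)])
  reads <- seq_records(ids, seqs, strrep("I", 101L))
  if (!is.null(path)) write_fastq(reads, path)
  reads
}
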