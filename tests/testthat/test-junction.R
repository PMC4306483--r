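scan_one <- function(reads, model, exon, side = "exon_end", k = 20) {
  hits <- scan_reads(reads, design_anchors(model, k = k, exons = exon,
                                           sides = side))
  hits[1, ]
}

test_that("the chimeric read splits at read position 43 with 3-base microhomology", {
  ex <- kat6b_kansl1_example()
  mini <- worked_example_refs()
  hit <- scan_one(seq_records("chimeric", ex$chimeric_read), mini$donor, 1)
  sa <- split_align(hit, mini$donor, mini$partners)
  expect_equal(sa$status, "ok")
  expect_equal(sa$donor_read_start, 1L)
  expect_equal(sa$donor_read_end, 43L)        # read 1-43 is donor-derived
  expect_equal(sa$acceptor_read_start, 41L)   # acceptor-maximal start
  expect_equal(sa$acceptor_read_end, 101L)
  expect_equal(sa$microhomology_len, 3L)
  expect_equal(sa$insertion_seq, "")
})

test_that("full-length references give the canonical 1322/2715 junction", {
  ex <- kat6b_kansl1_example()
  refs <- synthetic_reference_models()
  hit <- scan_one(seq_records("chimeric", ex$chimeric_read), refs$donor, 3)
  sa <- split_align(hit, refs$donor, refs$acceptor)
  expect_equal(sa$status, "ok")
  expect_equal(sa$donor_pos, 1322L)
  expect_equal(sa$acceptor_pos, 2715L)
  expect_equal(sa$donor_read_end, 43L)
  expect_equal(sa$donor_ref_pos, 1322L)
})

test_that("split alignment equals the exhaustive enumeration oracle", {
  for (seed in 1:120) {
    inst <- make_oracle_instance(seed)
    sa <- split_align(inst$hit, inst$donor, inst$partners)
    or <- oracle_split(inst$hit$read_seq, inst$donor$seq,
                       inst$hit$boundary_pos, inst$hit$offset, inst$hit$k,
                       inst$partners)
    expect_equal(sa$status, or$status, info = paste("seed", seed))
    if (or$status == "ok") {
      expect_equal(sa$donor_read_end, or$donor_read_end,
                   info = paste("seed", seed))
      expect_equal(sa$acceptor_read_start, or$acceptor_read_start,
                   info = paste("seed", seed))
      expect_equal(sa$acceptor_ref_id, or$acceptor_id,
                   info = paste("seed", seed))
      expect_equal(sa$partner_orientation, or$strand,
                   info = paste("seed", seed))
      expect_equal(sa$microhomology_len, or$microhomology_len,
                   info = paste("seed", seed))
      # and both recover the planted truth
      expect_equal(sa$donor_pos, inst$truth$donor_pos,
                   info = paste("seed", seed))
      expect_equal(sa$microhomology_len, inst$truth$microhomology_len,
                   info = paste("seed", seed))
    }
  }
})

test_that("the read is reconstructable from donor prefix + insertion + acceptor suffix", {
  set.seed(31)
  for (seed in c(2, 17, 44, 101)) {
    inst <- make_oracle_instance(seed)
    sa <- split_align(inst$hit, inst$donor, inst$partners)
    expect_equal(sa$status, "ok")
    aligned <- substr(sa$read_seq, sa$donor_read_start, sa$acceptor_read_end)
    donor_part <- substr(inst$donor$seq,
                         sa$donor_pos - (sa$donor_read_end -
                                           sa$donor_read_start),
                         sa$donor_pos)
    acc_fwd <- if (sa$partner_orientation == "forward")
      inst$partners$seq[1] else reverse_complement(inst$partners$seq[1])
    acc_scan_pos <- if (sa$partner_orientation == "forward")
      sa$acceptor_pos else nchar(acc_fwd) - sa$acceptor_pos + 1L
    acc_part <- substr(acc_fwd, acc_scan_pos,
                       acc_scan_pos + (sa$acceptor_read_end -
                                         sa$donor_read_end -
                                         nchar(sa$insertion_seq)) - 1L)
    expect_equal(aligned, paste0(donor_part, sa$insertion_seq, acc_part))
  }
})

test_that("donor-maximal canonicalisation is idempotent and shifts homology to the donor", {
  inst <- make_oracle_instance(7)  # seed 7 plants microhomology > 0 or not; check both paths
  sa <- split_align(inst$hit, inst$donor, inst$partners)
  expect_equal(canonicalise_split(sa), sa)
  if (sa$microhomology_len > 0 && sa$partner_orientation == "forward") {
    # acceptor-maximal assignment would start microhomology_len bases earlier
    expect_equal(sa$acceptor_pos,
                 sa$acceptor_ref_pos + sa$microhomology_len)
  }
  # engineered 2-base homology: canonical acceptor start sits 2 bases 3'
  set.seed(99)
  dvec <- sample(c("A", "C", "G", "T"), 200, TRUE)
  avec <- sample(c("A", "C", "G", "T"), 200, TRUE)
  dpos <- 100L; apos <- 80L
  avec[(apos - 2):(apos - 1)] <- dvec[(dpos - 1):dpos]
  if (avec[apos - 3] == dvec[dpos - 2]) avec[apos - 3] <- setdiff(c("A", "C", "G", "T"), dvec[dpos - 2])[1]
  if (dvec[dpos + 1] == avec[apos]) dvec[dpos + 1] <- setdiff(c("A", "C", "G", "T"), avec[apos])[1]
  donor <- transcript_model("D", paste(dvec, collapse = ""), c(dpos, 200))
  partners <- seq_records("A", paste(avec, collapse = ""))
  read <- paste0(substr(donor$seq, dpos - 49, dpos),
                 substr(partners$seq, apos, apos + 49))
  hit <- scan_one(seq_records("r", read), donor, 1)
  sa2 <- split_align(hit, donor, partners)
  expect_equal(sa2$microhomology_len, 2L)
  expect_equal(sa2$acceptor_pos, apos)
  expect_equal(sa2$acceptor_ref_pos, apos - 2L)  # acceptor-maximal start
})

test_that("exon_start anchors recover junctions with the candidate as 3' partner", {
  set.seed(55)
  tg <- make_toy_genes(seed = 55, microhomology_len = 1)
  read_start <- tg$truth$donor_pos - 49L
  read <- substr(tg$fusion$seq, read_start, read_start + 99L)
  hit <- scan_one(seq_records("r", read), tg$acceptor,
                  tg$truth$acceptor_exon, side = "exon_start")
  sa <- split_align(hit, tg$acceptor, tg$donor)
  expect_equal(sa$status, "ok")
  expect_equal(sa$donor_ref_id, "TOY_DONOR")
  expect_equal(sa$acceptor_ref_id, "TOY_ACCEPTOR")
  expect_equal(sa$donor_pos, tg$truth$donor_pos)
  expect_equal(sa$acceptor_pos, tg$truth$acceptor_pos)
})

test_that("equally good partner loci give an ambiguous no-call naming both", {
  set.seed(61)
  inst <- make_oracle_instance(12)
  dup <- inst$partners
  dup$seq[2] <- dup$seq[1]   # decoy becomes an identical second locus
  sa <- split_align(inst$hit, inst$donor, dup)
  expect_equal(sa$status, "ambiguous")
  expect_equal(length(sa$detail), 2L)
})

test_that("short unexplained segments and short flanks are no-calls", {
  inst <- make_oracle_instance(23)
  # truncate the read right after the junction: acceptor segment too short
  hit <- inst$hit
  hit$read_seq <- substr(hit$read_seq, 1, inst$truth$donor_read_end + 10L)
  sa <- split_align(hit, inst$donor, inst$partners)
  expect_equal(sa$status, "short_flank")
})

test_that("junction calls aggregate support and honour min_support", {
  inst <- make_oracle_instance(31)
  sa <- split_align(inst$hit, inst$donor, inst$partners)
  calls <- call_junctions(list(sa, sa, sa), min_support = 1)
  expect_equal(nrow(calls), 1L)
  expect_equal(calls$support, 3L)
  expect_equal(calls$donor_pos, inst$truth$donor_pos)
  expect_equal(nrow(call_junctions(list(sa), min_support = 2)), 0L)
  expect_equal(nrow(call_junctions(list(), min_support = 1)), 0L)
})

test_that("200 planted junctions with microhomology 0-5 are recovered exactly", {
  n_ok <- 0L
  for (seed in 1:200) {
    inst <- make_oracle_instance(1000 + seed)
    sa <- split_align(inst$hit, inst$donor, inst$partners)
    if (sa$status == "ok" &&
        sa$donor_pos == inst$truth$donor_pos &&
        sa$microhomology_len == inst$truth$microhomology_len)
      n_ok <- n_ok + 1L
  }
  expect_equal(n_ok, 200L)
})
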