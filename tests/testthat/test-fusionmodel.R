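test_that("fusion assembly concatenates and keeps exon bookkeeping", {
  set.seed(71)
  donor <- transcript_model("D", rand_dna(100), c(40, 80, 100))
  acceptor <- transcript_model("A", rand_dna(120), c(30, 60, 90, 120))
  fus <- assemble_fusion(donor, 40, acceptor, 61)
  expect_equal(nchar(fus$seq), 100L)  # 40 + 60
  expect_equal(fus$seq, paste0(substr(donor$seq, 1, 40),
                               substr(acceptor$seq, 61, 120)))
  # cut exactly at exon 1 end retains exon 1 only; acceptor from exon 3 start
  expect_equal(fus$donor_exons, 1L)
  expect_equal(fus$acceptor_exons, 3:4)
  expect_equal(fus$junction_offset, 40L)
  # a cut inside exon 2 retains it as truncated
  expect_equal(assemble_fusion(donor, 41, acceptor, 61)$donor_exons, 1:2)
  expect_error(assemble_fusion(donor, 0, acceptor, 61), "out of range")
  expect_error(assemble_fusion(donor, 40, acceptor, 121), "out of range")
})

test_that("every fusion base is attributable to exactly one source position", {
  set.seed(72)
  donor <- transcript_model("D", rand_dna(100), c(40, 100))
  acceptor <- transcript_model("A", rand_dna(120), c(60, 120))
  fus <- assemble_fusion(donor, 37, acceptor, 55)
  expect_equal(substr(fus$seq, 1, fus$junction_offset),
               substr(donor$seq, 1, 37))
  expect_equal(substr(fus$seq, fus$junction_offset + 1, nchar(fus$seq)),
               substr(acceptor$seq, 55, 120))
})

test_that("ORF finding follows the ATG..stop convention", {
  orf <- find_orf("ATGAAATAA")
  expect_equal(orf$orf_start, 1L)
  expect_equal(orf$orf_end, 6L)    # stop codon excluded
  expect_equal(orf$protein, "MK")
  expect_null(find_orf("CCCCCC"))
  expect_null(find_orf("ATGAAAAAA"))  # no in-frame stop: rejected
  # tie on length resolved by smaller start
  two <- find_orf("ATGAAATAATTATGCCCTAA")
  expect_equal(two$orf_start, 1L)
})

test_that("ORF finder agrees with a naive scan on random sequences", {
  set.seed(73)
  for (i in 1:200) {
    s <- rand_dna(sample(30:200, 1))
    got <- find_orf(s)
    want <- oracle_orf(s)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$orf_start, want$orf_start, info = s)
      expect_equal(got$orf_end, want$orf_end, info = s)
      expect_equal(nchar(got$protein),
                   (want$orf_end - want$orf_start + 1L) / 3L)
    }
  }
})

test_that("frame preservation follows the codon-phase arithmetic", {
  set.seed(74)
  donor <- transcript_model("D", rand_dna(30), 30, cds_start = 1,
                            cds_end = 30)
  acceptor <- transcript_model("A", rand_dna(30), 30, cds_start = 1,
                               cds_end = 30)
  expect_true(check_in_frame(donor, 6, acceptor, 7))
  expect_false(check_in_frame(donor, 6, acceptor, 8))
  no_cds <- transcript_model("N", rand_dna(30), 30)
  expect_true(is.na(check_in_frame(no_cds, 6, acceptor, 7)))
  expect_equal(attr(check_in_frame(no_cds, 6, acceptor, 7), "reason"),
               "CDS annotation missing")
  wide <- transcript_model("W", rand_dna(30), 30, cds_start = 10,
                           cds_end = 21)
  expect_true(is.na(check_in_frame(wide, 5, acceptor, 7)))
})

test_that("the in-frame fusion protein starts with the wild-type donor prefix", {
  for (seed in c(1, 8, 21)) {
    tg <- make_toy_genes(seed = seed, microhomology_len = seed %% 3)
    fus <- build_fusion_model(tg$donor, tg$truth$donor_pos,
                              tg$acceptor, tg$truth$acceptor_pos)
    expect_true(isTRUE(fus$in_frame))
    expect_equal(fus$orf_start, tg$donor$cds_start)
    expect_equal((fus$orf_end - fus$orf_start + 1L) %% 3L, 0L)
    expect_equal(nchar(fus$protein), (fus$orf_end - fus$orf_start + 1L) / 3L)
    wt <- translate_dna(substr(tg$donor$seq, tg$donor$cds_start,
                               tg$donor$cds_end - 3L))
    jaa <- (tg$truth$donor_pos - tg$donor$cds_start + 1L) %/% 3L
    expect_equal(substr(fus$protein, 1, jaa), substr(wt, 1, jaa))
  }
})

test_that("out-of-frame toy junctions are reported as such", {
  tg <- make_toy_genes(seed = 4, in_frame = FALSE)
  expect_false(check_in_frame(tg$donor, tg$truth$donor_pos,
                              tg$acceptor, tg$truth$acceptor_pos))
})

test_that("domain retention is classified by interval intersection", {
  doms <- data.frame(
    name = c("early", "spanning", "late", "acc_kept", "acc_lost",
             "acc_span"),
    source = c("donor", "donor", "donor", "acceptor", "acceptor",
               "acceptor"),
    aa_start = c(1, 15, 30, 210, 100, 195),
    aa_end = c(10, 25, 40, 260, 150, 230))
  res <- map_domains(doms, donor_junction_aa = 20,
                     acceptor_junction_aa = 200)
  expect_equal(res$status,
               c("retained", "truncated", "lost", "retained", "lost",
                 "truncated"))
  expect_equal(res$fusion_aa_start[1], 1)
  expect_equal(res$fusion_aa_end[1], 10)
  expect_equal(res$fusion_aa_end[2], 20)
  # acceptor residue 200 is fusion residue 21
  expect_equal(res$fusion_aa_start[4], 210 - 200 + 21)
  expect_equal(res$fusion_aa_start[6], 21)
  expect_error(map_domains(doms, 20, 200, donor_protein_len = 35),
               "outside")
})

test_that("the synthetic fusion retains NEMM/H15 (donor) and PEHE (acceptor)", {
  refs <- synthetic_reference_models()
  djaa <- (1322L - refs$donor$cds_start + 1L) %/% 3L
  ajaa <- as.integer(ceiling((2715L - refs$acceptor$cds_start + 1L) / 3))
  res <- map_domains(refs$domains, donor_junction_aa = djaa,
                     acceptor_junction_aa = ajaa)
  expect_equal(res$status, rep("retained", 3))
})
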