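# Independent brute-force oracles used to validate the seed-and-extend
# split aligner and the ORF finder. Deliberately naive: exhaustive
# enumeration, no seeding, no shared code with the implementation.

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                              collapse = "")

# all maximal exact matching runs between read and ref, every diagonal
oracle_runs <- function(read, ref, min_len = 1L) {
  r <- utf8ToInt(read); p <- utf8ToInt(ref)
  L <- length(r); M <- length(p)
  out <- list()
  for (diag in (1L - L):(M - 1L)) {
    t0 <- max(1L, 1L - diag); t1 <- min(L, M - diag)
    if (t1 - t0 + 1L < min_len) next
    eq <- r[t0:t1] == p[(t0:t1) + diag]
    rl <- rle(eq)
    ends <- cumsum(rl$lengths)
    starts <- ends - rl$lengths + 1L
    keep <- which(rl$values & rl$lengths >= min_len)
    for (i in keep)
      out[[length(out) + 1L]] <- c(diag = diag,
                                   start = t0 + starts[i] - 1L,
                                   end = t0 + ends[i] - 1L)
  }
  if (length(out) == 0L) return(NULL)
  as.data.frame(do.call(rbind, out))
}

# exhaustive split: donor side on the anchor-fixed diagonal, acceptor side
# over every (partner, strand, diagonal) maximal run; scored by coverage of
# the unexplained suffix, as the aligner contract states
oracle_split <- function(read, donor_seq, boundary_pos, offset, k,
                         partners, min_flank = 20L) {
  r <- utf8ToInt(read); d <- utf8ToInt(donor_seq)
  d0 <- (boundary_pos - k + 1L) - offset
  i <- offset - 1L
  while (i >= 1L && i + d0 >= 1L && r[i] == d[i + d0]) i <- i - 1L
  j <- offset + k
  while (j <= length(r) && j + d0 <= length(d) && r[j] == d[j + d0])
    j <- j + 1L
  donor_read_end <- j - 1L
  region <- c(donor_read_end + 1L, length(r))
  best <- NULL; best_score <- -Inf; n_best_loci <- 0L
  for (p in seq_len(nrow(partners))) {
    for (strand in c("forward", "revcomp")) {
      pseq <- if (strand == "forward") partners$seq[p] else
        anchorfusion::reverse_complement(partners$seq[p])
      runs <- oracle_runs(read, pseq, min_len = min_flank)
      if (is.null(runs)) next
      for (q in seq_len(nrow(runs))) {
        score <- min(runs$end[q], region[2L]) -
          max(runs$start[q], region[1L]) + 1L
        if (score < 1L) next
        if (score > best_score) {
          best_score <- score; n_best_loci <- 1L
          best <- list(id = partners$id[p], strand = strand,
                       a_start = runs$start[q], a_end = runs$end[q],
                       diag = runs$diag[q])
        } else if (score == best_score) {
          same <- !is.null(best) && best$id == partners$id[p] &&
            best$strand == strand &&
            best$a_start + best$diag == runs$start[q] + runs$diag[q]
          if (!same) n_best_loci <- n_best_loci + 1L
        }
      }
    }
  }
  if (is.null(best)) return(list(status = "no_partner_match"))
  if (n_best_loci > 1L) return(list(status = "ambiguous"))
  mh <- max(0L, donor_read_end - best$a_start + 1L)
  list(status = "ok", donor_read_end = donor_read_end,
       acceptor_read_start = best$a_start,
       acceptor_read_end = best$a_end,
       acceptor_id = best$id, strand = best$strand,
       microhomology_len = mh, score = best_score)
}

# random split-alignment instance: a planted junction read, one true
# partner (random strand), one decoy partner; engineered non-extension so
# the planted coordinates are the unique maximal split
make_oracle_instance <- function(seed) {
  set.seed(seed)
  k <- 20L
  dvec <- sample(c("A", "C", "G", "T"), 240L, TRUE)
  avec <- sample(c("A", "C", "G", "T"), 240L, TRUE)
  dpos <- sample(100:140, 1L)
  apos <- sample(60:160, 1L)
  m <- sample(0:5, 1L)
  if (m > 0L) avec[(apos - m):(apos - 1L)] <- dvec[(dpos - m + 1L):dpos]
  if (dvec[dpos + 1L] == avec[apos])
    dvec[dpos + 1L] <- setdiff(c("A", "C", "G", "T"), avec[apos])[1L]
  if (avec[apos - m - 1L] == dvec[dpos - m])
    avec[apos - m - 1L] <- setdiff(c("A", "C", "G", "T"), dvec[dpos - m])[1L]
  donor_seq <- paste(dvec, collapse = "")
  acc_seq <- paste(avec, collapse = "")
  lf <- sample(24:60, 1L)          # donor-derived read prefix length
  rf <- sample(24:60, 1L)          # acceptor-derived read suffix length
  read <- paste0(substr(donor_seq, dpos - lf + 1L, dpos),
                 substr(acc_seq, apos, apos + rf - 1L))
  strand <- sample(c("forward", "revcomp"), 1L)
  partner_seq <- if (strand == "forward") acc_seq else
    anchorfusion::reverse_complement(acc_seq)
  partners <- data.frame(id = c("true_partner", "decoy"),
                         seq = c(partner_seq, rand_dna(240L)),
                         stringsAsFactors = FALSE)
  hit <- data.frame(read_id = paste0("inst", seed), read_seq = read,
                    anchor_seq = substr(donor_seq, dpos - k + 1L, dpos),
                    transcript_id = "ORACLE_DONOR", exon_index = 1L,
                    side = "exon_end", boundary_pos = dpos, k = k,
                    offset = lf - k + 1L, source_orientation = "as_read",
                    stringsAsFactors = FALSE)
  donor <- anchorfusion::transcript_model("ORACLE_DONOR", donor_seq,
                                          exon_ends = c(dpos, 240L))
  list(hit = hit, donor = donor, partners = partners,
       truth = list(donor_pos = dpos, acceptor_pos = apos,
                    microhomology_len = m, strand = strand,
                    donor_read_end = lf))
}

# naive longest-ATG-ORF finder: scan every ATG, walk codons to the first
# stop, keep the longest (earliest start on ties)
oracle_orf <- function(seq) {
  L <- nchar(seq)
  best <- NULL
  for (s in seq_len(max(0L, L - 5L))) {
    if (substr(seq, s, s + 2L) != "ATG") next
    p <- s
    repeat {
      p <- p + 3L
      if (p + 2L > L) { p <- NA; break }
      if (substr(seq, p, p + 2L) %in% c("TAA", "TAG", "TGA")) break
    }
    if (is.na(p)) next
    len <- p - s
    if (is.null(best) || len > best$len) best <- list(start = s, len = len)
  }
  if (is.null(best)) return(NULL)
  list(orf_start = best$start, orf_end = best$start + best$len - 1L)
}
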