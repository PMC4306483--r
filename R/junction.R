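# Exact maximal extension split alignment. All coordinates 1-based inclusive.

# leftmost read position still matching, walking down from read pos i / ref pos j
ext_left <- function(r, s, i, j) {
  while (i >= 1L && j >= 1L && r[i] == s[j]) { i <- i - 1L; j <- j - 1L }
  i + 1L
}

# rightmost read position still matching, walking up from read pos i / ref pos j
ext_right <- function(r, s, i, j) {
  n <- length(r); m <- length(s)
  while (i <= n && j <= m && r[i] == s[j]) { i <- i + 1L; j <- j + 1L }
  i - 1L
}

ref_coord <- function(scan_pos, strand, plen) {
  if (strand == "forward") scan_pos else plen - scan_pos + 1L
}

as_partner_records <- function(partners) {
  if (inherits(partners, "transcript_model"))
    return(seq_records(partners$transcript_id, partners$seq))
  if (is.list(partners) && !is.data.frame(partners) &&
      all(vapply(partners, inherits, logical(1), "transcript_model")))
    return(seq_records(vapply(partners, `[[`, character(1), "transcript_id"),
                       vapply(partners, `[[`, character(1), "seq")))
  if (is.character(partners)) {
    if (is.null(names(partners))) stop("character partners must be named")
    return(seq_records(names(partners), partners))
  }
  stopifnot(is.data.frame(partners), all(c("id", "seq") %in% names(partners)))
  partners
}

# seed-and-extend search of `region` (read coords) against all partner
# sequences on both strands; returns candidate maximal runs
partner_candidates <- function(read_int, region, partners, seed_len, min_flank) {
  rs <- region[1L]; re <- region[2L]
  tiles <- unique(c(seq(rs, re - seed_len + 1L, by = seed_len),
                    re - seed_len + 1L))
  read_chr <- intToUtf8(read_int)
  cand <- list(); seen <- character()
  for (p in seq_len(nrow(partners))) {
    plen <- nchar(partners$seq[p])
    if (plen < seed_len) next
    for (strand in c("forward", "revcomp")) {
      pseq <- if (strand == "forward") partners$seq[p] else
        reverse_complement(partners$seq[p])
      pv <- utf8ToInt(pseq)
      pds <- Biostrings::DNAString(pseq)
      for (t in tiles) {
        seed <- substr(read_chr, t, t + seed_len - 1L)
        if (grepl("N", seed, fixed = TRUE)) next
        occ <- Biostrings::start(
          Biostrings::matchPattern(seed, pds, fixed = TRUE))
        for (q in occ) {
          a_start <- ext_left(read_int, pv, t - 1L, q - 1L)
          a_end <- ext_right(read_int, pv, t + seed_len, q + seed_len)
          key <- paste(p, strand, q - t, a_start)
          if (key %in% seen) next
          seen <- c(seen, key)
          if (a_end - a_start + 1L < min_flank) next
          score <- min(a_end, re) - max(a_start, rs) + 1L
          if (score < 1L) next
          cand[[length(cand) + 1L]] <- list(
            partner = p, id = partners$id[p], strand = strand,
            diag = q - t, a_start = a_start, a_end = a_end,
            plen = plen, score = score)
        }
      }
    }
  }
  cand
}

no_call <- function(status, hit, detail = NULL) {
  structure(list(status = status, read_id = hit$read_id, detail = detail),
            class = "split_alignment")
}

#' Split-align an anchor-containing read across a fusion junction
#'
#' Partitions a read into a segment explained by the anchor's transcript and
#' a segment explained by a partner search set, by exact maximal extension —
#' a mismatch-free reimplementation of the split localisation that genome
#' browsers perform on a chimeric read. Around the anchor occurrence the read
#' is extended base-by-base against the anchor's transcript in both
#' directions; the unexplained remainder is seeded (`seed_len`-mer exact
#' seeds) into the partner set, on both strands, and extended the same way.
#' Both the transcript-matching and the partner-matching segment must reach
#' `min_flank` matched bases, otherwise the read is a no-call. Sequencing
#' errors are tolerated only through the flank requirement, never through
#' scored alignment.
#'
#' When the two matched segments overlap on the read, the overlapping bases
#' match both partners: junction microhomology. The canonical breakpoint
#' assigns all shared bases to the donor (5') side, see
#' [canonicalise_split()].
#'
#' For an `exon_end` anchor the anchor's transcript is the donor and the
#' partner set supplies the acceptor; for an `exon_start` anchor the roles
#' are mirrored.
#'
#' @param hit one row of a [scan_reads()] hit table (data frame or list).
#' @param donor the [transcript_model()] the anchor was designed on.
#' @param partners partner search set: a [seq_records()] data frame, a named
#'   character vector, a [transcript_model()] or a list of them.
#' @param min_flank minimum matched bases required on each side (default 20).
#' @param seed_len partner seed length (default 16); unexplained segments
#'   shorter than this are no-calls.
#' @return a `split_alignment` list. `status` is `"ok"` or a no-call reason
#'   (`"short_flank"`, `"no_partner_match"`, `"ambiguous"`). For `"ok"`:
#'   `donor_read_end` / `acceptor_read_start` give the read coordinates of
#'   the last donor-matching and first acceptor-matching base under maximal
#'   extension, `donor_ref_pos` / `acceptor_ref_pos` the corresponding
#'   reference coordinates, `microhomology_len` and `insertion_seq` describe
#'   the junction, and `donor_pos` / `acceptor_pos` are the canonical
#'   (donor-maximal) breakpoint coordinates.
#' @export
split_align <- function(hit, donor, partners, min_flank = 20L,
                        seed_len = 16L) {
  stopifnot(inherits(donor, "transcript_model"))
  hit <- as.list(hit)
  partners <- as_partner_records(partners)
  if (nrow(partners) == 0L) stop("empty partner set")
  k <- as.integer(hit$k); off <- as.integer(hit$offset)
  anchor_on_ref <- if (hit$side == "exon_end")
    substr(donor$seq, hit$boundary_pos - k + 1L, hit$boundary_pos)
  else substr(donor$seq, hit$boundary_pos, hit$boundary_pos + k - 1L)
  if (anchor_on_ref != hit$anchor_seq)
    stop("anchor does not belong to transcript ", donor$transcript_id)
  r <- utf8ToInt(hit$read_seq)
  L <- length(r)
  dv <- utf8ToInt(donor$seq)

  if (hit$side == "exon_end") {
    d0 <- (as.integer(hit$boundary_pos) - k + 1L) - off
    anchor_start <- off; anchor_end <- off + k - 1L
    a_rs <- ext_left(r, dv, anchor_start - 1L, anchor_start - 1L + d0)
    a_re <- ext_right(r, dv, anchor_end + 1L, anchor_end + 1L + d0)
    if (a_re - a_rs + 1L < min_flank) return(no_call("short_flank", hit))
    if (L - a_re < seed_len) return(no_call("short_flank", hit))
    cand <- partner_candidates(r, c(a_re + 1L, L), partners,
                               seed_len, min_flank)
    if (length(cand) == 0L) return(no_call("no_partner_match", hit))
    scores <- vapply(cand, `[[`, integer(1), "score")
    best <- cand[scores == max(scores)]
    loci <- unique(vapply(best, function(cc)
      paste(cc$id, cc$strand, cc$a_start + cc$diag), character(1)))
    if (length(loci) > 1L) return(no_call("ambiguous", hit, detail = loci))
    w <- best[[1L]]
    sa <- list(status = "ok", read_id = hit$read_id, side = "exon_end",
               read_seq = hit$read_seq,
               donor_ref_id = donor$transcript_id,
               acceptor_ref_id = w$id,
               partner_orientation = w$strand,
               donor_read_start = a_rs, donor_read_end = a_re,
               acceptor_read_start = w$a_start, acceptor_read_end = w$a_end,
               donor_ref_pos = a_re + d0,
               acceptor_ref_pos = ref_coord(w$a_start + w$diag, w$strand,
                                            w$plen),
               donor_diag = d0, acceptor_diag = w$diag,
               acceptor_len = w$plen)
  } else {
    d0 <- as.integer(hit$boundary_pos) - off
    anchor_start <- off; anchor_end <- off + k - 1L
    a_rs <- ext_left(r, dv, anchor_start - 1L, anchor_start - 1L + d0)
    a_re <- ext_right(r, dv, anchor_end + 1L, anchor_end + 1L + d0)
    if (a_re - a_rs + 1L < min_flank) return(no_call("short_flank", hit))
    if (a_rs - 1L < seed_len) return(no_call("short_flank", hit))
    cand <- partner_candidates(r, c(1L, a_rs - 1L), partners,
                               seed_len, min_flank)
    if (length(cand) == 0L) return(no_call("no_partner_match", hit))
    scores <- vapply(cand, `[[`, integer(1), "score")
    best <- cand[scores == max(scores)]
    loci <- unique(vapply(best, function(cc)
      paste(cc$id, cc$strand, cc$a_start + cc$diag), character(1)))
    if (length(loci) > 1L) return(no_call("ambiguous", hit, detail = loci))
    w <- best[[1L]]
    sa <- list(status = "ok", read_id = hit$read_id, side = "exon_start",
               read_seq = hit$read_seq,
               donor_ref_id = w$id,
               acceptor_ref_id = donor$transcript_id,
               partner_orientation = w$strand,
               donor_read_start = w$a_start, donor_read_end = w$a_end,
               acceptor_read_start = a_rs, acceptor_read_end = a_re,
               donor_ref_pos = ref_coord(w$a_end + w$diag, w$strand, w$plen),
               acceptor_ref_pos = a_rs + d0,
               donor_diag = w$diag, acceptor_diag = d0,
               donor_len = w$plen)
  }
  sa$microhomology_len <- max(0L, sa$donor_read_end - sa$acceptor_read_start + 1L)
  sa$insertion_seq <- if (sa$acceptor_read_start > sa$donor_read_end + 1L)
    substr(hit$read_seq, sa$donor_read_end + 1L, sa$acceptor_read_start - 1L)
  else ""
  class(sa) <- "split_alignment"
  canonicalise_split(sa)
}

#' Canonicalise a split alignment (donor-maximal breakpoint)
#'
#' Within a microhomology window the junction coordinate is ambiguous: the
#' shared bases can be attributed to either partner. The canonical rule used
#' throughout the package assigns every shared base to the donor (5')
#' partner: `donor_pos` is the donor reference coordinate of the last
#' donor-matching read base, and `acceptor_pos` is the acceptor coordinate
#' aligned to the next read base (or, across an untemplated insertion, the
#' acceptor coordinate of its first matching base). The operation is
#' idempotent.
#'
#' @param sa a `split_alignment` with `status == "ok"`.
#' @return the split alignment with `donor_pos` / `acceptor_pos` set.
#' @export
canonicalise_split <- function(sa) {
  stopifnot(inherits(sa, "split_alignment"))
  if (!identical(sa$status, "ok")) return(sa)
  if (sa$side == "exon_end") {
    sa$donor_pos <- sa$donor_read_end + sa$donor_diag
    first_acc_read <- if (sa$insertion_seq == "") sa$donor_read_end + 1L
                      else sa$acceptor_read_start
    sa$acceptor_pos <- ref_coord(first_acc_read + sa$acceptor_diag,
                                 sa$partner_orientation, sa$acceptor_len)
  } else {
    sa$donor_pos <- ref_coord(sa$donor_read_end + sa$donor_diag,
                              sa$partner_orientation, sa$donor_len)
    first_acc_read <- if (sa$insertion_seq == "") sa$donor_read_end + 1L
                      else sa$acceptor_read_start
    sa$acceptor_pos <- first_acc_read + sa$acceptor_diag
  }
  sa
}

#' @export
print.split_alignment <- function(x, ...) {
  if (!identical(x$status, "ok")) {
    cat("split_alignment <", x$read_id, ">: no-call (", x$status, ")\n",
        sep = "")
  } else {
    cat("split_alignment <", x$read_id, ">: ", x$donor_ref_id, ":",
        x$donor_pos, " | ", x$acceptor_ref_id, ":", x$acceptor_pos,
        " (read ", x$donor_read_start, "-", x$donor_read_end, " / ",
        x$acceptor_read_start, "-", x$acceptor_read_end,
        ", microhomology ", x$microhomology_len,
        if (x$insertion_seq != "") paste0(", insertion ", x$insertion_seq),
        ")\n", sep = "")
  }
  invisible(x)
}

#' Aggregate split alignments into junction calls
#'
#' Split alignments sharing the same canonical breakpoint (donor id and
#' position, acceptor id and position, insertion, partner orientation) are
#' merged into one call whose `support` is the number of merged reads.
#' Calls below `min_support` are dropped; the result is sorted by decreasing
#' support, ties broken by smaller donor position.
#'
#' @param splits a list of `split_alignment` objects (no-calls are ignored).
#' @param min_support minimum supporting reads per call (default 1).
#' @return a data frame (class `junction_calls`) with columns `donor_id`,
#'   `donor_pos`, `acceptor_id`, `acceptor_pos`, `orientation`, `support`,
#'   `microhomology_len`, `insertion_seq`, `in_frame` (NA until frame
#'   information is supplied, see [check_in_frame()]).
#' @export
call_junctions <- function(splits, min_support = 1L) {
  if (inherits(splits, "split_alignment")) splits <- list(splits)
  splits <- Filter(function(s) identical(s$status, "ok"), splits)
  if (length(splits) == 0L) return(empty_calls())
  df <- do.call(rbind, lapply(splits, function(s) data.frame(
    donor_id = s$donor_ref_id, donor_pos = s$donor_pos,
    acceptor_id = s$acceptor_ref_id, acceptor_pos = s$acceptor_pos,
    orientation = s$partner_orientation,
    microhomology_len = s$microhomology_len,
    insertion_seq = s$insertion_seq, stringsAsFactors = FALSE)))
  key <- paste(df$donor_id, df$donor_pos, df$acceptor_id, df$acceptor_pos,
               df$insertion_seq, df$orientation, sep = "\r")
  agg <- df[!duplicated(key), , drop = FALSE]
  agg$support <- as.integer(table(key)[key[!duplicated(key)]])
  agg <- agg[agg$support >= min_support, , drop = FALSE]
  agg <- agg[order(-agg$support, agg$donor_pos), , drop = FALSE]
  agg$in_frame <- rep(NA, nrow(agg))
  rownames(agg) <- NULL
  class(agg) <- c("junction_calls", "data.frame")
  agg
}

empty_calls <- function() {
  out <- data.frame(donor_id = character(), donor_pos = integer(),
                    acceptor_id = character(), acceptor_pos = integer(),
                    orientation = character(), microhomology_len = integer(),
                    insertion_seq = character(), support = integer(),
                    in_frame = logical(), stringsAsFactors = FALSE)
  class(out) <- c("junction_calls", "data.frame")
  out
}

#' Write junction calls as TSV and JSON
#'
#' @param calls a `junction_calls` data frame.
#' @param path output path; `.json` suffix selects JSON, anything else TSV.
#' @return `path`, invisibly.
#' @export
write_junctions <- function(calls, path) {
  if (endsWith(path, ".json")) {
    jsonlite::write_json(as.data.frame(calls), path, auto_unbox = FALSE,
                         digits = NA, na = "null")
  } else {
    utils::write.table(as.data.frame(calls), path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
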