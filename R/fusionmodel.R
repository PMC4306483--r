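#' Assemble a fusion transcript from a junction call
#'
#' Concatenates donor bases `1..donor_pos` with acceptor bases
#' `acceptor_pos..end` and records the retained exons: a cut exactly at an
#' exon's last base retains that whole exon, a cut inside an exon retains it
#' as truncated; on the acceptor side the exon containing `acceptor_pos` and
#' all later exons are retained.
#'
#' @param donor,acceptor [transcript_model()] objects.
#' @param donor_pos last donor base retained (1-based, canonical breakpoint).
#' @param acceptor_pos first acceptor base retained.
#' @return a `fusion_transcript` list with `seq`, `donor_exons`,
#'   `acceptor_exons`, `junction_offset` (position in `seq` of the last donor
#'   base) and provenance ids/positions. ORF fields are filled by
#'   [find_orf()] via [build_fusion_model()].
#' @export
assemble_fusion <- function(donor, donor_pos, acceptor, acceptor_pos) {
  stopifnot(inherits(donor, "transcript_model"),
            inherits(acceptor, "transcript_model"))
  donor_pos <- as.integer(donor_pos); acceptor_pos <- as.integer(acceptor_pos)
  if (donor_pos < 1L || donor_pos > nchar(donor$seq))
    stop("donor_pos out of range 1..", nchar(donor$seq))
  if (acceptor_pos < 1L || acceptor_pos > nchar(acceptor$seq))
    stop("acceptor_pos out of range 1..", nchar(acceptor$seq))
  seq <- paste0(substr(donor$seq, 1L, donor_pos),
                substr(acceptor$seq, acceptor_pos, nchar(acceptor$seq)))
  donor_last <- min(which(donor$exon_ends >= donor_pos))
  acc_first <- min(which(acceptor$exon_ends >= acceptor_pos))
  structure(list(
    seq = seq,
    donor_id = donor$transcript_id, acceptor_id = acceptor$transcript_id,
    donor_pos = donor_pos, acceptor_pos = acceptor_pos,
    donor_exons = seq_len(donor_last),
    acceptor_exons = seq(acc_first, length(acceptor$exon_ends)),
    junction_offset = donor_pos),
    class = "fusion_transcript")
}

#' @export
print.fusion_transcript <- function(x, ...) {
  cat("fusion_transcript ", x$donor_id, ":", x$donor_pos, " | ",
      x$acceptor_id, ":", x$acceptor_pos, "\n",
      "  length ", nchar(x$seq), " nt; donor exons ",
      paste(range(x$donor_exons), collapse = "-"), "; acceptor exons ",
      paste(range(x$acceptor_exons), collapse = "-"), "\n", sep = "")
  if (!is.null(x$orf_start))
    cat("  ORF ", x$orf_start, "-", x$orf_end, " (",
        x$orf_end - x$orf_start + 1L, " nt, ", nchar(x$protein),
        " aa); in_frame = ", x$in_frame, "\n", sep = "")
  invisible(x)
}

#' Find the longest ATG-initiated open reading frame
#'
#' Scans all three frames of the forward strand for ATG-initiated ORFs
#' terminated by an in-frame stop codon; ORFs running off the sequence end
#' without a stop are rejected. The reported ORF length excludes the stop
#' codon; ties on length are broken by the smaller start coordinate. The
#' protein is the standard-genetic-code translation without the stop.
#'
#' @param seq a DNA string.
#' @return `NULL` if no terminated ORF exists, else a list with `orf_start`,
#'   `orf_end` (1-based inclusive, stop codon excluded) and `protein`.
#' @export
#' @examples
#' find_orf("ATGAAATAA") # ORF 1-6, protein "MK"
find_orf <- function(seq) {
  seq <- normalise_dna(seq)
  L <- nchar(seq)
  if (L < 6L) return(NULL)
  best <- NULL
  for (f in 0:2) {
    starts <- seq.int(f + 1L, L - 2L, by = 3L)
    if (length(starts) < 2L) next
    cod <- substring(seq, starts, starts + 2L)
    atg <- which(cod == "ATG")
    stp <- which(cod %in% c("TAA", "TAG", "TGA"))
    if (length(atg) == 0L || length(stp) == 0L) next
    nxt <- stp[findInterval(atg, stp) + 1L]  # first stop strictly after ATG
    ok <- !is.na(nxt)
    if (!any(ok)) next
    len <- (nxt[ok] - atg[ok]) * 3L
    i <- which.max(len)  # ties: earliest ATG (which.max takes first)
    cand <- list(orf_start = starts[atg[ok][i]],
                 orf_end = starts[atg[ok][i]] + len[i] - 1L)
    if (is.null(best) ||
        (cand$orf_end - cand$orf_start) > (best$orf_end - best$orf_start) ||
        ((cand$orf_end - cand$orf_start) == (best$orf_end - best$orf_start) &&
         cand$orf_start < best$orf_start))
      best <- cand
  }
  if (is.null(best)) return(NULL)
  best$protein <- translate_dna(substr(seq, best$orf_start, best$orf_end))
  best
}

#' Translate a DNA string with the standard genetic code
#'
#' @param seq in-frame DNA coding sequence (length a multiple of 3).
#' @return amino-acid string; fuzzy codons (containing `N`) become `X`.
#' @export
translate_dna <- function(seq) {
  as.character(Biostrings::translate(Biostrings::DNAString(seq),
                                     if.fuzzy.codon = "X"))
}

#' Check reading-frame preservation across a fusion junction
#'
#' A junction preserves the reading frame when the acceptor's codon phase at
#' its breakpoint continues the donor's frame, i.e. when
#' `(donor_pos - donor_cds_start + 1) mod 3 == (acceptor_pos - acceptor_cds_start) mod 3`.
#' Requires CDS annotations on both models and both breakpoints inside their
#' CDS; otherwise returns `NA` with a `reason` attribute.
#'
#' @param donor,acceptor [transcript_model()] objects with CDS annotations.
#' @param donor_pos,acceptor_pos canonical breakpoint coordinates.
#' @return `TRUE`, `FALSE`, or `NA` (with attribute `reason`).
#' @export
check_in_frame <- function(donor, donor_pos, acceptor, acceptor_pos) {
  unknown <- function(reason) structure(NA, reason = reason)
  if (is.null(donor$cds_start) || is.null(acceptor$cds_start))
    return(unknown("CDS annotation missing"))
  if (donor_pos < donor$cds_start || donor_pos > donor$cds_end)
    return(unknown("junction outside donor CDS"))
  if (acceptor_pos < acceptor$cds_start || acceptor_pos > acceptor$cds_end)
    return(unknown("junction outside acceptor CDS"))
  ((donor_pos - donor$cds_start + 1L) %% 3L) ==
    ((acceptor_pos - acceptor$cds_start) %% 3L)
}

#' Assemble a fusion transcript and characterise its ORF and frame
#'
#' Convenience wrapper chaining [assemble_fusion()], [find_orf()] and
#' [check_in_frame()].
#'
#' @inheritParams assemble_fusion
#' @return a `fusion_transcript` with `orf_start`, `orf_end`, `protein` and
#'   `in_frame` filled in (`NULL`/`NA` when undeterminable).
#' @export
build_fusion_model <- function(donor, donor_pos, acceptor, acceptor_pos) {
  fus <- assemble_fusion(donor, donor_pos, acceptor, acceptor_pos)
  orf <- find_orf(fus$seq)
  if (!is.null(orf)) {
    fus$orf_start <- orf$orf_start; fus$orf_end <- orf$orf_end
    fus$protein <- orf$protein
  } else {
    fus$orf_start <- fus$orf_end <- NA_integer_; fus$protein <- NA_character_
  }
  fus$in_frame <- check_in_frame(donor, donor_pos, acceptor, acceptor_pos)
  fus
}

#' Classify protein-domain retention in a fusion protein
#'
#' Each domain, given in the amino-acid coordinates of its wild-type
#' protein, is classified by interval intersection with the part of that
#' protein retained in the fusion: donor domains against the donor-derived
#' prefix (residues `1..donor_junction_aa` of both the wild-type donor and
#' the fusion protein), acceptor domains against the acceptor-derived suffix
#' (wild-type acceptor residues `acceptor_junction_aa..end`). Retained and
#' truncated domains are also mapped into fusion-protein coordinates.
#'
#' For an in-frame junction, `donor_junction_aa` is the number of complete
#' donor-derived codons, `floor((donor_pos - donor_cds_start + 1) / 3)`, and
#' `acceptor_junction_aa` is `ceiling((acceptor_pos - acceptor_cds_start + 1) / 3)`.
#'
#' @param domains data frame with columns `name`, `source` (`"donor"` or
#'   `"acceptor"`), `aa_start`, `aa_end` (1-based, wild-type protein
#'   coordinates).
#' @param donor_junction_aa number of donor-derived residues in the fusion
#'   protein.
#' @param acceptor_junction_aa first wild-type acceptor residue retained in
#'   the fusion protein.
#' @param donor_protein_len,acceptor_protein_len optional wild-type protein
#'   lengths; domains extending beyond them raise an error.
#' @return the domain table with added `status`
#'   (`retained`/`truncated`/`lost`) and `fusion_aa_start`, `fusion_aa_end`
#'   (NA for lost domains).
#' @export
map_domains <- function(domains, donor_junction_aa, acceptor_junction_aa,
                        donor_protein_len = NA, acceptor_protein_len = NA) {
  stopifnot(all(c("name", "source", "aa_start", "aa_end") %in% names(domains)),
            all(domains$source %in% c("donor", "acceptor")),
            all(domains$aa_start <= domains$aa_end),
            all(domains$aa_start >= 1L))
  lim <- ifelse(domains$source == "donor", donor_protein_len,
                acceptor_protein_len)
  bad <- !is.na(lim) & domains$aa_end > lim
  if (any(bad))
    stop("domain outside wild-type protein: ",
         paste(domains$name[bad], collapse = ", "))
  out <- domains
  out$status <- NA_character_
  out$fusion_aa_start <- out$fusion_aa_end <- NA_integer_
  for (i in seq_len(nrow(out))) {
    s <- out$aa_start[i]; e <- out$aa_end[i]
    if (out$source[i] == "donor") {
      if (e <= donor_junction_aa) {
        out$status[i] <- "retained"
        out$fusion_aa_start[i] <- s; out$fusion_aa_end[i] <- e
      } else if (s > donor_junction_aa) {
        out$status[i] <- "lost"
      } else {
        out$status[i] <- "truncated"
        out$fusion_aa_start[i] <- s
        out$fusion_aa_end[i] <- donor_junction_aa
      }
    } else {
      shift <- donor_junction_aa - acceptor_junction_aa + 1L
      if (s >= acceptor_junction_aa) {
        out$status[i] <- "retained"
        out$fusion_aa_start[i] <- s + shift; out$fusion_aa_end[i] <- e + shift
      } else if (e < acceptor_junction_aa) {
        out$status[i] <- "lost"
      } else {
        out$status[i] <- "truncated"
        out$fusion_aa_start[i] <- acceptor_junction_aa + shift
        out$fusion_aa_end[i] <- e + shift
      }
    }
  }
  out
}

#' Read a protein-domain coordinate table
#'
#' TSV with header `name`, `source`, `aa_start`, `aa_end`.
#'
#' @param path path to the TSV file.
#' @return a data frame.
#' @export
read_domain_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "source", "aa_start", "aa_end")
  if (!all(need %in% names(tab)))
    stop("domain table must have columns: ", paste(need, collapse = ", "))
  tab
}
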