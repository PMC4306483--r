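#' Scan reads for exact anchor occurrences
#'
#' Streams a set of reads and reports every exact occurrence of every anchor,
#' in either orientation — the computational equivalent of running `grep`
#' with the anchor sequence over the sequence lines of a FASTQ file, plus the
#' reverse-complement search that `grep` does not do. Matching is exact
#' (`N` only matches `N`); base qualities, headers and separator lines are
#' never searched because records are parsed, not treated as raw lines.
#'
#' A read matching a reverse-complement anchor is reverse-complemented before
#' being stored, so `read_seq` in the result is always in transcript
#' orientation and `source_orientation` records the flip. A read is reported
#' once per distinct (anchor identity, offset); overlapping occurrences are
#' all reported.
#'
#' @param reads a [seq_records()] data frame (e.g. from [read_fastq()]).
#' @param anchors an anchor table from [design_anchors()]. Both orientations
#'   are searched for every anchor identity regardless of which orientation
#'   rows are present.
#' @return a data frame (class `read_hits`) with columns `read_id`,
#'   `read_seq` (orientation-normalised), `anchor_seq` (forward anchor),
#'   `transcript_id`, `exon_index`, `side`, `boundary_pos`, `k`, `offset`
#'   (1-based position of the anchor's first base in `read_seq`) and
#'   `source_orientation` (`as_read` / `reverse_complemented`). Zero rows if
#'   nothing matches.
#' @export
scan_reads <- function(reads, anchors) {
  if (nrow(anchors) == 0L) stop("empty anchor table")
  key <- paste(anchors$transcript_id, anchors$exon_index, anchors$side,
               anchors$boundary_pos, anchors$k)
  idx <- !duplicated(key)
  ident <- anchors[idx, , drop = FALSE]
  # canonical forward sequence per anchor identity
  ident$fwd <- ifelse(ident$orientation == "forward", ident$seq,
                      reverse_complement(ident$seq))
  if (nrow(reads) == 0L) return(empty_hits())
  subj <- Biostrings::DNAStringSet(reads$seq)
  rlen <- nchar(reads$seq)
  out <- list()
  for (a in seq_len(nrow(ident))) {
    fwd <- ident$fwd[a]
    k <- nchar(fwd)
    for (ori in c("as_read", "reverse_complemented")) {
      pat <- if (ori == "as_read") fwd else reverse_complement(fwd)
      m <- Biostrings::vmatchPattern(pat, subj, fixed = TRUE)
      st <- Biostrings::startIndex(m)
      hit_reads <- which(lengths(st) > 0L)
      for (r in hit_reads) {
        pos <- st[[r]]
        if (ori == "as_read") {
          rs <- reads$seq[r]
          off <- pos
        } else {
          rs <- reverse_complement(reads$seq[r])
          off <- rlen[r] - (pos + k - 1L) + 1L
        }
        out[[length(out) + 1L]] <- data.frame(
          read_index = r, read_id = reads$id[r], read_seq = rs,
          anchor_seq = fwd, transcript_id = ident$transcript_id[a],
          exon_index = ident$exon_index[a], side = ident$side[a],
          boundary_pos = ident$boundary_pos[a], k = k,
          offset = sort(off), source_orientation = ori,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  hits <- hits[order(hits$read_index, hits$boundary_pos, hits$offset), ,
               drop = FALSE]
  hits$read_index <- NULL
  rownames(hits) <- NULL
  class(hits) <- c("read_hits", "data.frame")
  hits
}

empty_hits <- function() {
  hits <- data.frame(read_id = character(), read_seq = character(),
                     anchor_seq = character(), transcript_id = character(),
                     exon_index = integer(), side = character(),
                     boundary_pos = integer(), k = integer(),
                     offset = integer(), source_orientation = character(),
                     stringsAsFactors = FALSE)
  class(hits) <- c("read_hits", "data.frame")
  hits
}

#' Count anchor occurrences in a read set
#'
#' Equals the number of [scan_reads()] hits for that single anchor identity;
#' supports presence/absence style negative checks (e.g. showing that no
#' read carries a reciprocal-fusion boundary k-mer).
#'
#' @param reads a [seq_records()] data frame.
#' @param anchor a one-identity anchor table (one or two orientation rows).
#' @return integer occurrence count.
#' @export
count_matches <- function(reads, anchor) {
  nrow(scan_reads(reads, anchor))
}

#' Write / read a hit table as TSV
#'
#' @param hits a hit table from [scan_reads()].
#' @param path file path.
#' @return `path` (write) or the hit table (read).
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_hits
#' @export
read_hits <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("read_hits", "data.frame")
  out
}
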