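#' Reverse complement
#'
#' Exact reverse complement over the `{A,C,G,T,N}` alphabet (`N`
#' self-complements). An involution: `reverse_complement(reverse_complement(x))`
#' is `x`.
#'
#' @param seq character vector of DNA sequences.
#' @return character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("AAACCC")
reverse_complement <- function(seq) {
  if (any(!grepl("^[ACGTN]+$", seq)))
    stop("reverse_complement: sequence contains symbols outside {A,C,G,T,N}")
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}

#' Design exon-boundary anchor k-mers
#'
#' For each requested exon boundary of a candidate transcript, emits the
#' terminal k-mer of that exon (`side = "exon_end"`: the last `k` bases of
#' the exon) and/or the initial k-mer (`side = "exon_start"`: the first `k`
#' bases), each in forward and reverse-complement orientation. These anchors
#' are the exact search terms used to fish junction-spanning reads out of raw
#' FASTQ: a fusion created by translocation plus splicing joins partners at
#' exon boundaries, so a read crossing the junction must carry one partner's
#' boundary k-mer.
#'
#' The default `k = 20` gives an expected chance-hit rate of roughly
#' `81 * 4^-20` per 100 bp read; `k` below 12 is rejected because random hits
#' then stop being negligible. Anchors containing `N` are suppressed with a
#' warning (exact matching against `N` is undefined).
#'
#' @param model a [transcript_model()].
#' @param k anchor length in nt (default 20, minimum 12).
#' @param exons integer vector of 1-based exon indices; default all exons.
#' @param sides subset of `c("exon_end", "exon_start")`.
#' @return a data frame (class `anchor_table`) with columns `seq`,
#'   `transcript_id`, `gene`, `exon_index`, `side`, `boundary_pos`,
#'   `orientation`, `k`. `boundary_pos` is the transcript coordinate of the
#'   boundary base (exon last base for `exon_end`, first base for
#'   `exon_start`).
#' @export
design_anchors <- function(model, k = 20L, exons = NULL,
                           sides = c("exon_end", "exon_start")) {
  stopifnot(inherits(model, "transcript_model"))
  k <- as.integer(k)
  if (k < 12L) stop("anchor length k must be >= 12 (got ", k, ")")
  sides <- match.arg(sides, c("exon_end", "exon_start"), several.ok = TRUE)
  n_exon <- length(model$exon_ends)
  if (is.null(exons)) exons <- seq_len(n_exon)
  exons <- sort(unique(as.integer(exons)))
  if (any(exons < 1L | exons > n_exon))
    stop("requested exon(s) outside 1..", n_exon)
  starts <- exon_starts(model)
  rows <- list()
  for (e in exons) {
    exon_len <- model$exon_ends[e] - starts[e] + 1L
    if (exon_len < k)
      stop("anchor length k = ", k, " exceeds exon ", e,
           " length (", exon_len, " nt) of ", model$transcript_id)
    for (side in sides) {
      if (side == "exon_end") {
        bpos <- model$exon_ends[e]
        aseq <- substr(model$seq, bpos - k + 1L, bpos)
      } else {
        bpos <- starts[e]
        aseq <- substr(model$seq, bpos, bpos + k - 1L)
      }
      if (grepl("N", aseq, fixed = TRUE)) {
        warning("anchor at exon ", e, " ", side, " of ", model$transcript_id,
                " contains N; suppressed")
        next
      }
      for (ori in c("forward", "revcomp")) {
        rows[[length(rows) + 1L]] <- data.frame(
          seq = if (ori == "forward") aseq else reverse_complement(aseq),
          transcript_id = model$transcript_id, gene = model$gene,
          exon_index = e, side = side, boundary_pos = bpos,
          orientation = ori, k = k, stringsAsFactors = FALSE)
      }
    }
  }
  out <- if (length(rows) == 0L)
    data.frame(seq = character(), transcript_id = character(),
               gene = character(), exon_index = integer(),
               side = character(), boundary_pos = integer(),
               orientation = character(), k = integer(),
               stringsAsFactors = FALSE)
  else do.call(rbind, rows)
  class(out) <- c("anchor_table", "data.frame")
  out
}

#' Write / read an anchor table as TSV
#'
#' @param anchors an anchor table from [design_anchors()].
#' @param path output path.
#' @return `path` (write) or the anchor table (read), invisibly for write.
#' @export
write_anchors <- function(anchors, path) {
  utils::write.table(anchors, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_anchors
#' @export
read_anchors <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  class(out) <- c("anchor_table", "data.frame")
  out
}
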