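#' Define a primer pair
#'
#' Primers are given as ordered for synthesis, 5' to 3': the forward primer
#' matches the template strand directly, the reverse primer is the reverse
#' complement of its template binding site.
#'
#' @param name pair name.
#' @param fwd,rev primer sequences (length >= 10, alphabet `{A,C,G,T}`).
#' @return a `primer_pair` list.
#' @export
primer_pair <- function(name, fwd, rev) {
  fwd <- normalise_dna(gsub("[ -]", "", fwd))
  rev <- normalise_dna(gsub("[ -]", "", rev))
  for (p in c(fwd, rev)) {
    if (nchar(p) < 10L) stop("primer shorter than 10 nt in pair ", name)
    if (grepl("N", p, fixed = TRUE))
      stop("primer contains non-ACGT symbols in pair ", name)
  }
  structure(list(name = name, fwd = fwd, rev = rev), class = "primer_pair")
}

#' Read a primer table
#'
#' TSV with header `name`, `fwd`, `rev`.
#'
#' @param path path to the TSV file.
#' @return a list of [primer_pair()] objects, named by pair.
#' @export
read_primer_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("name", "fwd", "rev")
  if (!all(need %in% names(tab)))
    stop("primer table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(seq_len(nrow(tab)), function(i)
    primer_pair(tab$name[i], tab$fwd[i], tab$rev[i]))
  names(out) <- tab$name
  out
}

#' Predict PCR amplicons on a template (in-silico PCR)
#'
#' Locates every exact occurrence of the forward primer and of the reverse
#' complement of the reverse primer on the template, and reports every
#' (forward site, reverse site) combination in which the forward site ends
#' strictly before the reverse site starts and the spanned product is at
#' most `max_len`. Matching is exact — this verifies primer design logic,
#' not hybridisation thermodynamics. An empty result means no product (the
#' computational analogue of a negative RT-PCR lane).
#'
#' @param template a single-row [seq_records()], a named length-1 character
#'   vector, or a [transcript_model()].
#' @param pair a [primer_pair()].
#' @param max_len maximum product length in bp (default 5000).
#' @return data frame (class `amplicons`) with `template_id`, `pair`,
#'   `start`, `end` (1-based inclusive: forward-site 5' end to reverse-site
#'   3' end), `length` and `product_seq`, sorted by `start` then `length`.
#' @export
predict_amplicons <- function(template, pair, max_len = 5000L) {
  stopifnot(inherits(pair, "primer_pair"))
  if (inherits(template, "transcript_model"))
    template <- seq_records(template$transcript_id, template$seq)
  if (is.character(template))
    template <- seq_records(names(template), template)
  stopifnot(nrow(template) == 1L)
  if (max_len <= nchar(pair$fwd) + nchar(pair$rev))
    stop("max_len must exceed the combined primer length")
  subj <- Biostrings::DNAString(template$seq)
  fs <- BiocGenerics::start(
    Biostrings::matchPattern(pair$fwd, subj, fixed = TRUE))
  rs <- BiocGenerics::start(
    Biostrings::matchPattern(reverse_complement(pair$rev), subj,
                             fixed = TRUE))
  lf <- nchar(pair$fwd); lr <- nchar(pair$rev)
  rows <- list()
  for (f in fs) for (r in rs) {
    if (f + lf - 1L >= r) next           # no overlapping primer sites
    end <- r + lr - 1L
    len <- end - f + 1L
    if (len > max_len) next
    rows[[length(rows) + 1L]] <- data.frame(
      template_id = template$id, pair = pair$name, start = f, end = end,
      length = len, product_seq = substr(template$seq, f, end),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    out <- data.frame(template_id = character(), pair = character(),
                      start = integer(), end = integer(), length = integer(),
                      product_seq = character(), stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, rows)
    out <- out[order(out$start, out$length), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("amplicons", "data.frame")
  out
}
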