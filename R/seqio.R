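#' Normalise a DNA character vector
#'
#' Uppercases, converts RNA `U` to `T` and replaces every symbol outside
#' `{A,C,G,T,N}` with `N`. All sequence input to the package passes through
#' this function so downstream exact matching only ever sees the five-letter
#' DNA alphabet.
#'
#' @param x character vector of nucleotide sequences.
#' @return character vector of the same length over `{A,C,G,T,N}`.
#' @export
#' @examples
#' normalise_dna(c("acgu", "ACGTX"))
normalise_dna <- function(x) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  gsub("[^ACGTN]", "N", x)
}

#' Construct a set of sequence records
#'
#' The package's light-weight container for reads and reference sequences:
#' a data frame with columns `id`, `seq` and (optionally) `qual`. Sequences
#' are normalised with [normalise_dna()]; qualities are carried verbatim but
#' never interpreted.
#'
#' @param id character vector of identifiers.
#' @param seq character vector of sequences (same length as `id`).
#' @param qual optional character vector of per-base quality strings; each
#'   must have the same number of characters as its sequence.
#' @return a `seq_records` data frame.
#' @export
seq_records <- function(id, seq, qual = NA_character_) {
  stopifnot(length(id) == length(seq))
  seq <- normalise_dna(as.character(seq))
  if (any(!nzchar(seq))) stop("empty sequence in record(s): ",
                              paste(id[!nzchar(seq)], collapse = ", "))
  qual <- as.character(qual)
  if (length(qual) == 1L) qual <- rep(qual, length(seq))
  bad <- !is.na(qual) & nchar(qual) != nchar(seq)
  if (any(bad)) stop("seq/qual length mismatch in record(s): ",
                     paste(id[bad], collapse = ", "))
  out <- data.frame(id = as.character(id), seq = seq, qual = qual,
                    stringsAsFactors = FALSE)
  class(out) <- c("seq_records", "data.frame")
  out
}

#' Read a FASTQ file
#'
#' Parses 4-line FASTQ records (optionally gzip-compressed; compression is
#' detected transparently). Record order is preserved and base qualities are
#' carried but never interpreted.
#'
#' @param path path to a FASTQ or FASTQ.gz file.
#' @return a [seq_records()] data frame with `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  n <- length(lines)
  if (n == 0L) return(seq_records(character(), character(), character()))
  if (n %% 4L != 0L)
    stop("truncated FASTQ record starting at line ", 4L * (n %/% 4L) + 1L,
         " of ", path)
  hd <- lines[seq(1L, n, by = 4L)]
  sq <- lines[seq(2L, n, by = 4L)]
  pl <- lines[seq(3L, n, by = 4L)]
  ql <- lines[seq(4L, n, by = 4L)]
  if (any(bad <- !startsWith(hd, "@")))
    stop("malformed FASTQ header at line ", 4L * (which(bad)[1L] - 1L) + 1L)
  if (any(bad <- !startsWith(pl, "+")))
    stop("malformed FASTQ separator at line ", 4L * (which(bad)[1L] - 1L) + 3L)
  if (any(bad <- nchar(sq) != nchar(ql)))
    stop("seq/qual length mismatch in FASTQ record at line ",
         4L * (which(bad)[1L] - 1L) + 1L)
  id <- sub("\\s.*$", "", sub("^@", "", hd))
  seq_records(id, sq, ql)
}

#' Write a FASTQ file
#'
#' @param records a [seq_records()] data frame; records without qualities get
#'   a uniform `"I"` quality string.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(records, path) {
  qual <- ifelse(is.na(records$qual),
                 vapply(nchar(records$seq),
                        function(n) strrep("I", n), character(1)),
                 records$qual)
  con <- if (endsWith(path, ".gz")) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  writeLines(paste0("@", records$id, "\n", records$seq, "\n+\n", qual),
             con, sep = "\n")
  invisible(path)
}

#' Read a FASTA file
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that tokenises headers
#' at the first whitespace, normalises sequences to the `{A,C,G,T,N}` DNA
#' alphabet and rejects empty files and duplicate identifiers.
#'
#' @param path path to a FASTA file (optionally gzip-compressed).
#' @return a [seq_records()] data frame (`qual` is `NA`).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  id <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(id))
    stop("duplicate FASTA id: ", id[duplicated(id)][1L])
  seq_records(id, as.character(set))
}

#' Write a FASTA file
#'
#' @param records a [seq_records()] data frame (or any data frame with `id`
#'   and `seq` columns).
#' @param path output path.
#' @param width line width for sequence wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  set <- Biostrings::BStringSet(records$seq)
  names(set) <- records$id
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Construct a transcript model
#'
#' An mRNA sequence together with its ordered exon boundaries and optional
#' CDS interval, in 1-based inclusive transcript coordinates. `exon_ends`
#' gives, for each exon in order, the transcript coordinate of its last base;
#' the last entry must equal the sequence length. When both CDS bounds are
#' present their span must be a whole number of codons (the stop codon is
#' conventionally included).
#'
#' @param transcript_id transcript identifier (e.g. a versioned accession).
#' @param seq mRNA sequence, 5' to 3'.
#' @param exon_ends strictly increasing integer vector of exon end
#'   coordinates; last entry equals `nchar(seq)`.
#' @param gene gene symbol.
#' @param cds_start,cds_end optional CDS bounds (1-based inclusive).
#' @return a `transcript_model` object (list).
#' @export
transcript_model <- function(transcript_id, seq, exon_ends,
                             gene = NA_character_,
                             cds_start = NULL, cds_end = NULL) {
  seq <- normalise_dna(seq)
  exon_ends <- as.integer(exon_ends)
  if (length(exon_ends) == 0L || any(diff(exon_ends) <= 0L) || exon_ends[1L] < 1L)
    stop("exon_ends must be strictly increasing positive coordinates")
  if (exon_ends[length(exon_ends)] != nchar(seq))
    stop("last exon end (", exon_ends[length(exon_ends)],
         ") does not equal sequence length (", nchar(seq), ") for ",
         transcript_id)
  if (!is.null(cds_start) != !is.null(cds_end))
    stop("cds_start and cds_end must be given together")
  if (!is.null(cds_start)) {
    cds_start <- as.integer(cds_start); cds_end <- as.integer(cds_end)
    if (!(1L <= cds_start && cds_start < cds_end && cds_end <= nchar(seq)))
      stop("CDS interval out of range for ", transcript_id)
    if ((cds_end - cds_start + 1L) %% 3L != 0L)
      stop("CDS length not a multiple of 3 for ", transcript_id)
  }
  structure(list(transcript_id = as.character(transcript_id),
                 gene = as.character(gene), seq = seq,
                 exon_ends = exon_ends,
                 cds_start = cds_start, cds_end = cds_end),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat("transcript_model ", x$transcript_id,
      if (!is.na(x$gene)) paste0(" (", x$gene, ")"), "\n",
      "  length ", nchar(x$seq), " nt, ", length(x$exon_ends), " exons",
      if (!is.null(x$cds_start))
        paste0(", CDS ", x$cds_start, "-", x$cds_end), "\n", sep = "")
  invisible(x)
}

#' First transcript coordinate of each exon
#'
#' @param model a [transcript_model()].
#' @return integer vector of exon start coordinates.
#' @export
exon_starts <- function(model) {
  c(1L, utils::head(model$exon_ends, -1L) + 1L)
}

#' Read an exon-boundary table
#'
#' Expects a TSV with header columns `transcript_id`, `exon_index`,
#' `exon_end`; optional constant `cds_start`/`cds_end` columns are honoured.
#'
#' @param path path to the TSV file.
#' @return a data frame.
#' @export
read_exon_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("transcript_id", "exon_index", "exon_end")
  if (!all(need %in% names(tab)))
    stop("exon table must have columns: ", paste(need, collapse = ", "))
  tab
}

#' Load a transcript model from FASTA plus exon table
#'
#' @param fasta path to a FASTA file containing the transcript sequence.
#' @param exon_table path to a TSV read by [read_exon_table()].
#' @param transcript_id transcript to load; defaults to the first FASTA record.
#' @param gene optional gene symbol.
#' @param cds_start,cds_end optional CDS bounds; override any table columns.
#' @return a [transcript_model()].
#' @export
load_transcript_model <- function(fasta, exon_table, transcript_id = NULL,
                                  gene = NA_character_,
                                  cds_start = NULL, cds_end = NULL) {
  recs <- read_fasta(fasta)
  tab <- read_exon_table(exon_table)
  if (is.null(transcript_id)) transcript_id <- recs$id[1L]
  seq <- recs$seq[match(transcript_id, recs$id)]
  if (is.na(seq)) stop("transcript ", transcript_id, " not in ", fasta)
  rows <- tab[tab$transcript_id == transcript_id, , drop = FALSE]
  if (nrow(rows) == 0L) stop("transcript ", transcript_id, " not in exon table")
  rows <- rows[order(rows$exon_index), , drop = FALSE]
  if (!identical(as.integer(rows$exon_index), seq_len(nrow(rows))))
    stop("exon_index must be contiguous 1..n for ", transcript_id)
  if (is.null(cds_start) && "cds_start" %in% names(rows) &&
      !is.na(rows$cds_start[1L])) {
    cds_start <- rows$cds_start[1L]; cds_end <- rows$cds_end[1L]
  }
  transcript_model(transcript_id, seq, rows$exon_end, gene = gene,
                   cds_start = cds_start, cds_end = cds_end)
}

#' Derive a transcript-relative exon table from a GTF subset
#'
#' Convenience reader for minimal GTF annotation (`exon` features carrying
#' `transcript_id` attributes). Exons of the requested transcript are ordered
#' 5' to 3' (by strand) and their cumulative lengths projected into
#' transcript-relative exon end coordinates. Only exon order and boundary
#' coordinates are consumed; requires the rtracklayer package.
#'
#' @param path path to a GTF file.
#' @param transcript_id transcript to extract.
#' @return a data frame with columns `transcript_id`, `exon_index`, `exon_end`.
#' @export
read_gtf_exons <- function(path, transcript_id) {
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("read_gtf_exons requires the rtracklayer package")
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon" & gr$transcript_id == transcript_id]
  if (length(gr) == 0L) stop("no exon features for ", transcript_id)
  ord <- order(BiocGenerics::start(gr),
               decreasing = as.character(BiocGenerics::strand(gr)[1L]) == "-")
  w <- BiocGenerics::width(gr)[ord]
  data.frame(transcript_id = transcript_id,
             exon_index = seq_along(w),
             exon_end = cumsum(w))
}
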