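#' Run the targeted fusion-discovery pipeline end to end
#'
#' Chains anchor design, FASTQ scanning, split alignment, junction calling
#' and fusion-transcript modelling: anchors are designed on the candidate
#' transcript, reads carrying any anchor are extracted, each hit is
#' split-aligned against the candidate and the partner search set, canonical
#' junction calls are aggregated, and for the top-supported call the fusion
#' transcript is assembled and its ORF, protein and reading-frame status
#' predicted. Optionally, in-silico PCR products of verification primer
#' pairs are predicted on the assembled fusion.
#'
#' @param fastq FASTQ path(s) (optionally gzipped) or a [seq_records()]
#'   data frame.
#' @param donor candidate [transcript_model()] (the anchors' transcript).
#' @param partners partner search set (see [split_align()]).
#' @param k anchor length (default 20).
#' @param exons exon subset for anchor design; default all.
#' @param sides boundary sides for anchor design (default `"exon_end"`,
#'   the configuration for a 5' candidate).
#' @param min_flank,seed_len,min_support see [split_align()] and
#'   [call_junctions()].
#' @param acceptor_model optional [transcript_model()] for the partner the
#'   top call lands in; enables exon bookkeeping, CDS-based frame checking
#'   and a full-length fusion assembly. Without it the partner sequence is
#'   treated as a single-exon model without CDS.
#' @param primers optional list of [primer_pair()]s to test on the
#'   assembled fusion.
#' @param out_dir optional output directory; writes `junctions.tsv`,
#'   `junctions.json`, `fusion.fa`, `protein.fa` and `report.json`.
#' @return a `fusion_pipeline_result` list with `status` (`"call"` /
#'   `"no_call"`), `anchors`, `hits`, `splits`, `no_call_reasons`, `calls`,
#'   `fusion` (NULL when no call) and `amplicons`.
#' @export
run_pipeline <- function(fastq, donor, partners, k = 20L, exons = NULL,
                         sides = "exon_end", min_flank = 20L,
                         seed_len = 16L, min_support = 1L,
                         acceptor_model = NULL, primers = NULL,
                         out_dir = NULL) {
  reads <- if (is.character(fastq))
    do.call(rbind, lapply(fastq, read_fastq)) else fastq
  anchors <- design_anchors(donor, k = k, exons = exons, sides = sides)
  hits <- scan_reads(reads, anchors)
  splits <- lapply(seq_len(nrow(hits)), function(i)
    split_align(hits[i, ], donor, partners, min_flank = min_flank,
                seed_len = seed_len))
  status_v <- vapply(splits, `[[`, character(1), "status")
  calls <- call_junctions(splits, min_support = min_support)
  fusion <- NULL
  amplicons <- NULL
  if (nrow(calls) > 0L) {
    top <- calls[1L, ]
    partner_recs <- as_partner_records(partners)
    get_model <- function(id) {
      if (id == donor$transcript_id) return(donor)
      if (!is.null(acceptor_model) && id == acceptor_model$transcript_id)
        return(acceptor_model)
      s <- partner_recs$seq[match(id, partner_recs$id)]
      transcript_model(id, s, exon_ends = nchar(s))
    }
    dm <- get_model(top$donor_id)
    am <- get_model(top$acceptor_id)
    fusion <- build_fusion_model(dm, top$donor_pos, am, top$acceptor_pos)
    calls$in_frame[1L] <- fusion$in_frame
    if (!is.null(primers)) {
      if (inherits(primers, "primer_pair")) primers <- list(primers)
      tmpl <- seq_records(paste0(top$donor_id, "-", top$acceptor_id),
                          fusion$seq)
      amplicons <- do.call(rbind, lapply(primers, function(p)
        predict_amplicons(tmpl, p)))
    }
  }
  res <- structure(list(
    status = if (nrow(calls) > 0L) "call" else "no_call",
    n_reads = nrow(reads), anchors = anchors, hits = hits, splits = splits,
    no_call_reasons = table(status_v[status_v != "ok"]),
    calls = calls, fusion = fusion, amplicons = amplicons),
    class = "fusion_pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(res, out_dir)
  res
}

write_pipeline_outputs <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_junctions(res$calls, file.path(out_dir, "junctions.tsv"))
  write_junctions(res$calls, file.path(out_dir, "junctions.json"))
  if (!is.null(res$fusion)) {
    fid <- paste0(res$fusion$donor_id, "-", res$fusion$acceptor_id)
    write_fasta(data.frame(id = fid, seq = res$fusion$seq),
                file.path(out_dir, "fusion.fa"))
    if (!is.na(res$fusion$protein))
      write_fasta(data.frame(id = paste0(fid, "_protein"),
                             seq = res$fusion$protein),
                  file.path(out_dir, "protein.fa"))
  }
  report <- list(
    status = res$status, n_reads = res$n_reads,
    n_anchors = nrow(res$anchors), anchor_seqs = unique(res$anchors$seq),
    n_hits = nrow(res$hits),
    no_call_reasons = as.list(res$no_call_reasons),
    n_calls = nrow(res$calls),
    calls = as.data.frame(res$calls))
  if (!is.null(res$fusion))
    report$fusion <- list(
      length = nchar(res$fusion$seq),
      donor_exons = res$fusion$donor_exons,
      acceptor_exons = res$fusion$acceptor_exons,
      orf_start = res$fusion$orf_start, orf_end = res$fusion$orf_end,
      orf_length = if (is.na(res$fusion$orf_start)) NA_integer_ else
        res$fusion$orf_end - res$fusion$orf_start + 1L,
      protein_length = if (is.na(res$fusion$protein)) NA_integer_ else
        nchar(res$fusion$protein),
      in_frame = res$fusion$in_frame)
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(out_dir)
}

#' @export
print.fusion_pipeline_result <- function(x, ...) {
  cat("fusion pipeline: ", x$n_reads, " reads, ", nrow(x$anchors),
      " anchors, ", nrow(x$hits), " hits, ", nrow(x$calls), " junction call",
      if (nrow(x$calls) != 1L) "s", " [", x$status, "]\n", sep = "")
  if (nrow(x$calls) > 0L) {
    print(utils::head(as.data.frame(x$calls), 5L))
    if (!is.null(x$fusion)) print(x$fusion)
  }
  invisible(x)
}
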