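# Synthetic data: toy fusion gene pairs and FASTQ read simulation with truth.

BASES <- c("A", "C", "G", "T")
STOPS <- c("TAA", "TAG", "TGA")
SENSE_CODONS <- setdiff(
  apply(expand.grid(BASES, BASES, BASES), 1L, paste, collapse = ""), STOPS)

random_dna_vec <- function(n) sample(BASES, n, replace = TRUE)

# remove every ATG wholly inside positions 1..limit by mutating its T to C
strip_atg <- function(chars, limit = length(chars)) {
  if (limit < 3L) return(chars)
  repeat {
    s <- paste(chars[1:limit], collapse = "")
    m <- gregexpr("ATG", s, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) break
    chars[m + 1L] <- "C"
  }
  chars
}

# sense-codon run of n codons as a character vector (3n bases)
sense_run <- function(n) {
  unlist(strsplit(sample(SENSE_CODONS, n, replace = TRUE), ""))
}

# replace chars[pos] with a base != avoid, preferring `prefer`
base_differing <- function(avoid, prefer = NULL) {
  pool <- setdiff(BASES, avoid)
  if (!is.null(prefer) && prefer %in% pool) prefer else pool[1L]
}

#' Simulation configuration
#'
#' @param read_len read length in nt.
#' @param n_reads total number of reads.
#' @param error_rate per-base substitution probability in `[0, 1)`.
#' @param fusion_fraction proportion of reads drawn from the fusion
#'   transcript; the remainder is split evenly between the two wild-type
#'   transcripts.
#' @param seed integer seed governing all randomness of the simulation.
#' @return a `sim_config` list.
#' @export
sim_config <- function(read_len = 100L, n_reads = 1000L, error_rate = 0,
                       fusion_fraction = 0.1, seed = 1L) {
  stopifnot(read_len >= 40L, n_reads >= 1L,
            error_rate >= 0, error_rate < 1,
            fusion_fraction >= 0, fusion_fraction <= 1)
  structure(list(read_len = as.integer(read_len),
                 n_reads = as.integer(n_reads),
                 error_rate = error_rate,
                 fusion_fraction = fusion_fraction,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a toy fusion gene pair with a planted junction
#'
#' Builds two random multi-exon transcript models with stop-free CDSs and a
#' planted fusion junction at a donor exon end / acceptor exon start pair —
#' the configuration produced by a genomic translocation followed by
#' splicing. The construction engineers three local properties so that the
#' planted breakpoint is exactly recoverable: (i) when
#' `microhomology_len = m > 0`, the `m` acceptor bases 5' of the acceptor
#' breakpoint are overwritten with the `m` donor bases preceding the
#' junction; (ii) the donor base after the junction differs from the first
#' acceptor base (donor-maximal extension stops exactly at the planted
#' coordinate); (iii) the acceptor base 5' of the homology tract differs
#' from the corresponding donor base. With `in_frame = TRUE` the acceptor
#' CDS phase is chosen so the junction preserves the reading frame and the
#' fusion's longest ORF runs from the donor start codon to the acceptor stop.
#'
#' Calls `set.seed(seed)`; identical seeds give byte-identical models.
#'
#' @param seed integer seed.
#' @param microhomology_len engineered junction microhomology (0-5 typical).
#' @param in_frame should the junction preserve the reading frame?
#' @return list with `donor`, `acceptor` ([transcript_model()]s), `fusion`
#'   (a `fusion_transcript`) and `truth` (planted `donor_pos`,
#'   `acceptor_pos`, `microhomology_len`, `donor_exon`, `acceptor_exon`,
#'   `in_frame`).
#' @export
make_toy_genes <- function(seed = 1L, microhomology_len = 0L,
                           in_frame = TRUE) {
  set.seed(as.integer(seed))
  m <- as.integer(microhomology_len)
  stopifnot(m >= 0L, m <= 10L)

  ## donor: 1600 nt, 4 exons, CDS 121..1500 (stop included)
  d_ends <- c(300L, 700L, 1100L, 1600L) +
    c(sample(-30:30, 3L, replace = TRUE), 0L)
  dcs <- 121L
  d <- c(strip_atg(random_dna_vec(dcs - 1L)),
         unlist(strsplit("ATG", "")), sense_run(458L),
         unlist(strsplit("TAA", "")), random_dna_vec(100L))
  dce <- dcs + 459L * 3L - 1L                       # 1500
  dpos <- d_ends[2L]                                # junction: exon 2 end
  d_exon <- 2L

  ## acceptor: 1600 nt, 5 exons, junction at exon 3 start, CDS phase chosen
  a_ends <- c(250L, 600L, 950L, 1300L, 1600L) +
    c(sample(-30:30, 4L, replace = TRUE), 0L)
  apos <- a_ends[2L] + 1L                           # exon 3 start
  a_exon <- 3L
  phase <- (dpos - dcs + 1L) %% 3L
  acs <- apos - phase - 3L * ((apos - phase - 100L) %/% 3L)
  if (!in_frame) acs <- acs + 1L                    # breaks the phase match
  n_cod <- (1400L - acs + 1L) %/% 3L
  ace <- acs + n_cod * 3L - 1L
  a <- c(random_dna_vec(acs - 1L),
         unlist(strsplit("ATG", "")), sense_run(n_cod - 2L),
         unlist(strsplit("TAA", "")), random_dna_vec(1600L - ace))

  ## junction engineering
  if (in_frame && phase != 0L) {
    # mixed codon spanning the junction must not be a stop
    mixed <- paste(c(d[(dpos - phase + 1L):dpos],
                     a[apos:(apos + 2L - phase)]), collapse = "")
    if (mixed %in% STOPS) a[apos] <- base_differing(a[apos], prefer = "C")
  }
  d[dpos + 1L] <- base_differing(a[apos])
  if (m > 0L) {
    a[(apos - m):(apos - 1L)] <- d[(dpos - m + 1L):dpos]
  }
  if (a[apos - m - 1L] == d[dpos - m]) {
    a[apos - m - 1L] <- base_differing(d[dpos - m])
  }

  donor <- transcript_model("TOY_DONOR", paste(d, collapse = ""), d_ends,
                            gene = "toyD", cds_start = dcs, cds_end = dce)
  acceptor <- transcript_model("TOY_ACCEPTOR", paste(a, collapse = ""),
                               a_ends, gene = "toyA",
                               cds_start = acs, cds_end = ace)
  fusion <- assemble_fusion(donor, dpos, acceptor, apos)
  list(donor = donor, acceptor = acceptor, fusion = fusion,
       truth = list(donor_pos = dpos, acceptor_pos = apos,
                    microhomology_len = m, donor_exon = d_exon,
                    acceptor_exon = a_exon, in_frame = in_frame))
}

#' Simulate single-end RNA-seq reads with a planted fusion
#'
#' Draws reads with uniformly distributed start positions from the fusion
#' transcript and the two wild-type transcripts, applies per-base
#' substitution errors, and returns a truth manifest recording each read's
#' source, position and — for fusion reads — the number of bases on either
#' side of the junction (so junction-spanning support at any flank
#' requirement can be recomputed). Qualities are uniform `"I"` and never
#' consumed. Substitutions only; the detection method is exact-match based
#' and indel tolerance is out of scope.
#'
#' Calls `set.seed(cfg$seed)`; a fixed seed gives byte-identical output.
#'
#' @param genes output of [make_toy_genes()] (or any list with `donor`,
#'   `acceptor` [transcript_model()]s and `fusion` with `seq` and
#'   `junction_offset`).
#' @param cfg a [sim_config()].
#' @param fastq optional output FASTQ path (`.gz` for compression).
#' @param truth_path optional JSON output path for the truth manifest.
#' @return list with `reads` (a [seq_records()]) and `truth` (data frame
#'   with `read_id`, `source`, `start`, `end`, `left_flank`, `right_flank`).
#' @export
simulate_reads <- function(genes, cfg, fastq = NULL, truth_path = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  rl <- cfg$read_len
  srcs <- list(fusion = genes$fusion$seq,
               donor_wt = genes$donor$seq,
               acceptor_wt = genes$acceptor$seq)
  if (rl > min(nchar(unlist(srcs))))
    stop("read_len exceeds the shortest source transcript")
  n_fus <- round(cfg$n_reads * cfg$fusion_fraction)
  n_wt <- cfg$n_reads - n_fus
  counts <- c(fusion = n_fus, donor_wt = ceiling(n_wt / 2),
              acceptor_wt = floor(n_wt / 2))
  joff <- genes$fusion$junction_offset
  rows <- list()
  for (s in names(srcs)) {
    n_i <- counts[[s]]
    if (n_i == 0L) next
    L <- nchar(srcs[[s]])
    starts <- sample.int(L - rl + 1L, n_i, replace = TRUE)
    rows[[s]] <- data.frame(
      source = s, start = starts, end = starts + rl - 1L,
      seq = substring(srcs[[s]], starts, starts + rl - 1L),
      stringsAsFactors = FALSE)
  }
  tr <- do.call(rbind, rows)
  tr$read_id <- sprintf("sim%05d_%s", seq_len(nrow(tr)), tr$source)
  if (cfg$error_rate > 0) {
    tr$seq <- vapply(tr$seq, function(s) {
      v <- strsplit(s, "")[[1L]]
      hit <- which(stats::runif(rl) < cfg$error_rate)
      for (i in hit) v[i] <- sample(setdiff(BASES, v[i]), 1L)
      paste(v, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  }
  tr$left_flank <- ifelse(tr$source == "fusion",
                          pmax(0L, joff - tr$start + 1L), NA_integer_)
  tr$right_flank <- ifelse(tr$source == "fusion",
                           pmax(0L, tr$end - joff), NA_integer_)
  reads <- seq_records(tr$read_id, tr$seq, strrep("I", rl))
  truth <- tr[, c("read_id", "source", "start", "end",
                  "left_flank", "right_flank")]
  rownames(truth) <- NULL
  if (!is.null(fastq)) write_fastq(reads, fastq)
  if (!is.null(truth_path))
    jsonlite::write_json(truth, truth_path, digits = NA, na = "null")
  list(reads = reads, truth = truth)
}

#' Expected junction-spanning read count
#'
#' Closed-form expectation for the number of fusion-derived reads covering
#' the junction with at least `flank` bases on both sides, under uniform
#' start positions: `n_fusion * (read_len - 2 * flank + 1) / (L - read_len + 1)`.
#'
#' @param n_fusion number of fusion-derived reads.
#' @param read_len read length.
#' @param fusion_len fusion transcript length.
#' @param flank minimum bases required on each side of the junction.
#' @return expected count (double).
#' @export
expected_spanning_reads <- function(n_fusion, read_len, fusion_len,
                                    flank = 20L) {
  n_fusion * (read_len - 2L * flank + 1L) / (fusion_len - read_len + 1L)
}
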