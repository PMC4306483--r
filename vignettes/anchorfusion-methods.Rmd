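---
title: "Targeted fusion-transcript discovery by exon-boundary anchor search"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Targeted fusion-transcript discovery by exon-boundary anchor search}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(anchorfusion)
```

## The method

When a chromosomal translocation disrupts a known candidate gene, the
resulting fusion transcript can be found directly in raw RNA-seq reads
without genome-wide fusion calling. Because translocation followed by
splicing joins the partners at exon boundaries, any read spanning the fusion
junction must contain the terminal bases of a candidate-gene exon followed by
foreign sequence. anchorfusion operationalises this as a four-stage
pipeline:

1. **Anchor design.** For each exon boundary of the candidate transcript,
   take the terminal k-mer (last *k* bases of the exon for a 5' candidate,
   first *k* bases for a 3' candidate), in forward and reverse-complement
   orientation.
2. **Exact scan.** Stream the FASTQ files and extract every read containing
   any anchor exactly — the computational equivalent of `grep` over the
   sequence lines, plus the reverse-strand search that `grep` does not do.
3. **Split alignment.** For each anchor-carrying read, extend the match
   against the candidate transcript base by base in both directions; seed
   the unexplained remainder into a k-mer index of a partner search set
   (a transcriptome or small genomic regions, both strands) and extend the
   same way. The read is thereby partitioned into a donor-matching prefix
   and an acceptor-matching suffix.
4. **Junction calling and modelling.** Aggregate canonical breakpoints over
   reads, assemble the predicted fusion transcript, locate its longest
   ATG-initiated ORF, translate it, check reading-frame preservation, and
   classify retained protein domains. An in-silico PCR layer predicts the
   verification amplicons a wet-lab RT-PCR design would produce.

The motivating application is the KAT6B-KANSL1 fusion of a
t(10;17)(q22;q21) retroperitoneal leiomyoma, where the 20-mer ending KAT6B
exon 3 (`TACCCCATGAGAAAGACCAG`, nt 1303–1322 of NM_012330.3) extracts a
single 101 bp chimeric read whose bases 1–43 are KAT6B (ending at nt 1322)
and whose bases 44–101 are KANSL1 (from nt 2715), with a 3-base
microhomology in genomic context. `kat6b_kansl1_example()` carries these
published sequences and `worked_example_refs()` rebuilds the desk-scale
references around them.

## Exact matching, by design

Matching is exact at every stage — anchors, split extension, primer sites.
This mirrors the discovery tool (`grep`) and keeps behaviour fully
auditable: a hit means the bases are literally present. Sequencing errors
are tolerated only structurally, by requiring `min_flank` matched bases on
each side of the junction rather than by scored alignment; an error inside a
flank shortens it and, at worst, turns that read into a no-call rather than
a shifted call. The simulation results below quantify the cost: at a 1%
per-base substitution rate roughly half of the junction-spanning reads still
produce a clean split, which is ample at any realistic coverage. An
error-tolerant mode is deliberately out of scope.

## Parameters

* `k = 20` (anchor length, minimum 12). The expected number of chance exact
  hits of one anchor per 100 bp read is about `81 * 4^-k` per orientation —
  around `7e-11` at `k = 20`, and still only `5e-6` at the floor of 12. The
  floor exists because below it random FASTQ hits stop being negligible in
  multi-million-read data.
* `min_flank = 20` (matched bases required on each side of the junction).
  Twenty bases uniquely place a sequence in a transcriptome-sized search set
  with overwhelming probability and match the anchor length, so a read that
  passes the scan can in principle pass the donor-side flank.
* `seed_len = 16` (partner seed). Unexplained segments shorter than the
  seed are no-calls (`"short_flank"`); 16 keeps the index selective
  (`4^16 ≈ 4e9`) while letting segments barely above `min_flank` seed.
* `min_support = 1`. Targeted discovery on a single sample may legitimately
  rest on one perfect junction read — exactly the worked example's
  situation; raise it for noisy data.
* `max_len = 5000` for in-silico PCR, covering any cDNA amplicon a
  verification design would use.

## Microhomology and the canonical breakpoint

When the two partners share identical bases at the junction, the breakpoint
is ambiguous within the homology window: the shared bases can be attributed
to either side. `split_align()` reports the maximal-extension coordinates
(`donor_read_end`, `acceptor_read_start`; their overlap is
`microhomology_len`) and a *canonical* pair (`donor_pos`, `acceptor_pos`)
under a fixed donor-maximal rule: every shared base is assigned to the 5'
partner. This rule is what makes coordinates comparable across reads — two
reads splitting the same junction at different points inside the homology
window merge into one call — and it reproduces the published transcript
coordinates of the worked example (1322/2715 rather than the
acceptor-maximal alternative). The rule is idempotent and applied uniformly
to calls and to simulation truth before comparison.

Ties elsewhere are broken deterministically: equal-support junction calls
sort by smaller donor position; equal-length ORFs resolve to the smaller
start; equally extending partner loci are *not* resolved — they yield an
`"ambiguous"` no-call naming the loci, because picking one silently would
fabricate a breakpoint.

## ORF and frame conventions

`find_orf()` scans the three forward frames (the assembled fusion's
orientation is known) for ATG-initiated ORFs ending at an in-frame stop;
ORFs running off the 3' end are rejected. The reported length excludes the
stop codon, so protein length is always ORF length / 3 — the convention
under which the worked example's 1398 bp ORF encodes exactly 466 residues.
`check_in_frame()` is independent of ORF content: the junction preserves
frame iff `(donor_pos − donor_cds_start + 1) mod 3` equals
`(acceptor_pos − acceptor_cds_start) mod 3`, and returns `NA` with a reason
when CDS annotation is missing or the junction lies outside a CDS. CDS
intervals include the stop codon, as reference annotations do.

Domain retention (`map_domains()`) is pure interval arithmetic in protein
coordinates: donor domains against the donor-derived prefix, acceptor
domains against the retained suffix, each classified retained / truncated /
lost and mapped into fusion coordinates. Since a domain specification is just a
user-supplied coordinate table, no remote domain databases are queried.

## Synthetic reference stand-ins

Full-length reference mRNAs are not redistributable inside the package, so
`synthetic_reference_models()` builds deterministic stand-ins in code. They
are *coordinate-faithful*: the two published junction fragments sit at their
published coordinates (KAT6B-like nt 1280–1322; KANSL1-like nt 2715–2772),
exon boundaries place the junction at donor exon 3 end / acceptor exon 11
start of 15, the concatenation `donor[1..1322] + acceptor[2715..end]` is
3667 bp, CDS starts are chosen so the junction is in-frame by the phase
formula, all ten published primer binding sites are embedded at their
name-implied positions, and a 1398 bp / 466 aa longest ORF is engineered
into the fusion. Everything between the landmarks is random sense-codon or
untranslated sequence; the builder verifies every landmark at construction
time and the stand-ins are clearly labelled `*_synthetic`.

One engineering point deserves note: the published 58-nt KANSL1-side
junction fragment contains a stop codon in all three reading frames within
its first 47 bases (offsets 0/1/2 stop at fragment positions 19–21, 11–13
and 45–47). Consequently *no* ATG-initiated ORF crossing the 1322/2715
junction can reach 1398 nt in any sequence that contains this fragment at
the junction — the reported junction-local sequence and the reported ORF
statistics are mutually inconsistent at face value. The stand-in therefore
realises the 1398 bp longest ORF downstream of the junction inside the
acceptor-derived region, which reproduces the reported ORF/protein/frame
numbers while keeping the published junction sequence exact. Tests that use
the stand-in check coordinate arithmetic, scanning, split alignment and
primer logic; they do not, and cannot, validate real KAT6B/KANSL1 sequence
content.

## What the simulator emulates — and what it does not

`make_toy_genes()` plants a junction at a donor exon end / acceptor exon
start with engineered microhomology (0–5 nt) and controllable frame
preservation; `simulate_reads()` draws single-end reads with uniform start
positions and independent per-base substitutions, writing a truth manifest
with each read's source and junction flanks. Defaults (100 bp reads,
substitution-only errors at 0–1%, uniform `"I"` qualities) reflect the
Illumina paired-end data the method targets, with mates treated
independently because the scan is per-read.

Deliberately not modelled: coverage and GC bias, fragment-size and
paired-end geometry, indels, quality-dependent errors, expression levels,
intron retention, and alternative isoforms. Passing the simulation suite
therefore shows that the pipeline recovers planted junctions under uniform
substitution noise — not that it is robust to every artefact of real
libraries. The closed-form check
`E[spanning] = n_fusion (read_len − 2·flank + 1) / (L − read_len + 1)`
validates the generator itself against binomial sampling.

## Problem sizes used by the test suite

The suite runs entirely on generated data: 500 random split-alignment
instances compared against an exhaustive enumeration oracle (240 nt
references, ~50–120 nt reads), 50 error-free and 30 one-percent-error
simulations of 300–600 reads each over ~1.6 kb toy transcripts, ten
1500-read simulations for the spanning-count calibration, and 200 random
sequences for the ORF-finder oracle. These sizes give the statistical
assertions comfortable margins (e.g. ≥ 25 informative error simulations for
a ≥ 90% top-call criterion) while keeping a full run in the low minutes.

## Degenerate inputs and edge behaviour

Lowercase and RNA bases are normalised (`U → T`), anything outside
`{A,C,G,T}` becomes `N`; `N` matches only itself in exact search, and
anchors containing `N` are suppressed with a warning. Reads shorter than an
anchor are skipped silently; an empty hit list, an empty junction table and
a clean no-call exit are all valid outcomes, not errors. Duplicate read IDs
are allowed (hits keep file order); duplicate FASTA IDs are not. Quality
strings are carried through FASTQ round-trips but never interpreted.

## Known limitations

* Exact matching means a SNP or RNA-editing site inside the anchor hides a
  real junction from the scan; design anchors on several exons to mitigate.
* Partner coordinates are reported in the coordinate system of the supplied
  partner sequences; there is no liftover between genomic and transcript
  context (the worked example's 61 bp genomic vs 58 nt transcript acceptor
  segment is reported as-is on each reference).
* Genome-wide untargeted fusion discovery, scored alignment, paired-end
  rescue and breakpoint assembly from discordant pairs are out of scope —
  this is a verification-grade targeted tool, not a replacement for
  genome-wide fusion callers.
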