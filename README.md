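# anchorfusion

Targeted discovery and characterisation of gene-fusion transcripts from raw
RNA-seq reads, for the situation where cytogenetics (or prior biology)
already names a candidate gene: a t(10;17)(q22;q21) translocation and a
known 10q22 target, say, rather than a genome-wide fishing expedition.

Fusions created by translocation plus splicing join their partners at exon
boundaries. A read spanning the junction must therefore contain the
terminal k-mer of a candidate-gene exon followed by foreign sequence, and
that k-mer can be searched for *exactly* in the FASTQ files — `grep`
semantics, no alignment. anchorfusion packages that idea as a pipeline:

1. **anchors** — exon-boundary k-mers (default k = 20, both orientations)
   from a candidate transcript model;
2. **scan** — exact streaming extraction of anchor-carrying reads from
   FASTQ (plain or gzipped), reverse-complement hits normalised to
   transcript orientation;
3. **split alignment** — mismatch-free maximal extension of each hit
   against the candidate and a partner search set (seed-and-extend, both
   strands), yielding a donor prefix / acceptor suffix partition with
   junction microhomology resolved by a donor-maximal canonical rule;
4. **junction calls** — aggregation by canonical breakpoint with read
   support;
5. **fusion model** — assembled chimeric transcript, longest ATG-initiated
   ORF (stop excluded; protein = ORF/3), reading-frame check from CDS
   phases, protein-domain retention report;
6. **in-silico PCR** — exact-match amplicon prediction for verification
   primer pairs;
7. **simulator** — toy fusion gene pairs with planted junctions
   (microhomology 0–5 nt, controllable frame) and substitution-error reads
   with a truth manifest, so every stage is testable without external data.

The canonical breakpoint rule assigns microhomologous bases to the 5'
partner: `donor_pos` is the donor coordinate of the last donor-matching
base, `acceptor_pos` the acceptor coordinate of the next read base. The
frame check is `(donor_pos − donor_cds_start + 1) ≡ (acceptor_pos −
acceptor_cds_start) (mod 3)`.

The package ships the published KAT6B-KANSL1 worked example (retroperitoneal
leiomyoma, t(10;17)(q22;q21)): the 20-nt search term
`TACCCCATGAGAAAGACCAG` (KAT6B exon 3 end, nt 1303–1322 of NM_012330.3), the
101 bp chimeric read it extracted, the published junction fragments and all
verification primer sets (`kat6b_kansl1_example()`), desk-scale references
built around the fragments (`worked_example_refs()`), and deterministic
coordinate-faithful synthetic stand-ins for the full-length reference mRNAs
(`synthetic_reference_models()` — random backbone, every published
coordinate landmark engineered and verified at build time; see the methods
vignette).

## Worked example

```r
library(anchorfusion)

reads <- example_fixture_reads(n_decoys = 100, seed = 1)  # 101 bp chimeric read among decoys
refs  <- synthetic_reference_models()
res <- run_pipeline(reads, refs$donor, refs$acceptor, k = 20, exons = 3,
                    acceptor_model = refs$acceptor,
                    primers = kat6b_kansl1_example()$fusion_primers)
print(res)
```

```
fusion pipeline: 101 reads, 2 anchors, 1 hits, 1 junction call [call]
         donor_id donor_pos      acceptor_id acceptor_pos orientation
1 KAT6B_synthetic      1322 KANSL1_synthetic         2715     forward
  microhomology_len insertion_seq support in_frame
1                 0                     1     TRUE
fusion_transcript KAT6B_synthetic:1322 | KANSL1_synthetic:2715
  length 3667 nt; donor exons 1-3; acceptor exons 11-15
  ORF 1389-2786 (1398 nt, 466 aa); in_frame = TRUE
```

Reading: among 101 reads the two exon-3-end anchors (forward +
reverse-complement of the 20-mer) extract exactly one read; its split
alignment places the junction at KAT6B nt 1322 / KANSL1 nt 2715; the
assembled fusion is 3667 bp, retains donor exons 1–3 and acceptor exons
11–15, carries a 1398 bp ORF encoding 466 residues, and the junction
preserves the reading frame. All four verification primer pairs give
exactly one product each on the fusion and none on either wild-type
transcript:

```r
res$amplicons[, c("pair", "start", "end", "length")]
#>                       pair start  end length
#> 1 MORF-1234F/KANSL1-2969R1  1234 1577    344
#> 2 MORF-1234F/KANSL1-2900R1  1234 1508    275
#> 3 MORF-1261F/KANSL1-2969R1  1261 1577    317
#> 4 MORF-1261F/KANSL1-2900R1  1261 1508    248
```

Against the desk-scale references of `worked_example_refs()` (the published
fragments in non-extending flanks, with the chromosome-17 genomic context
on the acceptor side), the same read splits with its donor-matching prefix
ending at read position 43 and the acceptor match extending back to
position 41 — a 3-base junction microhomology.

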