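Package: anchorfusion
Title: Targeted Gene-Fusion Discovery from RNA-Seq by Exon-Boundary Anchor Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Targeted discovery and characterisation of gene-fusion transcripts
    from raw RNA-seq reads. Exon-boundary anchor k-mers designed on a candidate
    transcript are matched exactly ("grep"-style) against FASTQ files in both
    orientations; anchor-containing reads are split-aligned by exact maximal
    extension against the candidate and a partner search set to localise the
    fusion junction and resolve junction microhomology; junction calls are
    aggregated, the chimeric transcript is assembled, its longest open reading
    frame and protein are predicted, reading-frame preservation is checked, and
    retained protein domains are reported. An in-silico RT-PCR layer predicts
    verification amplicons for primer pairs, and a read simulator with planted
    fusions provides truth sets for every pipeline stage. Includes the published
    KAT6B-KANSL1 (t(10;17)(q22;q21) retroperitoneal leiomyoma) worked example.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    rtracklayer,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
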