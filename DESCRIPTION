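Package: tilescan
Title: CRISPR Mutagenesis-Scanning Screens: Tiling Guide Libraries,
    Enrichment Scoring and Cut-Site Haplotype Calling
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for CRISPR-Cas mutagenesis scanning of drug-resistance
    hotspots. Designs exhaustive PAM-tiling guide libraries over coding exons
    for SpCas9 (NGG) and AsCpf1/Cas12a (TTTN), including exon-boundary
    extensions, gene-level deduplication, poly-T filtering, synthesizable
    oligo assembly, scrambled controls and sub-pool splitting. Quantifies
    guides in pooled-screen FASTQ, computes the adjusted log2 fold-change
    enrichment statistic with reads-per-million normalization, calls hits and
    intersects replicates. Aligns targeted amplicon reads, extracts cut-site
    window haplotypes, classifies alleles at the protein level with HGVS-like
    names, and computes per-position single-nucleotide variant spectra. A
    built-in NHEJ editing, drug-selection and sequencing simulator makes the
    whole pipeline testable at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
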