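---
title: "Mutagenesis scanning with tilescan: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mutagenesis scanning with tilescan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tilescan)
```

## The method

CRISPR mutagenesis scanning identifies the protein region a drug acts on by
brute force. A *tiling* guide library -- every PAM-adjacent site across the
coding exons of candidate target genes -- is transduced into Cas-expressing
cells, NHEJ repair of the cuts sprays small in-frame and frameshift mutations
across the proteins, and drug selection keeps only cells whose mutation
disables drug action while preserving protein function. Guides whose cut
sites enrich in the surviving pool point at the drug-binding residues;
amplicon sequencing of the cut-site locus then names the resistance alleles.

`tilescan` implements the four computational stages of this workflow (library
design, pooled-screen quantification, amplicon haplotype calling, and a
simulator that generates faithful synthetic inputs for all of them).

## Library design

For **SpCas9**, every N~21~GG site (20-nt protospacer + NGG PAM, 23 nt
total) is enumerated on both strands. Each CDS exon is expanded by 20 bp on
the 5\' side and 9 bp on the 3\' side *of the strand being searched* before
scanning, so guides straddling exon--intron boundaries are found; the wording
of the underlying protocol is ambiguous on the strand semantics, and we adopt
the per-strand symmetric reading (the plus- and minus-strand search spaces
are mirror images) because it is the only reading that catches boundary
guides on both strands. For **AsCpf1/Cas12a**, every TTTN~24~ site (TTTN PAM
5\' of a 24-nt protospacer) is enumerated, with a 25-bp expansion applied at
intron--exon boundaries only -- not at the CDS start/stop termini, which is
how the source protocol phrases it ("for each intron--exon boundary").
Overlapping expanded intervals are merged before scanning so short introns
are not enumerated twice.

Filtering follows the published protocol exactly: duplicate protospacers are
removed *per gene* (isoform annotations merged; the representative is the
5\'-most site in gene orientation, ties broken by plus strand), and any
protospacer containing `TTTTT` -- a Pol III terminator -- is dropped.
Identical protospacers in different genes are retained in both.

Oligos are `left_adapter [+ direct repeat] + protospacer + right_adapter`
with published totals of 60 nt (SpCas9) and 79 nt (AsCpf1); the AsCpf1 crRNA
carries the direct repeat `TAATTTCTACTCTTGTAGA` immediately 5\' of the
protospacer. The adapter *sequences* were not published, so fixed defaults
sized 20+20 (SpCas9) and 18+18 (AsCpf1) are built in and user-overridable.

Scrambled controls (the published libraries carried 100 sgRNA / 30 crRNA
controls) are produced by shuffling randomly chosen library protospacers
until the shuffle has no exact match anywhere on either strand of the
reference; generation is deterministic given a seed. Sub-pools are contiguous
alphabetical gene blocks (mirroring the published A/B split *ABL1--HDAC9* /
*IFNAR1--VEGFB*), chosen by an exact linear-partition DP that minimizes the
largest pool while keeping each gene whole.

**Cut-site convention.** The canonical SpCas9 cut is blunt, between
protospacer positions 17 and 18 (3 bp 5\' of the PAM). For AsCpf1 the cut is
staggered with a 4-nt 5\' overhang; we record the non-target-strand nick
after protospacer position 18 as the canonical coordinate and keep the
overhang as profile metadata. Both are standard enzymology; the source only
marks cut sites graphically.

## Pooled-screen quantification

Reads are anchored on the constant cassette sequence 5\' of the protospacer
(first exact occurrence), the following protospacer-length bases are
extracted and counted on exact match to the library. No mismatch rescue is
attempted: the protocol states none, and exact counting is reproducible.
Reads per million (RPM) are normalized to *assigned* reads, which makes the
statistic invariant to junk-read contamination (the protocol is silent on
the denominator).

The enrichment statistic is the adjusted log~2~ fold change

$$\log_2 \frac{1 + \mathrm{RPM}_{\text{after drug}}}{1 +
\mathrm{RPM}_{\text{after puromycin}}}$$

with the +1 pseudocount on RPM, following the protocol's displayed equation.
Some of the published dot plots instead add 1 to each raw read count before
normalization; `enrichment(..., pseudocount_on = "count")` reproduces that
convention. Hits are guides whose adjusted fold change exceeds 100 (the
published threshold for the bortezomib screen; the other screens print no
numeric cutoff, so the same default is applied). Replicate hit lists are
intersected by guide id with a per-gene rollup.

## Amplicon haplotype calling

Reads are aligned semi-globally (read global, amplicon local) with affine
gaps. Defaults -- match +2, mismatch −3, gap open −8, gap extend −1, 70%
identity floor -- are not stated in the source; they were chosen to tolerate
the ≤17-bp indels this assay produces while rejecting junk, and all are
configuration keys. Mate 2 is reverse-complemented before alignment. Mates
must tell the same story wherever their coverage overlaps; discordant pairs
are discarded and tallied. This is stricter than only comparing inside the
haplotype window, and it matters: a read ending one or two bases past an
indel inside a repeat aligns better as substitutions than as a gap, and the
coverage-overlap rule catches exactly these cases. How the original analysis
handled mate conflicts is unstated; discard-on-conflict is our decision.

The haplotype window spans `[cut − upstream, cut + downstream)` with each
arm restricted to 15--70 bp (total 35--140 bp, as in the source); the
default 35/35 is the midpoint of the supported span. Only reads fully
spanning the window count; an allele is the exact op list (deletions,
insertions, substitutions) restricted to the window, with straddling indels
kept whole. Indels are left-aligned through repeats, the standard variant
normalization, so equivalent gap placements merge into one allele. Allele
frequencies are relative to spanning reads and sum to 1 before filtering;
the default display threshold is 0.5% (some published panels use 1%), with
removed mass reported as "other".

**Protein-level classification.** An allele touching no coding base is
`noncoding` and described at the nucleotide level (such intronic alleles
exist in the source data and are never translated). Otherwise the net coding
indel decides: not divisible by 3 is `frameshift` (`G383fs`); else the
mutant CDS is spliced through the codon map (strand-aware) and translated.
A stop internal to the mutant protein is `nonsense`; an unchanged protein is
`silent` (named like `S301S`) or `WT`. Remaining cases are named HGVS-like
by trimming the common prefix and suffix of the reference and mutant
proteins: `G383del`, `D130_L132del`, `V166_K167insL`, per-residue
substitution lists (`C528S,E529V,Q530H,K531I`), and `delins` for combined
changes. Protein numbering is 1-based from the initiator Met of the isoform
attached to the amplicon -- names are isoform-dependent by construction.

The four-way display rollup {wild-type, in-frame, frameshift, nonsense} is
an inference (the source does not enumerate its categories in text) and is
isolated in one mapping table inside `mutation_type_summary()`; non-coding
mass is reported separately. Per-position SNV spectra report the frequency
of each base and of deletion among covering reads; the variant frequency of
a position is one minus the reference-base frequency.

## The simulator: what it emulates and what it does not

`nhej_model()` draws, per cell: edited or not (`p_edit`, default 0.8, a
typical transient-Cas9 editing efficiency); then deletion / insertion /
substitution with probabilities 0.55 / 0.25 / 0.10 (remainder: precise
repair). These class weights are modelling choices in the range the source
reports across loci; the source also shows strong locus-specific asymmetries
(one locus almost all deletions, another mixed) which the simulator does not
attempt to learn. Indel lengths are truncated geometric (deletion mean 4,
max 17 -- the largest deletions observed; insertion mean 2, max 10);
lesion starts are uniform in the 17 bp upstream of the cut, matching the
observed localization of mutations upstream of the SpCas9 cleavage site.
Deletion ends are clipped at `cut + max_ins`: unclipped geometric deletions
starting upstream could reach 16 bp past the cut, which would contradict
both the observed localization and the package's own footprint invariant,
so the lesion window is closed on the right as a modelling decision.

Selection is binary (an allele survives drug iff it is an in-frame protein
change touching a hotspot codon), because colonies-versus-none is the
phenotype the method reads out; no growth kinetics are modelled. In an
essential gene, frameshift and nonsense alleles are lethal unless the cell
escapes with probability `diploid_escape` (default 0.02) -- haploid lines
spontaneously diploidize and retain a wild-type copy, which is how the
source explains the frameshift alleles it observes.

`simulate_screen()` works at the *categorical* level (outcome type and
length per integration, not nucleotide-resolved lesions): a hotspot-capable
guide produces a resistance allele when the outcome is an in-frame indel or
a substitution. Sequence-resolved editing is exercised separately by
`simulate_editing()` + `simulate_amplicon_reads()` on a real amplicon; the
screen generator only needs the *rank structure* of the read pools, and the
categorical shortcut keeps 10^5^-cell screens fast on one CPU. Integration
counts are Poisson (published MOIs: 0.25 SpCas9, 0.35 AsCpf1); cells with
two or more guides carry their extra guides into the surviving pool at full
read weight, reproducing the double-transduction false-positive mechanism
the source describes (a co-transduced passenger guide enriching alongside
the causal one) for tests of replicate-intersection filtering.

Desk-scale note: the published screens ran at 5000× coverage per guide
(~10^6^ cells); the test suite runs 200-guide screens at 20,000 cells and
10^5^ reads per pool to stay within CI budgets. All generator defaults are
the stated conditions above, independent of any test outcome.

What a green test establishes: the pipeline recovers, at binomial accuracy,
exactly the alleles and guide enrichments the generator planted, under
uniform sequencing error and perfect cassette structure. What it does not:
PCR duplicates and chimeras, base-quality variation, locus-specific repair
profiles, microhomology-mediated joining, and growth-rate selection are all
out of scope, so real-data performance on those axes is untested.

## Numerical choices and degenerate inputs

* Coordinates are 0-based half-open everywhere internally; 1-based only in
  GFF3/GenBank I/O and human-facing variant names.
* Guide enumeration skips sites containing `N` (unsynthesizable).
* Ties in dedup representatives are broken deterministically (position, then
  plus strand); the whole designer is byte-reproducible for a fixed seed.
* `enrichment()` reports guides absent from both pools as `log2_fc = 0`
  rather than dropping them, conserving library accounting.
* Zero assigned reads, empty FASTQ, windows outside the amplicon, and
  adapter/oligo length mismatches are hard errors or loud warnings, never
  silent.
* Frequencies are exact rationals of read counts; conservation (allele
  frequencies summing to 1, rollup mass equal to retained mass) is asserted
  to 10^−9^ in the tests.

## Known limitations

* The GenBank reader is minimal (single-record files, `join`/`complement`
  CDS locations, `/gene` and `/locus_tag` qualifiers) -- enough for
  annotation fixtures, not a general parser. GFF3 I/O uses rtracklayer.
* Off-target and on-target efficiency scoring are deliberately absent (the
  source used none).
* Nonsense variants arising downstream of in-frame indels are numbered in
  mutant coordinates, which can differ from reference numbering by the
  indel's codon count.
* `read_len` in the amplicon simulator must let the mate pair cover the
  amplicon contiguously (`length ≤ 2 × read_len`); longer amplicons need
  longer reads, as on a real sequencer.
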