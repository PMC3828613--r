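---
title: "Methods: coverage-based transcript detection in rRNA-dominated EV libraries"
author: "evrnaseq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based transcript detection in rRNA-dominated EV libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evrnaseq)
```

# The problem

RNA sequencing of exosomes (30–130 nm extracellular vesicles) differs from
cellular RNA-seq in one dominant respect: although intact ribosomal RNA is
nearly absent from vesicle preparations, the libraries are overwhelmingly
rRNA-derived — on the order of 97% of reads — because the rRNA is present
as fragments spanning the entire length of the 28S, 18S, 5.8S and 5S
subunits. Fragment-based depletion probes miss most of these pieces. The
practical consequences for analysis are:

* the non-rRNA signal is a few percent of the library, so per-transcript
  read depth is very low;
* with low depth, RPKM-based presence calls (RPKM > 1 in at least one
  sample) are driven by small read piles on short stretches of a
  transcript and misannotate heavily;
* any credible detection rule must therefore look at *how much of the
  transcript* the reads cover, not how many reads landed somewhere on it.

`evrnaseq` implements this workflow: partition reads against the rRNA set
before genome alignment, filter the genome alignments conservatively,
detect transcripts by covered fraction of their CDS (coding) or exon union
(non-coding), quantify isoforms by EM, and compare gene sets with
enrichment and rank-sum statistics.

# Stage-by-stage model

## Read QC

Adapter trimming removes the longest read suffix that exactly matches a
prefix of the adapter, requiring at least `min_overlap` (default 5) bases;
no mismatches are tolerated. An error-tolerant matcher would trim slightly
more read-through at the cost of bit-unstable behaviour; with the exact
rule every trim is reproducible and testable by enumeration. Quality
trimming removes the maximal trailing run of bases below the Phred
threshold (default 15). The minimum length after trimming defaults to 6
bases: these libraries legitimately contain very short informative reads,
and short spurious alignments are handled later by the aligned-length
filter rather than by discarding raw reads. Instrument-level filters
(polyclonal wells, off-scale signal) exist only upstream of FASTQ; they are
carried in the QC report as an explicit zero-count stage so the read
funnel is complete.

## rRNA partition

Fragmented rRNA is a *contiguous* substring of a subunit, so the matcher is
ungapped by design: a read matches a subunit if the whole read can be
placed at some offset, in either orientation, with at most
`max_mismatches` (default 2) substitutions. Matching is seed-and-extend:
k-mers of length 12 at `max_mismatches + 1` disjoint offsets guarantee, by
pigeonhole, that every qualifying placement of a read of at least 36 bases
is examined; shorter reads fall back to an exhaustive scan. Ties are
resolved deterministically (fewest mismatches, then subunit name, then
offset, forward orientation preferred). Both orientations are searched
because library strandedness is not assumed. The matcher is verified
against an exhaustive all-offsets Hamming-scan oracle in the test suite.

Reads with a hit leave the pipeline here; everything downstream sees only
the remainder. Per-base density profiles (depth = number of hits covering
each base) confirm the full-length tiling of each subunit, and per-subunit
read fractions summarise the rRNA species mix.

## Alignment post-processing

The pipeline consumes spliced genome alignments (SAM/BAM) produced
externally — or, for testing, the simulator's ground-truth alignments.
CIGAR `N` runs split an alignment into blocks; `D` consumes reference
within a block; `I`, `S`, `H` consume none. Three filters run in a fixed
order so the funnel counts are well defined:

1. remove all records of any read reported at more than one location
   (NH tag, or grouping by read id when NH is absent);
2. remove records whose *aligned reference length* is below 20 nt — the
   wording "short aligned reads" makes aligned length, not raw read
   length, the filtered quantity, and the two differ under soft clipping;
3. remove records with MAPQ below 10.

A record failing several filters is counted once, at the first stage that
catches it. Conservation (`input = removed + kept`) is exact and asserted
on randomized inputs.

Kept reads are labelled `known_gene` if any block overlaps any annotated
exon by at least one base, else `unknown`. The exon-level rule (rather
than transcript-span overlap) is the stricter reading of "overlaps
annotated gene models" and is the package's chosen convention; strand is
ignored because strandedness of the protocol is unspecified (a stranded
mode would be a straightforward extension of the same overlap machinery).

## Coverage detection

For each transcript the target is the CDS union for protein-coding
biotypes and the exon union otherwise. The covered fraction is

> |union(blocks) ∩ union(target)| / |union(target)|

with overlapping reads counted once. Rules, both read literally as strict
inequalities ("over 90%", "> 50%"):

* **cellular**: detected iff fraction > 0.9;
* **exosomal**: the exosomal samples' blocks are pooled; detected in
  sample S iff pooled fraction > 0.9 AND S's own fraction > 0.5. The
  pooled gate borrows power across vesicle samples (each is only ~2%
  usable reads) while the per-sample gate keeps the call sample-specific.
  The sentence defining this rule admits more than one reading; the
  AND-of-two-gates interpretation is isolated in `detect_exosomal()` so it
  can be swapped without touching anything else.

A gene is detected iff any isoform is detected; the maximum isoform
fraction is reported. Coverage is deliberately computed per transcript,
so a read in an exon shared by two isoforms contributes to both — double
counting across transcripts is intended for a *presence* criterion;
apportioning ambiguity is the quantifier's job, not the detector's.

## EM quantification

Reads are assigned to isoforms via a binary compatibility relation: every
block inside the isoform's exon union, and every junction implied by the
read's block gaps coinciding with an isoform intron within `tolerance`
bases (default 0). The likelihood model is the standard mixture: a read
from isoform *i* is uniform over its effective length ℓᵢ, taken as the
spliced transcript length with no fragment-length correction — the
simplest defensible choice, stated openly rather than imitating any
particular tool's internal correction. EM from a uniform start:

* E-step: read mass to isoform *i* ∝ θᵢ/ℓᵢ over compatible isoforms;
* M-step: θᵢ ∝ Σ mass;
* stop at max |Δθ| < 10⁻⁸ or 1000 iterations.

Mass is conserved at every iteration and the log-likelihood is
non-decreasing; both are asserted in tests, and θ is checked against an
exhaustive simplex grid search on small fixtures. The EM is run on the
whole compatibility matrix at once: reads cannot be compatible with
isoforms of non-overlapping genes, so the result is identical to running
per connected component, without the bookkeeping.

RPKM = 10⁹·mass/(ℓ·total). The denominator is the number of post-filter
genome-mapped reads, excluding the rRNA partition — quantification happens
after rRNA removal, and including a 97% rRNA load in the denominator would
make exosomal RPKMs incomparable with cellular ones. Whether to include
rRNA reads is nevertheless exposed (`total_mapped`), since conventions
differ.

## Statistics

* **EASE-adjusted Fisher test**: the one-sided hypergeometric upper tail
  with the list-hit cell reduced by one, P(X ≥ k−1), so single-gene hits
  can never look enriched (k ≤ 1 gives p = 1). Categories need at least 5
  list hits to be tested; Benjamini–Hochberg correction runs across the
  tested categories and q < 0.05 defines the strongly enriched set. The
  annotation is a user-supplied table — no live ontology queries, no
  redundancy trimming.
* **Rank-sum test**: midranks for ties; exact null enumeration when the
  pooled size is ≤ 12 with no ties, otherwise the normal approximation
  with tie and continuity corrections. The exact branch is verified
  against full enumeration of rank assignments.
* **2^−ΔΔCt**: ΔCt = Ct(gene) − Ct(control) per sample, ΔΔCt relative to a
  calibrator; the calibrator's fold change is exactly 1.

# The synthetic-data generator

The generator's defaults are the study conditions, not tuning knobs:

| parameter | exosome-like | cell-like | why |
|---|---|---|---|
| rRNA fraction | 0.97 | 0.24 | the observed library compositions |
| intergenic fraction | 0.01 | 0.18 | yields ~2% vs ~58% known-gene reads |
| fragment length | uniform 30–500 nt | same | the observed RNA size range; only a range is known, so uniform |
| reads | 20 000 | 20 000 | scale at which binomial recovery bands are tight (~0.4%) yet a full run takes seconds |
| quality model | Q36, 5-base decaying 3′ tail | same | enough to exercise 3′ trimming |
| adapter | 13-mer at rate 0.15 | same | enough to exercise adapter trimming |
| substitution errors | 0 | 0 | error tolerance is tested separately at the matcher level |

The toy reference is a 60 kb chromosome of i.i.d. uniform A/C/G/T with ten
genes: four coding (one with two isoforms sharing exons, so EM has real
ambiguity to resolve) and six non-coding spanning the small-RNA biotypes
that dominate vesicle libraries (snoRNA, snRNA, miRNA, Mt_tRNA, lincRNA,
misc). Two genes carry zero abundance in every profile and serve as
negative controls for detection. rRNA subunit analogs (1900/900/160/120 nt,
mixed 5:4:0.5:0.5 toward the large subunits) are generated independently
of the genome, mirroring the separate rRNA reference of the real
workflow; a fragment position is uniform over the subunit, which produces
the full-length tiling in expectation. Truth alignments are emitted as
SAM with N-gapped CIGARs so the pipeline runs without an external spliced
aligner; rRNA-origin reads are emitted unmapped because the genome never
sees them.

What the simulation does *not* emulate — and hence what passing tests do
not certify about real data: platform-specific error modes (homopolymer
indels), biased fragmentation, repeat structure and multi-mapping genuinely
caused by genome repeats (multi-mapping is exercised through constructed
records instead), expression-dependent coverage bias, and real annotation
pathologies (overlapping genes on opposite strands are present in the toy
set only via shared-exon isoforms). The end-to-end tests certify the
*bookkeeping and the rules*, not aligner behaviour.

# Numerical and design choices

* **Coordinates**: 1-based closed intervals (IRanges/GenomicRanges
  conventions) everywhere inside the package; GTF is 1-based on disk, BED
  output converts to 0-based half-open at the boundary. Using the
  ecosystem's native interval algebra for every union/intersection removes
  the usual off-by-one risk rather than re-deriving it in a second
  convention.
* **Strict thresholds**: "over 90%", "> 50%", "RPKM > 1", "q < 0.05" are
  all strict; boundary cases are pinned by tests on both sides.
* **Tie-breaks**: the rRNA matcher orders candidate placements by
  (mismatches, subunit name, offset, orientation); gene-level biotype
  conflicts resolve to the lexicographically smallest label with a
  warning; all string orderings use locale-independent (radix) sorting so
  outputs are byte-identical across environments.
* **Degenerate inputs**: empty libraries, header-only SAM, empty gene
  sets, categories with no qualifying hits and zero-coverage transcripts
  all produce well-formed empty outputs rather than errors; genuinely
  impossible inputs (CDS outside exons, malformed CIGAR, fragment range
  longer than every source) fail fast with the offending record named.
* **Determinism**: a single integer seed drives reference and library
  generation; identical inputs give byte-identical FASTQ/SAM/TSV outputs,
  asserted by checksum in the tests.

# Problem sizes used in the checks

The bundled checks run the full pipeline on one cell-like plus two
exosome-like libraries of 20 000 reads each, verify class-fraction
recovery within 3 binomial SD, coverage against a per-base boolean oracle
on 500 random transcript/block fixtures, funnel conservation on 1000
random record sets, EM against grid search on 2–3-isoform fixtures of at
most 200 reads (and θ recovery within 0.05 from 5000 simulated reads),
the EASE test against tail enumeration for every table with a universe of
at most 60 genes, and the rank-sum exact branch against full enumeration
of every split of ranks 1..10. These sizes were chosen so each property
is tested at a scale where its failure modes (off-by-one coverage,
mass leakage in EM, funnel miscounts) would be visible, while a complete
run stays in the minutes range on a single CPU.

# Known limitations

* The rRNA matcher is ungapped and full-read; reads spanning a true
  deletion in rRNA, or chimeric fragments, fall through to the genome
  stage.
* Effective length ignores fragment-length distribution, biasing θ
  slightly for isoforms of very different lengths at realistic fragment
  sizes; the recovery test bounds this at the simulated conditions.
* The exosomal detection rule's pooled gate means a transcript can be
  "detected" in a sample contributing just over half its coverage; that is
  the rule as stated, not an inference about abundance.
* Enrichment results depend entirely on the supplied category table;
  nothing is done about category redundancy.
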