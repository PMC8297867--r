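---
title: "Methods: comparative mitogenome structure analysis"
author: "mitostruct"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative mitogenome structure analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its models and the design
choices behind them: what each stage computes, which parameters matter,
what the synthetic-data generators do and do not emulate, and where the
numerics make a choice that a different implementation could make
differently.

## Genomes, gene orders and intron cataloguing

A genome is a single chromosome (circular by default, as assembled plant
mitogenomes are reported) with gene features; each feature is a gene
symbol, a category (protein-coding, tRNA, rRNA), a strand and an exon
list in transcript order. External coordinates are 1-based inclusive, the
dialect of both GenBank and GFF3; the internal representation stores
exactly those coordinates so I/O is lossless. Features whose location
wraps the origin (`join(950..1000,1..60)`) are kept as two internal
intervals and flagged; the wrap junction is treated as sequence
continuity, not an intron.

The signed gene order of a genome lists the genes of the included
categories by the coordinate of their first exon, signed by strand. Three
conventions matter for comparability:

* duplicated genes become distinct markers `name#1`, `name#2`, … in
  coordinate order (the numbering is per-genome coordinate rank only —
  homology of copies across genomes is *not* asserted here);
* each contiguous exon group of a trans-spliced gene is an independent
  marker `name_segK`, `K` in genome-coordinate order of the segments. The
  grouping comes from an explicit `segment` annotation when available and
  is otherwise inferred by breaking the exon chain where the strand flips
  or the coordinates stop being monotonic in transcript direction;
* pseudogenes, plastid-/nuclear-derived copies and categories outside
  {PCG, tRNA, rRNA} are excluded.

Intron records are cis (one per inter-exon gap inside a contiguous locus,
with `length = acceptor − donor − 1`) or trans (one per junction between
disjoint segments, with no meaningful length). Donor and acceptor are
reported in genome-forward orientation — donor is the last exon base left
of the intron — so the length identity holds on both strands; the strand
is carried in its own column. When the annotation supplies a published
intron ID (`nad1i394` style) it is kept verbatim; otherwise the ID is the
gene plus `i` plus the 1-based position of the last spliced-CDS base
before the intron *within this genome's own CDS*. The published
nomenclature is defined against a cross-species reference alignment that
this package does not reconstruct, so recomputed IDs are comparable only
within a genome.

## DCJ rearrangement distance

Gene orders are compared under the double-cut-and-join model. Each marker
contributes two extremities (tail, head); a circular order induces one
adjacency per consecutive marker pair. For two genomes over the same `n`
single-copy markers the adjacency graph (one edge set per genome over the
shared extremities) decomposes into cycles, and the distance is `n − c`
with `c` the cycle count; with both chromosomes circular no paths arise.
Distances are integers — minimal operation counts — matching how
rearrangement counts are reported.

Because the model needs equal single-copy content, every pair is first
reduced: per-genome duplicate suffixes are stripped and a symbol is kept
only if it occurs exactly once in *both* genomes; everything else is
dropped with a logged reason. This is the most conservative reduction
consistent with treating duplicates and trans-segments as independent
markers, and the per-pair shared-marker count is recorded in the distance
matrix so the effect of the reduction stays visible. Pairs with an empty
shared set are recorded as missing, never fabricated. We compute the
parsimony (minimal-distance) DCJ; no likelihood weighting of operations
is involved anywhere in the computation.

The test oracle is a breadth-first search over adjacency-set states: a
DCJ operation cuts two adjacencies and rejoins the four extremities
either way. Order A is relabelled to the identity genome (a bijection on
extremities that preserves marker edges), so one exhaustive BFS per
marker count serves all pairs; the table is cached. The guard `n ≤ 8`
keeps the state space (perfect matchings on 2n points) enumerable.

The heatmap view is linear-scale, shared across cells, with missing cells
grey, and accepts an externally supplied (e.g. phylogeny-derived) leaf
order; tree inference itself is out of scope.

## Dispersed repeats

The unit is the **maximal exact repeat**: a sequence of length ≥
`min_length` (default 50 bp) with at least two genomic occurrences —
counting reverse-complement occurrences when inverted matching is on —
whose occurrence set is left- and right-diverse, i.e. the sequence cannot
be extended on either flank without losing an occurrence. Exact identity
makes the definition, the seed-and-extend implementation and the
full-enumeration oracle agree symbol for symbol; near-identical repeat
families (as a self-BLAST at ~100% identity would merge) are deliberately
out of scope, and published repeat counts obtained that way are not
expected to reproduce under strict exactness.

Reporting follows unique-sequence accounting: one family per distinct
sequence, totals summing family lengths once each, not genomic footprint.
Occurrences abutting within one period are tandem copies and are excluded
from dispersed families (tandem-repeat detection proper is a separate
concern handled by dedicated tools). When a shorter maximal repeat lies
inside a longer one at every occurrence it is suppressed to avoid double
counting nested seeds. Circular genomes are scanned with the first
`min_length − 1` bases appended, so wrapping occurrences are found; a
wrapped occurrence reports `end > genome length`. The size histogram uses
the short/intermediate/large classes (<100, 100–900, >1000 bp); the
unassigned 901–1000 band is counted with the intermediate class.

The seed-and-extend discovery enumerates duplicated `min_length`-mers and
extends only left-maximal seed pairs, so each maximal pair is generated
exactly once. Runtime is governed by the number of duplicated seeds; on
low-complexity (e.g. long homopolymeric) sequence the pair lists grow
quadratically, which is acceptable at the tested scales (genomes to a few
tens of kb) but untuned for megabase inputs.

## Bpu-like element scanning

The published blast-based search is replaced by its stated acceptance
criterion applied directly: a semi-global alignment of the full 36-bp
consensus against any genomic window, unit costs for substitutions,
insertions and deletions, accepted at edit distance ≤ 7. This also admits
exact truncated copies down to 29 bp (each lost consensus base costs one
deletion), which is exactly the published truncation class. The DP runs
vectorized over text positions (36 rows of vector operations per strand);
ambiguous bases count as mismatches, with a warning when they exceed 5%
of the genome.

Hit resolution: every end position within the bound is a candidate; the
start is the **tightest** window achieving the minimal distance (so an
exact truncated core is not padded with cost-neutral flank columns);
overlapping candidates are resolved greedily by ascending edit distance,
then ascending start, then `+` strand first. Classification is by
sequence identity: equal to the consensus → dominant-exact; equal to a
contiguous consensus substring of 29–35 bp → truncated-exact (which end
is truncated is unconstrained); otherwise variant. Circular genomes
append `36 + max_edits − 1` bases so origin-spanning copies are seen
once.

Cross-genome site orthology pairs hits whose flanks (50 bp each side,
element excluded, read in element orientation) are reciprocal best
matches at ≥ 90% edit-distance identity.

## Plastid-derived insertions

The alignment engine is NCBI blastn (`-task blastn`) with match +2,
mismatch −3, gap open 5, gap extend 2 — the scoring under which the
conventional E ≤ 1e-6 threshold is meaningful. Word size defaults to 11;
the permissive word size 7 used for organellar homology scans is a flag.
An insertion is one reported local alignment after containment removal
on the mitochondrial intervals (no chaining of nearby alignments into
loci). Genes natively shared by both compartments are masked before
reporting, so their cross-hits are not mistaken for transfers. Summaries
report both the union of mitochondrial intervals (non-redundant inserted
sequence) and the sum of alignment lengths (the accounting usually quoted
for insertion totals; gap columns make it slightly larger), with the
genome fraction from the union. Circular inputs get a 500-bp origin wrap
appended on both sequences; junction-spanning homology longer than that
is split, a limitation accepted at the tested scales.

## RNA editing

Evidence is a per-site pileup over each CDS on its coding strand: RNA
depth and per-base counts, optionally the same from genomic DNA reads. A
SAM adapter (via Rsamtools) produces this table from read alignments.
Calling is deliberately simple and fully parameterized, standing in for
manual curation: a site is called when the reference base is C, RNA depth
≥ 10 and the T fraction ≥ 0.1; a candidate is removed as a genomic SNP
when DNA reads support a non-reference base at ≥ 0.2 with depth ≥ 10;
candidates without DNA evidence are kept but flagged unverified. Only
C→U events are ever called.

Classification translates the codon before and after the edit under the
standard genetic code (the code plant mitochondria use), labels
conversions (`Pro->Leu`), and maps amino acids onto a configurable
hydropathy partition. The default partition counts {A, V, L, I, F, M, W,
C} as hydrophobic and everything else — including Pro, Gly and Tyr — as
hydrophilic, the assignment under which the canonical plant editing
conversions (Pro→Leu, Ser→Leu, Ser→Phe) read hydrophilic→hydrophobic.
Edits creating a stop codon are labelled `…->Stop` and excluded from
hydropathy proportions. The per-gene editing frequency is
`100 × edited sites / gene length`, scale-exact by construction.

Prediction lists (from in-silico editing predictors, which emit
non-silent sites only) are compared by site key: shared, predicted-only
and empirical-only partitions, silent empirical sites reported
separately, and the confirmed total counted as shared non-silent plus
empirical silent sites. Prediction itself is an input, not a computation
of this package.

## Synthetic data: what it does and does not emulate

Backgrounds are i.i.d. uniform nucleotides with a GC knob (default 0.47,
the GC content range of the study system); where a test requires that
*only* planted signal exists, the background is resampled until it is
repeat-free at a stated k. Generators plant: dispersed repeat families
(fresh random units, distinct forced flanking bases so planted boundaries
are maximal-repeat boundaries), motif copies at exact edit distances
(mutations re-drawn until the realized distance verifies), gene plans
with cis introns and trans-split genes, plastid segments copied at a
controlled substitution-only identity, and editing datasets with
binomially drawn read counts (sequencing-error knob, default 0) plus
genomic C→T SNP confounders present in both DNA and RNA reads. Every
generator is deterministic under (specification, seed) and returns a
manifest sufficient to compute expected outputs without re-running.

What passing on this synthetic data shows: the detectors implement their
definitions exactly (oracle equivalence), recover planted truth at the
stated signal levels, and are deterministic. What it does not show:
robustness to annotation errors, to mosaic or near-identical repeat
structure, to alignment artifacts in real read data, or to the curation
judgement embedded in published manual counts.

## Problem sizes and numerical choices

The test suite and the acceptance script size their simulations to run
comfortably on one CPU: 1,000 sampled order pairs at n ≤ 6 against the
BFS oracle (plus 300 in the script), 100-seed k-operation recovery at 40
markers, 100 (60 in the script) random ≤ 5 kb genomes against the repeat
oracle at min lengths 10/20/50, 100 (60) planted genomes against the
motif-scan oracle at edit bounds 0/3/7, and 20 editing datasets of 10 ×
900-bp CDS with 200 planted edits and 5% SNP confounders. These sizes
were chosen as the smallest at which the properties are exercised across
their parameter ranges, not tuned to any observed outcome.

Tie-breaks and degenerate inputs are fixed as follows: motif hits resolve
ties by (edit distance, start, strand), with the tightest minimal window
per hit; repeat families order by descending length then sequence;
marker-universe reduction errors out (naming both genomes) when nothing
is shared; zero-length sequences, empty exon lists, overlapping exons
within a feature, invalid word sizes and non-positive gene lengths are
rejected at the boundary with specific messages. Editing thresholds,
hydropathy partition, alignment scoring and the consensus sequence are
all exposed in the run configuration; the configuration is echoed with
every run so no effective parameter is silent.

## Known limitations

* Exact-identity repeat families only; no identity-thresholded merging.
* DCJ on single circular chromosomes; linear or fragmented genomes and
  scenario (operation-sequence) reconstruction are out of scope.
* The marker reduction discards information for genomes with extensive
  duplication; distances between such genomes are computed over fewer
  markers, and the matrix records how many.
* Recomputed intron IDs are per-genome, not alignment-anchored.
* The origin wrap for the plastid search is bounded (500 bp).
* The editing caller trusts its pileup input; mapping bias and strand
  errors must be handled upstream.
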