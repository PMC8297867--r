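# mitostruct

Comparative structural analysis of plant mitochondrial genomes in R.

Plant mitogenomes — and gymnosperm mitogenomes in particular — evolve by
structural rearrangement far more than by point mutation: gene order is
shuffled by repeat-mediated recombination, short mobile elements expand in
some lineages, plastid DNA is captured into the chromosome, group II
introns shift between cis- and trans-splicing, and transcripts are
post-transcriptionally edited (C→U). `mitostruct` packages the analyses a
comparative organellar-genomics study runs over these signals, each one
exercisable end to end on synthetic genomes with known ground truth:

* **Gene orders and DCJ rearrangement distance.** Signed circular gene
  orders are extracted from annotated genomes (GenBank or FASTA+GFF3;
  duplicated genes and trans-spliced gene segments become independent
  markers). The pairwise rearrangement distance uses the double-cut-and-join
  (DCJ) model: for two circular genomes over the same `n` single-copy
  markers, `d = n − c`, where `c` is the number of cycles of the adjacency
  graph built from the two genomes' marker-extremity adjacencies. A
  breadth-first-search oracle over all single DCJ operations certifies the
  formula in the tests.
* **Dispersed repeats (≥ 50 bp).** Maximal exact repeat families (direct
  and inverted), counted as unique sequences, with tandem-adjacent copies
  excluded — the "repeats of unusual size" accounting used for
  mitogenome repeat tables.
* **Bpu-like mobile elements.** A 36-bp consensus
  (`AAGGTTATCCCTTTCCTGAGCGTAGCGAAGGGAAGG`, AAGG terminal repeats, Bpu10I
  site at nt 15–21) is scanned semi-globally on both strands under a
  bounded unit-cost edit distance (default ≤ 7, insertions and deletions
  included), and hits are classified as dominant-exact, truncated-exact
  (29–35 bp identical substring) or variant.
* **Plastid-derived insertions (MTPTs).** Local alignment of the
  mitogenome against a plastid genome (NCBI blastn, +2/−3 match/mismatch,
  gap 5/2, E ≤ 1e-6), with genes natively present in both compartments
  (atp1/atpA, rpl16, rps4, rrn26/rrn23, rrn18/rrn16) masked out, and
  Table-style reporting of identity, coordinates, E-value and overlapped
  plastid genes.
* **Intron catalog.** Cis introns per inter-exon gap (with lengths and
  genome-forward donor/acceptor coordinates) and trans introns at the
  junctions of disjoint gene segments.
* **C→U RNA editing.** Empirical site calling from CDS pileups (reference
  C, RNA T fraction ≥ 0.1 at depth ≥ 10), genomic-SNP filtering against
  DNA reads, codon-level classification (position, amino-acid change,
  silent flag, hydropathy transition), per-gene editing frequency
  `100 × edited sites / gene length`, and concordance with an external
  prediction list.
* **Synthetic data.** Deterministic generators that plant repeats, motif
  copies at exact edit distances, DCJ-scrambled gene orders, plastid
  transfers at controlled identity, and editing datasets with SNP
  confounders — every planted object recorded in a truth manifest.

## A worked example

```r
library(mitostruct)

# simulate an annotated circular genome and scramble its gene order
sim  <- simulate_genome(20000, n_genes = 12, seed = 1)
base <- extract_gene_order(sim$genome)
derived <- apply_dcj_ops(base, k = 3, seed = 2)$order
derived$genome_id <- "derived"
dcj_distance(base, derived)$distance
#> [1] 3

# plant a dispersed repeat family and recover it
g  <- mt_genome("demo", repeat_free_dna(10000, 20))
pr <- plant_repeats(g, list(list(length = 120, copies = 2)), seed = 5)
fam <- find_exact_repeats(pr$genome, min_length = 50)
summarize_repeats(fam, pr$genome$length)[c("family_count", "total_unique_length")]
#> $family_count
#> [1] 1
#> $total_unique_length
#> [1] 120

# scan for the Bpu-like consensus
hits <- scan_motif(pr$genome, bpu_consensus())
classify_hits(hits)$summary$total
#> [1] 0        # none planted in this genome
```

The first number is the minimal count of double-cut-and-join operations
separating the two circular gene orders; the repeat summary counts each
unique repeated sequence once (120 bp here) regardless of copy number.

The same stages run from the shell through the bundled entry point:

```sh
exec/mitostruct simulate --out run1 --seed 5   # synthetic bundle + manifest
exec/mitostruct all --out run2 --seed 5        # simulate, then every stage
```

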