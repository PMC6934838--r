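# trimscape

Structural discovery and evolutionary analysis of **TRIM elements**
(terminal-repeat retrotransposons in miniature) in genome sequences.

TRIMs are small (<1000 bp) non-autonomous LTR retrotransposons: two
terminal direct repeats (TDRs, the LTR equivalents, here 202–218 bp)
flank a short internal domain (here 77–80 bp) that ends in a polypurine
tract (PPT) and canonically begins with a primer binding site (PBS)
complementary to a tRNA. Because TRIMs encode no proteins, they can only
be found structurally — by their repeats, their unit layout and their
inner-domain features — which is what this package does. It is aimed at
repeat annotators and molecular evolution researchers working on
genomes, such as the bivalve genomes where animal TRIMs have recently
been characterised, who need the whole chain from raw similarity hits to
classified insertion loci, genome-contribution statistics and
repeat-family phylogenetics in one reproducible, testable toolkit.

## What it computes

* **Seeded similarity search** (a deterministic blastn stand-in):
  k-mer seeds, diagonal chaining, affine-gap local-DP extension
  (match +2, mismatch −3, gap −5 − 2·L); hits kept at identity ≥ 0.75
  and length ≥ 100 bp, both strands, forward-strand coordinates.
* **Insertion loci**: contiguous hits merged into spans (0-based
  half-open internally; GFF3/BED writers convert), then each locus is
  decomposed into TDR and inner-domain unit matches and classified as
  `canonical` (TDR–I–TDR), `solo_TDR`, `fragment`, `rearranged`, or
  `tandem_array` obeying the tandemization identity
  TDR<sub>x</sub> I<sub>x−1</sub> (x read from the unit layout, up to
  x = 58).
* **Genome statistics**: locus count, length spectrum (lower median),
  covered bp and genome fraction, per-class counts.
* **Inner-domain features**: maximal purine-suffix PPT; inverted
  repeats / palindromes with arm, spacer and mismatch geometry (the
  9–10 bp arm / 25 bp spacer hairpin configuration, including the
  characteristic arm-position-7/arm-position-3 mismatch); shared-motif
  discovery across inner domains (e.g. `TGATCCCAAAGGAC`); PBS
  candidates against a user-supplied tRNA FASTA with a canonical-PBS
  flag.
* **Phylogenetics and horizontal transfer**: length filter (≥ 80 bp),
  MAFFT alignment, p-distances (pairwise deletion), neighbor-joining
  trees with 100-replicate column bootstrap, intra-/inter-specific
  identity summaries, and HT-candidate flagging when inter-specific
  identity ≥ min(intra) − δ.
* **A seeded synthetic-genome generator** that plants all five locus
  classes with complete ground truth, plus an evaluator (precision /
  recall / classification accuracy / genome-fraction error), so every
  stage is benchmarked by parameter recovery.

## Worked example

Simulate a two-species scenario, run the full pipeline and look at the
report:

```r
library(trimscape)

cfg <- trim_generator_config(seed = 42, genome_bp = 2e5, n_insertions = 25,
                             type_mix = c(fragment = 0.6, canonical = 0.2,
                                          solo_TDR = 0.1, tandem_array = 0.1,
                                          rearranged = 0),
                             divergence_per_copy = 0.03)
report <- run_pipeline(generator_config = cfg, out_dir = tempdir(),
                       seed = 1, bootstrap_reps = 50)
print(report)
```

```
trimscape run: 89 hits, 49 loci on 2 contig(s)
-- A --
25 insertion loci; lengths 100-1675 bp (median 151); 8905 bp covered = 4.2639% of 208845 bp
    fragment     solo_TDR    canonical tandem_array   rearranged
          14            1            7            3            0
-- B --
24 insertion loci; lengths 100-512 bp (median 145); 5770 bp covered = 2.8030% of 205852 bp
    fragment     solo_TDR    canonical tandem_array   rearranged
          13            5            6            0            0
precision 1.000 recall 0.980 F1 0.990; classification accuracy 1.000; fraction error 0.001
```

Reading this: 89 raw hits merged into 49 insertion loci across the two
contigs; species A carries three tandem arrays (its longest locus,
1,675 bp, is one of them) while B's copies are all simple; against the
planted truth the annotation recovered 98% of loci with every matched
locus correctly classified, and the covered-bp estimate is within 0.1%
of the planted value. The phylogenetics stage summarises divergence from
the TDR alignment:

```r
print(report$phylo$tdr$divergence)
```

```
Intra-specific identity (%):
  species mean_identity n_pairs
1 A                94.2     351
2 B                94.6     136
Inter-specific identity (%):
  species_a species_b mean_identity n_pairs
1 A         B                  77.4     459
```

Within-species copies are ~94% identical while the species differ by
~23% — a vertical-descent pattern, so
`report$phylo$tdr$ht_candidates` flags nothing. Re-running with
`ht_pair = list(donor = "A", recipient = "B")` in the generator raises
the inter-specific identity above the intra-specific minimum and the
A–B pair is flagged as a horizontal-transfer candidate.

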