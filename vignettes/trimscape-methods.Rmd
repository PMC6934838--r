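---
title: "Methods: structural TRIM annotation and its benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural TRIM annotation and its benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The element model

trimscape targets terminal-repeat retrotransposons in miniature (TRIMs):
non-autonomous LTR retrotransposons under 1000 bp in which two terminal
direct repeats (TDRs, the LTR equivalents) flank a short internal domain.
The model the package detects and validates against is parameterised by

* a TDR length range, default 202–218 bp;
* an inner-domain length range, default 77–80 bp;
* a polypurine tract (PPT): a purine-only run of at least 7 bp ending
  exactly at the inner-domain 3′ terminus (the common tract here is
  `GGGGAGA`);
* optional inner-domain substructure: an inverted-repeat pair (9–10 bp
  arms roughly 25 bp apart, frequently with a single internal mismatch
  pairing arm position 7 against arm position 3), a conserved central
  motif (`TGATCCCAAAGGAC`), and tRNA-complementary segments in lieu of a
  canonical primer binding site (PBS).

Insertion loci in a genome fall into five structural classes: `canonical`
(TDR–inner–TDR), `solo_TDR` (a single repeat left behind by unequal
recombination), `fragment` (sub-unit remnants), `rearranged` (an element
interrupted by foreign sequence or otherwise off-pattern), and
`tandem_array`. Arrays obey the tandemization identity TDR~x~ I~x−1~ —
x repeats alternating with x−1 inner domains — which the decomposer reads
from the positional unit layout, never from length arithmetic, because
unit-length variation makes length-based x estimates unreliable.

## Detection: seed, chain, extend, merge

The similarity search is a deterministic stand-in for blastn: exact
k-mer seeds (default k = 11) are located with a preprocessed dictionary,
chained single-link along diagonals (a seed joins a chain when it lies
within 120 bp downstream and within a diagonal band of max(16, x_drop)),
and every chain is extended by an exact affine-gap local alignment
restricted to a window around the chain. The `x_drop` parameter (default
20) sizes the window margin — a window-bounded DP rather than a classic
x-drop loop; for the hit lengths involved here the two give the same
spans, and the bounded window keeps extension from swallowing a
neighbouring unit of a tandem array. Hits are kept by identity ≥ 0.75
and subject-span length ≥ 100 bp (the genome-scan convention), and
near-duplicate hits (reciprocal overlap > 90% on one strand) are
collapsed to the best-scoring one. E-values are deliberately not
computed: an identity/length filter is deterministic and independent of
database size, whereas a Karlin–Altschul calibration would add nothing
to the structural analysis done here.

Scoring is BLASTN-like: match +2, mismatch −3, and affine gaps costing
`gap_open + L × gap_extend` = 5 + 2L for a gap of length L. `N` never
matches anything, including another `N` — conservative in repeat
contexts. Alignment identity is matches over aligned columns, counting
gap columns as non-matches. The pairwise DP engine is Biostrings'
`pairwiseAlignment`; its traceback is deterministic but follows its own
internal tie-break rather than a declared diagonal-first order, which
affects only the printed alignment strings, never scores, spans or
identities (the test suite checks scores against an independent
brute-force DP).

Overlapping and book-ended hits are merged into insertion loci
(`merge_distance = 0` by default; book-ended spans are contiguous under
the half-open convention). All internal coordinates are 0-based
half-open; conversions happen only in the writers (GFF3 is 1-based
closed, BED 0-based half-open).

## Classification

Each locus is decomposed by local alignment of the TDR and inner-domain
consensus against the locus sequence (seeded search with unit-level
thresholds: identity ≥ 0.65, span ≥ 25 bp), placing unit matches
greedily highest-score-first with overlap exclusion, then sorting
positionally. A unit match is *complete* when its span reaches 80% of
the unit length — the operational reading of "shorter than a single
copy" for fragments. The layout decides the class: alternating complete
TDR/I/…/TDR with x ≥ 3 is a tandem array (x = 2 is canonical by
definition, so arrays require at least three repeats); a lone complete
TDR is a solo-TDR; no complete TDR in a span shorter than one TDR is a
fragment; anything else — split TDRs around a foreign insert, TDR,TDR
without an inner domain, and similar — is rearranged. A locus with no
unit match at all defaults to fragment with a logged note. Genome
statistics use the lower median on sorted locus lengths for even counts.

## Phylogenetics and horizontal-transfer flagging

TDRs and inner domains are analysed in separate runs; the left and right
TDRs of one element are distinct taxa (suffixed `_L`/`_R`), since
inter-element recombination can make them cluster apart. Sequences under
80 bp are excluded. Alignment is progressive (MAFFT `--auto`,
deterministic for a given input); distances are p-distances with
pairwise deletion; trees are neighbor joining with negative branch
estimates clamped to zero. A maximum-likelihood search would be
disproportionate here: the trees are read at the cluster level
(species-specific clusters, intermingled clusters, unresolved pairs),
and NJ on p-distances preserves exactly those features while staying
fast enough for 100-replicate column bootstraps, whose supports are
reported on the point-estimate tree's bipartitions. Replicate seeds are
drawn once from the master seed, so supports are reproducible
bit-for-bit and invariant to taxon input order.

Divergence summaries report mean pairwise identity (100 × (1 − p))
within each species and for every species pair; cells with no pair are
absent rather than zero. A species pair is flagged as a
horizontal-transfer candidate when inter-specific identity reaches
`min(intra_A, intra_B) − delta` with `delta = 0` by default: elements as
similar across a species boundary as within species are hard to explain
by vertical descent. No numeric criterion beyond this comparison is
assumed; `delta` is exposed for sensitivity analyses.

## The synthetic-data generator

The generator is first-class, tested code: it is the package's stand-in
for clone libraries and a draft genome, and every benchmark reads its
ground truth. Its defaults are the study conditions:

* TDR length uniform in 202–218 bp, inner domain in 77–80 bp;
* inner-domain layout 5′→3′: PBS-like prefix, left IR arm (9 bp), a
  25 bp spacer containing the 14 bp central motif, right IR arm with the
  characteristic single internal mismatch, a pyrimidine guard, then
  `GGGGAGA` — the guard makes the maximal purine suffix exactly the PPT.
  The construction is verified (PPT exact; planted IR top-ranked by the
  detector) and the random filler is redrawn on the rare occasions a
  background inverted repeat would outrank the planted one;
* type mix 96% fragments (lengths 100–160 bp, median ≈ 130 bp, always
  below 80% of a TDR so fragments stay sub-unit), with the remaining 4%
  split across canonical, solo-TDR, tandem-array (x = 3 + geometric,
  truncated at 58, the largest array observed) and rearranged copies;
* rearranged copies carry a 100–300 bp foreign segment inserted at
  25–40% of the left TDR. The insert is capped at 300 bp and placed in
  the left half so that a rearranged element remains recoverable as a
  single locus under reciprocal-overlap evaluation with
  `merge_distance = 0` (the detached TDR head falls below the 100 bp hit
  filter); longer or more central inserts split a locus in two, which is
  a property of merge-based locus calling, not of the simulator;
* per-copy divergence 3% substitutions plus 0.2% indels (geometric
  lengths, mean 2), giving intra-species identities around 94%, the
  scale reported for the least diverged real species sets;
* species consensuses diverge from the ancestral element at 13%
  substitutions with the planted structural features (arms, motif, PPT,
  guard) protected — selection maintains exactly these features across
  real species — yielding inter-specific identities near 72–73%
  (≈ 27% divergence);
* the horizontal-transfer scenario gives the recipient species the
  donor's consensus verbatim (`transfer_divergence = 0`) and halves the
  recipient's per-copy divergence, modelling a recent invasion: donor
  intra ≈ 94%, recipient intra ≈ 97%, inter ≥ min(intra) — the
  flagging pattern seen in the motivating data;
* insertion sites are uniform per species with a 300 bp minimum gap so
  that separate planted loci cannot merge into one span, keeping truth
  matching one-to-one. Real genomes do have abutting insertions; the
  evaluator, not the detector, needs this simplification;
* one RNG stream per species is derived from the master seed, so adding
  a species never perturbs the others, and identical configurations
  reproduce byte-identical FASTA and truth.

The background genome is i.i.d. at 40% GC. That isolates detector
behaviour but means passing benchmarks say nothing about specificity
against satellite arrays, segmental duplications or other repeat
families that real bivalve genomes contain in quantity; a decoy family
can be planted manually for such stress tests.

## Benchmark problem sizes and numerical choices

The shipped benchmarks use 2 × 500 kb genomes with 40 insertions each
for the exact-recovery round trip (divergence 0: 100% recall and
classification; 5%: ≥ 95% classification accuracy); a 5 Mb genome with
~1% planted canonical/tandem content at 10% divergence for fraction
recovery (±15% relative); 500 insertions in 500 kb for fragment-share
recovery (±3 points around 96%); 10 copies per species for divergence
recovery (±1.5 points against the closed-form expectation
p = d₁(1−d₂) + d₂(1−d₁) + ⅔d₁d₂); and 20 seeded replicates of a
three-species horizontal-transfer scenario in which exactly the planted
pair must be flagged every time. Alignment scores are checked against a
brute-force affine DP on 1,000 random pairs up to 30 bp, NJ against an
exhaustive topology enumeration with least-squares branch fitting at
5–8 taxa, and interval merging against a naive coverage sweep on 10,000
random interval sets. These sizes were chosen as the smallest at which
the recovered quantities are statistically stable at the stated
tolerances.

Degenerate inputs are handled explicitly: queries shorter than the seed
produce a warning and no hits; an empty local alignment (score 0) is
returned when no positive-scoring pair exists; sequence pairs sharing no
comparable alignment column are an error in distance computation (and
are imputed to the maximum observed distance inside bootstrap
replicates only); homopolymer inverted-repeat arms are suppressed;
terminal mismatched arm pairs are trimmed so reported arms end in a
paired base; and the motif reporter trims weakly conserved edge columns
(< 60% column agreement) so windows that merely absorb random flanks
within the mismatch budget do not pad the consensus.

## Known limitations

* The flanking-similarity analysis of cloned fragments requires the
  deposited clone records; the function operates on any user-supplied
  clone FASTA.
* Minus-strand detection is implemented and tested at the hit level, but
  the generator plants forward-strand copies only.
* Insertion dating from TDR–TDR divergence and target-site-duplication
  detection are out of scope, as are translated searches and E-value
  statistics.
* Hairpin calls are geometric (arm/spacer), not thermodynamic; no RNA
  folding is attempted.
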