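Package: trimscape
Title: Detection, Classification and Evolutionary Analysis of TRIM
    Retrotransposons in Genome Sequences
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structural discovery and characterization of terminal-repeat
    retrotransposons in miniature (TRIMs), small non-autonomous LTR
    retrotransposons made of two terminal direct repeats (TDRs) flanking a
    short internal domain. Provides seeded local similarity search against
    genome contigs, merging of homology hits into insertion loci, structural
    classification of loci (canonical elements, solo-TDRs, fragments,
    rearranged copies and tandem arrays following the TDR[x] I[x-1] pattern),
    annotation of inner-domain features (polypurine tract, inverted repeats
    and hairpins, conserved motifs, primer-binding-site candidates against a
    tRNA collection), genome-contribution statistics, and distance-based
    phylogenetics of TDR and inner-domain sets with intra-/inter-specific
    divergence summaries and horizontal-transfer candidate flagging. A
    seeded synthetic-genome generator plants elements with full ground truth
    so that every stage can be benchmarked by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    ape,
    igraph,
    withr,
    tibble,
    stats,
    utils,
    methods
Suggests:
    testthat (>= 3.0.0),
    phangorn,
    jsonlite
Config/testthat/edition: 3
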