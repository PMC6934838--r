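## End-to-end orchestration: simulate -> search -> annotate -> features ->
## phylogenetics/divergence -> evaluation, with all artefacts written to
## an output directory. Reruns with an identical configuration reproduce
## identical outputs (all stochastic steps are seeded).

#' Extract locus sequences from a genome
#'
#' @param loci Locus tibble.
#' @param genomes A named `DNAStringSet` of contigs.
#' @return A `DNAStringSet` named `contig:start-end`.
#' @export
extract_locus_seqs <- function(loci, genomes) {
  genomes <- as_dna_set(genomes)
  seqs <- vapply(seq_len(nrow(loci)), function(i)
    as.character(Biostrings::subseq(genomes[[loci$contig_id[i]]],
                                    loci$start[i] + 1L, loci$end[i])),
    character(1))
  names(seqs) <- sprintf("%s:%d-%d", loci$contig_id, loci$start, loci$end)
  Biostrings::DNAStringSet(seqs)
}

#' Extract TDR and inner-domain unit sequences from classified loci
#'
#' Complete units are pulled from each locus `unit_layout`. The two TDRs
#' of a canonical element are distinct taxa suffixed `_L` / `_R`; array
#' TDRs are numbered `_T01`, `_T02`, ... and inner domains `_I01`, ...
#'
#' @param loci Classified locus tibble (with `unit_layout`).
#' @param genomes A named `DNAStringSet` of contigs.
#' @return A list of `DNAStringSet`s: `tdr`, `inner`; names carry the
#'   locus id plus unit suffix.
#' @export
extract_unit_seqs <- function(loci, genomes) {
  genomes <- as_dna_set(genomes)
  tdr <- character(0); inner <- character(0)
  for (i in seq_len(nrow(loci))) {
    lay <- loci$unit_layout[[i]]
    if (is.null(lay)) next
    lay <- lay[lay$complete %in% TRUE & lay$unit_type != "other", ,
               drop = FALSE]
    if (nrow(lay) == 0L) next
    base <- sprintf("%s:%d-%d", loci$contig_id[i], loci$start[i],
                    loci$end[i])
    contig <- genomes[[loci$contig_id[i]]]
    tdr_rows <- which(lay$unit_type == "TDR")
    for (k in seq_along(tdr_rows)) {
      r <- tdr_rows[k]
      suffix <- if (length(tdr_rows) == 2L) c("_L", "_R")[k]
                else sprintf("_T%02d", k)
      s <- Biostrings::subseq(contig, loci$start[i] + lay$start[r] + 1L,
                              loci$start[i] + lay$end[r])
      tdr[paste0(base, suffix)] <- as.character(s)
    }
    in_rows <- which(lay$unit_type == "I")
    for (k in seq_along(in_rows)) {
      r <- in_rows[k]
      s <- Biostrings::subseq(contig, loci$start[i] + lay$start[r] + 1L,
                              loci$start[i] + lay$end[r])
      inner[sprintf("%s_I%02d", base, k)] <- as.character(s)
    }
  }
  list(tdr = Biostrings::DNAStringSet(tdr),
       inner = Biostrings::DNAStringSet(inner))
}

#' Randomly select full-length elements
#'
#' Uniform sample without replacement among full-length loci (canonical
#' or tandem array), seeded. When fewer than `n` are eligible, all are
#' returned with a warning.
#'
#' @param loci Classified locus tibble.
#' @param n Sample size (default 10).
#' @param seed Seed.
#' @return The sampled locus rows.
#' @export
select_random_elements <- function(loci, n = 10L, seed) {
  eligible <- which(loci$classification %in% c("canonical", "tandem_array"))
  if (length(eligible) < n) {
    warning("only ", length(eligible), " full-length loci available (< ",
            n, "); returning all")
    return(loci[eligible, , drop = FALSE])
  }
  take <- withr::with_seed(seed, sample(eligible, n))
  loci[sort(take), , drop = FALSE]
}

#' Run the full analysis pipeline
#'
#' Stages: (optional) simulation, seeded search of the element consensus
#' against every contig, hit filtering, locus merging and classification,
#' genome statistics, inner-domain feature annotation, TDR / inner-domain
#' phylogenetics with divergence summaries and horizontal-transfer
#' flagging, and (when truth is available) evaluation against the planted
#' ground truth. All outputs are written under `out_dir`.
#'
#' @param generator_config A [trim_generator_config()] for a synthetic
#'   run, or NULL when `genomes` + `consensus` are supplied.
#' @param genomes Named `DNAStringSet` (or FASTA path) of contigs.
#' @param consensus A [trim_consensus()] (or FASTA path with records
#'   `TDR` and `inner`).
#' @param species_map Named character vector contig id -> species; for
#'   synthetic runs it is derived from the truth.
#' @param trnas Optional tRNA `DNAStringSet` (or FASTA path) for the PBS
#'   scan.
#' @param truth Optional truth tibble (synthetic runs supply it
#'   automatically).
#' @param out_dir Output directory (created if missing).
#' @param seed Seed for the bootstrap (and any other stochastic step).
#' @param min_hit_len Hit length filter (default 100 bp).
#' @param merge_distance Locus merge distance (default 0).
#' @param min_phylo_len Length filter before alignment (default 80 bp).
#' @param bootstrap_reps Bootstrap replicates (default 100).
#' @param run_phylo Set FALSE to skip the phylogenetics stage.
#' @return A `trim_run_report` list with per-stage results and the paths
#'   of every file written.
#' @export
run_pipeline <- function(generator_config = NULL, genomes = NULL,
                         consensus = NULL, species_map = NULL, trnas = NULL,
                         truth = NULL, out_dir, seed = 1L,
                         min_hit_len = 100L, merge_distance = 0L,
                         min_phylo_len = 80L, bootstrap_reps = 100L,
                         run_phylo = TRUE) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  sim <- NULL
  if (!is.null(generator_config)) {
    sim <- simulate_genomes(generator_config)
    genomes <- sim$genomes
    consensus <- sim$consensus
    truth <- sim$truth
    species_map <- setNames(truth$species[!duplicated(truth$contig_id)],
                            truth$contig_id[!duplicated(truth$contig_id)])
    files["genomes"] <- write_fasta(genomes,
                                    file.path(out_dir, "genomes.fasta"))
    files["truth_tsv"] <- file.path(out_dir, "truth.tsv")
    files["truth_bed"] <- file.path(out_dir, "truth.bed")
    write_truth(truth, bed_path = files["truth_bed"],
                tsv_path = files["truth_tsv"])
  } else {
    if (is.character(genomes)) genomes <- read_fasta(genomes)
    if (is.character(trnas)) trnas <- read_fasta(trnas)
    if (is.character(consensus)) {
      fa <- read_fasta(consensus)
      stopifnot(all(c("TDR", "inner") %in% names(fa)))
      consensus <- trim_consensus(fa[["TDR"]], fa[["inner"]])
    }
    stopifnot(!is.null(genomes), !is.null(consensus))
  }
  genomes <- as_dna_set(genomes)
  if (is.null(species_map)) {
    species_map <- setNames(names(genomes), names(genomes))
  }
  ## ---- search ----
  ## each species is searched (and classified) with its own element
  ## consensus when one is available, as in a per-species clone-derived
  ## consensus; otherwise the single supplied consensus serves all
  cons_for <- function(ctg) {
    sp <- species_map[[ctg]]
    if (!is.null(sim) && !is.null(sim$species_consensus[[sp]]))
      sim$species_consensus[[sp]] else consensus
  }
  hits <- do.call(rbind, lapply(names(genomes), function(ctg)
    seeded_search(cons_for(ctg)$element, genomes[[ctg]],
                  min_identity = 0.75, min_length = min_hit_len,
                  query_id = "consensus", subject_id = ctg)))
  hits <- filter_hits(hits, min_hit_len)
  files["hits"] <- write_hits_tsv(hits, file.path(out_dir, "hits.tsv"))
  ## ---- annotate ----
  loci <- merge_hits_to_loci(hits, merge_distance = merge_distance,
                             contig_lengths = setNames(
                               Biostrings::width(genomes), names(genomes)))
  loci <- do.call(rbind, lapply(names(genomes), function(ctg) {
    sub <- loci[loci$contig_id == ctg, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    classify_loci(sub, genomes, cons_for(ctg))
  }))
  if (is.null(loci)) {
    loci <- merge_hits_to_loci(hits)
    loci$unit_layout <- list()
  }
  files["loci_gff3"] <- write_loci_gff3(loci, file.path(out_dir, "loci.gff3"))
  files["loci_bed"] <- write_loci_bed(loci, file.path(out_dir, "loci.bed"))
  stats_by_species <- list()
  for (sp in unique(species_map)) {
    ctgs <- names(species_map)[species_map == sp]
    st <- genome_stats(loci[loci$contig_id %in% ctgs, , drop = FALSE],
                       sum(Biostrings::width(genomes[ctgs])))
    stats_by_species[[sp]] <- st
    f <- file.path(out_dir, paste0("stats_", sp, ".tsv"))
    write_genome_stats_tsv(st, f)
    files[paste0("stats_", sp)] <- f
  }
  ## ---- features ----
  units <- extract_unit_seqs(loci, genomes)
  features <- annotate_inner_domain(consensus$inner_seq, trnas = trnas)
  features$conserved_motif <- if (length(units$inner) >= 3L)
    find_conserved_motif(units$inner) else NULL
  files["features"] <- write_features_tsv(features,
                                          file.path(out_dir, "features.tsv"))
  if (length(units$tdr)) {
    files["tdr_fasta"] <- write_fasta(units$tdr,
                                      file.path(out_dir, "tdr_units.fasta"))
  }
  if (length(units$inner)) {
    files["inner_fasta"] <- write_fasta(units$inner,
                                        file.path(out_dir,
                                                  "inner_units.fasta"))
  }
  ## ---- phylogenetics & divergence ----
  phylo <- list()
  if (run_phylo) {
    for (part in c("tdr", "inner")) {
      seqs <- units[[part]]
      res <- list(skipped = TRUE,
                  reason = "fewer than 3 sequences after length filter")
      if (length(seqs) >= 3L) {
        seqs <- tryCatch(length_filter(seqs, min_phylo_len),
                         error = function(e) NULL)
        if (!is.null(seqs) && length(seqs) >= 3L) {
          msa <- align_msa(seqs)
          bs <- bootstrap_supports(msa, n_reps = bootstrap_reps,
                                   seed = derive_seed(seed,
                                                      match(part,
                                                            c("tdr",
                                                              "inner"))))
          sp_of <- setNames(
            unname(species_map[sub(":.*$", "", names(seqs))]), names(seqs))
          div <- divergence_summary(msa, sp_of)
          ht <- if (nrow(div$inter) && nrow(div$intra) >= 2L)
            flag_ht_candidates(div) else NULL
          f <- file.path(out_dir, paste0("tree_", part, ".nwk"))
          write_tree_newick(bs, f)
          files[paste0("tree_", part)] <- f
          res <- list(skipped = FALSE, msa = msa, bootstrap = bs,
                      divergence = div, ht_candidates = ht)
        }
      }
      phylo[[part]] <- res
    }
  } else {
    phylo <- list(skipped = TRUE, reason = "disabled")
  }
  ## ---- evaluation ----
  evaluation <- NULL
  if (!is.null(truth)) {
    evaluation <- evaluate_annotation(loci, truth)
  }
  report <- structure(list(
    n_contigs = length(genomes),
    hits = hits, loci = loci, stats = stats_by_species,
    features = features, phylo = phylo, evaluation = evaluation,
    truth = truth, consensus = consensus,
    seed = seed, files = files,
    params = list(min_hit_len = min_hit_len,
                  merge_distance = merge_distance,
                  min_phylo_len = min_phylo_len,
                  bootstrap_reps = bootstrap_reps)),
    class = "trim_run_report")
  report
}

#' @export
print.trim_run_report <- function(x, ...) {
  cat("trimscape run:", nrow(x$hits), "hits,", nrow(x$loci),
      "loci on", x$n_contigs, "contig(s)\n")
  for (sp in names(x$stats)) {
    cat("--", sp, "--\n"); print(x$stats[[sp]])
  }
  if (!is.null(x$evaluation)) print(x$evaluation)
  invisible(x)
}
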