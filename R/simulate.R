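## Synthetic multi-species genomes with planted TRIM-like elements and
## complete ground truth.
##
## The generator emulates the structure observed in the real elements:
## 202-218 bp TDRs; a 77-80 bp inner domain carrying (5' to 3') a
## PBS-like prefix, an inverted-repeat pair (9-10 bp arms, 25 bp apart,
## optionally with the characteristic single internal mismatch), the
## conserved central motif between the arms, and a terminal 7 bp
## polypurine tract preceded by a pyrimidine guard so the maximal purine
## run is exactly the PPT. Insertion loci cover the observed spectrum:
## canonical elements, solo-TDRs, sub-element fragments, rearranged
## copies (a foreign segment interrupting a TDR) and tandem arrays
## following TDR[x] I[x-1].

#' Generator configuration
#'
#' @param seed Master seed (mandatory). Every stochastic step derives its
#'   own stream from it; one stream per species, so adding a species never
#'   perturbs the others.
#' @param n_species Number of species.
#' @param species Species labels.
#' @param genome_bp Background genome size per species.
#' @param gc Background GC fraction.
#' @param n_insertions Planted insertion loci per species.
#' @param type_mix Proportions over fragment / canonical / solo_TDR /
#'   tandem_array / rearranged (must sum to 1). The default is
#'   fragment-dominated (96%), matching the composition seen in a real
#'   genome scan.
#' @param tandem_x_geom_p,tandem_x_max Tandem unit count x is
#'   `3 + Geometric(p)`, truncated at `tandem_x_max` (default 58, the
#'   largest array observed).
#' @param divergence_per_copy Per-copy substitution probability.
#' @param indel_rate Per-site indel probability per copy (geometric
#'   lengths, mean 2).
#' @param interspecies_divergence Substitution probability applied to the
#'   species consensus relative to the ancestral element (structural
#'   features are protected; see the methods vignette).
#' @param ht_pair Optional horizontal-transfer scenario:
#'   `list(donor, recipient, transfer_divergence = 0)`. The recipient
#'   shares the donor's consensus (mutated at `transfer_divergence`) and
#'   its copies diverge at half the per-copy rate (recent invasion).
#' @param plant_ir Inverted repeat to plant:
#'   `list(arm_len = 9, spacer = 25, mismatches = 1)`.
#' @param plant_motif Conserved central motif to plant.
#' @param ppt Polypurine tract (suffix of the inner domain).
#' @param tdr_len_range,inner_len_range Unit length ranges (bp).
#' @param fragment_len_range Planted fragment lengths (bp); kept below
#'   80% of the shortest TDR so fragments stay sub-unit.
#' @param min_gap Minimum gap (bp) between planted spans.
#' @return A `trim_generator_config` list.
#' @export
trim_generator_config <- function(seed,
                                  n_species = 2L,
                                  species = LETTERS[seq_len(n_species)],
                                  genome_bp = 5e5,
                                  gc = 0.4,
                                  n_insertions = 40L,
                                  type_mix = c(fragment = 0.96,
                                               canonical = 0.01,
                                               solo_TDR = 0.02,
                                               tandem_array = 0.005,
                                               rearranged = 0.005),
                                  tandem_x_geom_p = 0.5,
                                  tandem_x_max = 58L,
                                  divergence_per_copy = 0.03,
                                  indel_rate = 0.002,
                                  interspecies_divergence = 0.13,
                                  ht_pair = NULL,
                                  plant_ir = list(arm_len = 9L, spacer = 25L,
                                                  mismatches = 1L),
                                  plant_motif = "TGATCCCAAAGGAC",
                                  ppt = "GGGGAGA",
                                  tdr_len_range = c(202L, 218L),
                                  inner_len_range = c(77L, 80L),
                                  fragment_len_range = c(100L, 160L),
                                  min_gap = 300L) {
  if (missing(seed)) stop("seed is mandatory")
  stopifnot(abs(sum(type_mix) - 1) < 1e-9,
            all(type_mix >= 0),
            divergence_per_copy >= 0, divergence_per_copy < 1,
            indel_rate >= 0, indel_rate < 1,
            gc > 0, gc < 1,
            length(species) == n_species,
            plant_ir$arm_len %in% c(9L, 10L),
            plant_ir$mismatches %in% c(0L, 1L))
  if (!is.null(ht_pair)) {
    stopifnot(all(c(ht_pair$donor, ht_pair$recipient) %in% species))
    if (is.null(ht_pair$transfer_divergence)) ht_pair$transfer_divergence <- 0
  }
  structure(list(seed = as.integer(seed), n_species = n_species,
                 species = species, genome_bp = genome_bp, gc = gc,
                 n_insertions = n_insertions, type_mix = type_mix,
                 tandem_x_geom_p = tandem_x_geom_p,
                 tandem_x_max = tandem_x_max,
                 divergence_per_copy = divergence_per_copy,
                 indel_rate = indel_rate,
                 interspecies_divergence = interspecies_divergence,
                 ht_pair = ht_pair, plant_ir = plant_ir,
                 plant_motif = plant_motif, ppt = ppt,
                 tdr_len_range = as.integer(tdr_len_range),
                 inner_len_range = as.integer(inner_len_range),
                 fragment_len_range = as.integer(fragment_len_range),
                 min_gap = as.integer(min_gap)),
            class = "trim_generator_config")
}

derive_seed <- function(seed, i) {
  as.integer((as.numeric(seed) * 48271 + i * 16807) %% 2147483647)
}

## draws from the current RNG stream
random_dna_vec <- function(n, gc) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

#' Build a structured element consensus
#'
#' Draws a random element honouring the structural model: TDR length
#' uniform in the TDR range, inner-domain length uniform in the inner
#' range, and an inner domain laid out as PBS-like prefix, left IR arm,
#' spacer containing the central motif, right IR arm, pyrimidine guard,
#' PPT. The construction is verified (PPT is exactly the configured
#' tract; the planted inverted repeat is the top-ranked one) and redrawn
#' if a random background happens to beat it.
#'
#' @param seed Seed for this element.
#' @param config A [trim_generator_config()] (its own seed is ignored
#'   here).
#' @return A [trim_consensus()] with an `inner_features` attribute giving
#'   the planted 0-based spans (`prefix`, `ir_left`, `ir_right`, `motif`,
#'   `ppt`).
#' @export
build_consensus <- function(seed, config = trim_generator_config(seed)) {
  ir <- config$plant_ir
  motif <- dna_chars(config$plant_motif)
  ppt <- dna_chars(config$ppt)
  stopifnot(all(ppt %in% c("A", "G")))
  withr::with_seed(derive_seed(seed, 101L), {
    t_len <- sample(seq(config$tdr_len_range[1], config$tdr_len_range[2]), 1L)
    i_len <- sample(seq(config$inner_len_range[1], config$inner_len_range[2]),
                    1L)
    fixed_len <- 2L * ir$arm_len + ir$spacer + 1L + length(ppt)
    prefix_len <- i_len - fixed_len
    if (prefix_len < 0L) {
      stop("inner-domain length ", i_len, " too small to host the planted ",
           "features (need ", fixed_len, " bp)")
    }
    if (ir$spacer < length(motif)) {
      stop("IR spacer (", ir$spacer, " bp) too small for the ",
           length(motif), " bp motif")
    }
    tdr <- random_dna_vec(t_len, config$gc)
    for (try in seq_len(50L)) {
      inner <- build_inner(prefix_len, ir, motif, ppt, config$gc)
      ## verification: PPT exact, planted IR top-ranked with its geometry
      pptann <- find_ppt(paste(inner$seq, collapse = ""),
                         min_len = length(ppt))
      ok_ppt <- !is.null(pptann) && pptann$seq == config$ppt
      irs <- find_inverted_repeats(paste(inner$seq, collapse = ""),
                                   min_arm = 8L, max_spacer = 41L,
                                   max_mismatch = 1L)
      ok_ir <- nrow(irs) > 0L &&
        irs$arm_len[1] == ir$arm_len &&
        irs$spacer[1] == ir$spacer &&
        irs$mismatches[1] == ir$mismatches &&
        irs$left_start[1] == inner$features$ir_left[1]
      if (ok_ppt && ok_ir) break
      if (try == 50L) stop("could not build a verified inner domain")
    }
    cons <- trim_consensus(paste(tdr, collapse = ""),
                           paste(inner$seq, collapse = ""),
                           tdr_len_range = config$tdr_len_range,
                           inner_len_range = config$inner_len_range,
                           ppt_min_len = length(ppt))
    attr(cons, "inner_features") <- inner$features
    cons
  })
}

## assemble one inner domain; returns list(seq = chars, features = spans)
build_inner <- function(prefix_len, ir, motif, ppt, gc) {
  L <- ir$arm_len
  repeat {
    left_arm <- random_dna_vec(L, gc)
    if (length(unique(left_arm)) >= 3L) break
  }
  right_arm <- rev(unname(COMPLEMENT[left_arm]))
  mm_left_pos <- integer(0)
  if (ir$mismatches == 1L) {
    ## the characteristic internal mismatch: left-arm position 7 pairs
    ## with right-arm position 3 (for 9 bp arms)
    mm_left_pos <- min(7L, L - 2L)
    j <- L - mm_left_pos            # outward pair index
    rpos <- j + 1L                  # 1-based position in right arm
    good <- right_arm[rpos]
    right_arm[rpos] <- sample(setdiff(c("A", "C", "G", "T"), good), 1L)
  }
  spacer_len <- ir$spacer
  fa <- (spacer_len - length(motif)) %/% 2L
  fb <- spacer_len - length(motif) - fa
  spacer <- c(random_dna_vec(fa, gc), motif, random_dna_vec(fb, gc))
  guard <- sample(c("C", "T"), 1L)
  prefix <- random_dna_vec(prefix_len, gc)
  ## flank guard: the base before the left arm must not pair with the
  ## base after the right arm, so the planted arms cannot extend outward
  if (prefix_len > 0L) {
    while (prefix[prefix_len] == COMPLEMENT[guard]) {
      prefix[prefix_len] <- sample(c("A", "C", "G", "T"), 1L)
    }
  }
  seq <- c(prefix, left_arm, spacer, right_arm, guard, ppt)
  p0 <- prefix_len
  features <- list(
    prefix = c(0L, p0),
    ir_left = c(p0, p0 + L),
    ir_right = c(p0 + L + spacer_len, p0 + 2L * L + spacer_len),
    motif = c(p0 + L + fa, p0 + L + fa + length(motif)),
    ppt = c(length(seq) - length(ppt), length(seq)))
  list(seq = seq, features = features)
}

#' Mutate a sequence
#'
#' Per-site substitutions (uniform alternative base) and indels with
#' geometric lengths (mean 2). Deterministic under `seed`.
#'
#' @param seq Sequence (character or `DNAString`).
#' @param sub_rate Substitution probability per site, in \[0,1).
#' @param indel_rate Indel event probability per site, in \[0,1).
#' @param seed Seed.
#' @param protect Optional integer vector of 1-based positions exempt
#'   from mutation (used to preserve planted structural features at the
#'   consensus level).
#' @return The mutated sequence as a character string.
#' @export
mutate_sequence <- function(seq, sub_rate, indel_rate = 0, seed,
                            protect = NULL) {
  stopifnot(sub_rate >= 0, sub_rate < 1, indel_rate >= 0, indel_rate < 1)
  ch <- dna_chars(seq)
  n <- length(ch)
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    editable <- setdiff(seq_len(n), protect)
    subs <- editable[runif(length(editable)) < sub_rate]
    if (length(subs)) {
      off <- sample.int(3L, length(subs), replace = TRUE)
      ch[subs] <- bases[((match(ch[subs], bases) - 1L + off) %% 4L) + 1L]
    }
    if (indel_rate > 0) {
      ev <- editable[runif(length(editable)) < indel_rate]
      out <- as.list(ch)
      for (i in rev(ev)) {
        len <- stats::rgeom(1L, 0.5) + 1L
        if (runif(1) < 0.5) {
          out[[i]] <- c(ch[i], random_dna_vec(len, 0.5))
        } else {
          for (j in i:min(n, i + len - 1L)) out[[j]] <- character(0)
        }
      }
      ch <- unlist(out)
    }
    paste(ch, collapse = "")
  })
}

## species consensus: TDR and inner mutated separately (substitutions
## only, structural features protected) so unit boundaries stay known
species_consensus <- function(master, d, seed) {
  f <- attr(master, "inner_features")
  protect_inner <- unique(unlist(lapply(
    f[c("ir_left", "ir_right", "motif", "ppt")],
    function(sp) seq.int(sp[1] + 1L, sp[2]))))
  ## also protect the pyrimidine guard before the PPT
  protect_inner <- c(protect_inner, f$ppt[1])
  tdr <- mutate_sequence(master$tdr_seq, d, 0, derive_seed(seed, 11L))
  inner <- mutate_sequence(master$inner_seq, d, 0, derive_seed(seed, 12L),
                           protect = protect_inner)
  cons <- trim_consensus(tdr, inner,
                         tdr_len_range = master$tdr_len_range,
                         inner_len_range = master$inner_len_range,
                         ppt_min_len = master$ppt_min_len)
  attr(cons, "inner_features") <- f
  cons
}

build_insertion <- function(type, cons, config) {
  t <- as.character(cons$tdr_seq); i <- as.character(cons$inner_seq)
  t_len <- nchar(t)
  switch(type,
    canonical = list(seq = paste0(t, i, t), n_tdr = 2L, n_inner = 1L),
    solo_TDR = list(seq = t, n_tdr = 1L, n_inner = 0L),
    fragment = {
      len <- sample(seq(config$fragment_len_range[1],
                        config$fragment_len_range[2]), 1L)
      el <- paste0(t, i, t)
      at <- sample.int(nchar(el) - len + 1L, 1L)
      list(seq = substr(el, at, at + len - 1L), n_tdr = 0L, n_inner = 0L)
    },
    tandem_array = {
      x <- min(config$tandem_x_max, 3L + stats::rgeom(1L, config$tandem_x_geom_p))
      list(seq = paste0(t, strrep(paste0(i, t), x - 1L)),
           n_tdr = x, n_inner = x - 1L)
    },
    rearranged = {
      ## foreign segment interrupting the left TDR
      ins_len <- sample(100:300, 1L)
      cut <- round(t_len * runif(1, 0.25, 0.4))
      foreign <- paste(random_dna_vec(ins_len, config$gc), collapse = "")
      list(seq = paste0(substr(t, 1L, cut), foreign,
                        substr(t, cut + 1L, t_len), i, t),
           n_tdr = 2L, n_inner = 1L)
    },
    stop("unknown insertion type: ", type))
}

#' Simulate genomes with planted elements and ground truth
#'
#' Builds the ancestral element from the master seed, derives one element
#' consensus per species (structural features protected), plants
#' `n_insertions` copies per species into an i.i.d. background genome
#' (uniform positions, non-overlapping, minimum gap enforced), each copy
#' individually mutated. Under a horizontal-transfer scenario the
#' recipient species shares the donor consensus and its copies carry half
#' the per-copy divergence.
#'
#' @param config A [trim_generator_config()].
#' @return A list: `genomes` (`DNAStringSet`, one contig per species),
#'   `truth` (tibble: `species`, `contig_id`, `start`, `end`, `type`,
#'   `n_tdr`, `n_inner`, `element_id`, `divergence_applied`), `consensus`
#'   (ancestral [trim_consensus()]), `species_consensus` (per-species
#'   list), `config`.
#' @export
simulate_genomes <- function(config) {
  master <- build_consensus(config$seed, config)
  cons_by_sp <- list()
  ht <- config$ht_pair
  for (si in seq_along(config$species)) {
    sp <- config$species[si]
    sseed <- derive_seed(config$seed, 1000L + si)
    if (!is.null(ht) && sp == ht$recipient) next
    cons_by_sp[[sp]] <- species_consensus(master,
                                          config$interspecies_divergence,
                                          sseed)
  }
  if (!is.null(ht)) {
    rseed <- derive_seed(config$seed,
                         1000L + match(ht$recipient, config$species))
    cons_by_sp[[ht$recipient]] <-
      species_consensus(cons_by_sp[[ht$donor]], ht$transfer_divergence,
                        rseed)
  }
  genomes <- character(0)
  truth <- list()
  for (si in seq_along(config$species)) {
    sp <- config$species[si]
    cons <- cons_by_sp[[sp]]
    ## planted-unit soundness before per-copy mutation
    v <- validate_element(list(TDR = as.character(cons$tdr_seq),
                               I = as.character(cons$inner_seq)), master)
    if (!v$pass) stop("species consensus fails structural validation: ",
                      paste(v$reasons, collapse = "; "))
    d_copy <- if (!is.null(ht) && sp == ht$recipient)
      config$divergence_per_copy / 2 else config$divergence_per_copy
    res <- withr::with_seed(derive_seed(config$seed, 2000L + si), {
      k <- config$n_insertions
      types <- sample(names(config$type_mix), k, replace = TRUE,
                      prob = config$type_mix)
      pieces <- lapply(types, build_insertion, cons = cons, config = config)
      copy_seeds <- sample.int(.Machine$integer.max - 1L, k)
      seqs <- vapply(seq_len(k), function(j)
        mutate_sequence(pieces[[j]]$seq, d_copy, config$indel_rate,
                        copy_seeds[j]), character(1))
      total <- sum(nchar(seqs))
      if (total >= 0.5 * config$genome_bp) {
        stop("planted length ", total, " exceeds half the genome (",
             config$genome_bp, " bp); infeasible packing")
      }
      bg <- random_dna_vec(config$genome_bp, config$gc)
      slack <- config$genome_bp - (k - 1L) * config$min_gap
      if (slack <= 0L) stop("infeasible packing: min_gap too large")
      u <- sort(runif(k, 0, slack))
      pos <- floor(u) + (seq_len(k) - 1L) * config$min_gap  # 0-based points
      contig_id <- paste0(sp, "_contig1")
      out <- character(2L * k + 1L)
      spans <- matrix(0L, k, 2L)
      cur <- 0L; off <- 0L
      for (j in seq_len(k)) {
        out[2L * j - 1L] <- paste(bg[seq_len(pos[j] - cur) + cur],
                                  collapse = "")
        start <- pos[j] + off
        spans[j, ] <- c(start, start + nchar(seqs[j]))
        out[2L * j] <- seqs[j]
        off <- off + nchar(seqs[j])
        cur <- pos[j]
      }
      out[2L * k + 1L] <- paste(bg[seq.int(cur + 1L, length(bg))],
                                collapse = "")
      list(contig = paste(out, collapse = ""),
           truth = tibble::tibble(
             species = sp, contig_id = contig_id,
             start = spans[, 1], end = spans[, 2],
             type = types,
             n_tdr = vapply(pieces, `[[`, integer(1), "n_tdr"),
             n_inner = vapply(pieces, `[[`, integer(1), "n_inner"),
             element_id = sprintf("%s_e%03d", sp, seq_len(k)),
             divergence_applied = d_copy))
    })
    genomes[paste0(sp, "_contig1")] <- res$contig
    truth[[sp]] <- res$truth
  }
  list(genomes = Biostrings::DNAStringSet(genomes),
       truth = do.call(rbind, truth),
       consensus = master,
       species_consensus = cons_by_sp,
       config = config)
}

#' Simulate per-species element copy sets (no genome)
#'
#' Draws mutated copies of the species consensus TDR (or inner domain)
#' directly, for divergence and phylogenetics benchmarks.
#'
#' @param config A [trim_generator_config()].
#' @param n_copies Copies per species.
#' @param part `"tdr"` or `"inner"`.
#' @return A list: `seqs` (named `DNAStringSet`), `species_of` (named
#'   character vector).
#' @export
simulate_element_sets <- function(config, n_copies = 8L,
                                  part = c("tdr", "inner")) {
  part <- match.arg(part)
  master <- build_consensus(config$seed, config)
  ht <- config$ht_pair
  cons_by_sp <- list()
  for (si in seq_along(config$species)) {
    sp <- config$species[si]
    sseed <- derive_seed(config$seed, 1000L + si)
    if (!is.null(ht) && sp == ht$recipient) next
    cons_by_sp[[sp]] <- species_consensus(master,
                                          config$interspecies_divergence,
                                          sseed)
  }
  if (!is.null(ht)) {
    rseed <- derive_seed(config$seed,
                         1000L + match(ht$recipient, config$species))
    cons_by_sp[[ht$recipient]] <-
      species_consensus(cons_by_sp[[ht$donor]], ht$transfer_divergence,
                        rseed)
  }
  seqs <- character(0)
  for (si in seq_along(config$species)) {
    sp <- config$species[si]
    base <- if (part == "tdr") cons_by_sp[[sp]]$tdr_seq
            else cons_by_sp[[sp]]$inner_seq
    d_copy <- if (!is.null(ht) && sp == ht$recipient)
      config$divergence_per_copy / 2 else config$divergence_per_copy
    copy_seeds <- withr::with_seed(derive_seed(config$seed, 3000L + si),
                                   sample.int(.Machine$integer.max - 1L,
                                              n_copies))
    copies <- vapply(copy_seeds, function(s)
      mutate_sequence(base, d_copy, config$indel_rate, s), character(1))
    names(copies) <- sprintf("%s_c%02d", sp, seq_len(n_copies))
    seqs <- c(seqs, copies)
  }
  species_of <- setNames(sub("_c\\d+$", "", names(seqs)), names(seqs))
  list(seqs = Biostrings::DNAStringSet(seqs), species_of = species_of)
}

#' Score predicted loci against generator truth
#'
#' Truth and predicted loci are matched greedily (largest overlap first,
#' one-to-one) under a reciprocal-overlap criterion: the overlap must
#' reach `min_overlap` of both spans.
#'
#' @param predicted Locus tibble (classified).
#' @param truth Truth tibble from [simulate_genomes()].
#' @param min_overlap Reciprocal overlap fraction (default 0.5).
#' @return An `evaluation_report` list: `locus_precision`, `locus_recall`,
#'   `f1`, `classification_accuracy` (among matched), `fraction_error`
#'   (relative error of covered bp), `n_matched`, and the `matches`
#'   tibble. With no predictions, precision/recall are reported as 0 and
#'   `no_predictions` is flagged.
#' @export
evaluate_annotation <- function(predicted, truth, min_overlap = 0.5) {
  key <- paste(predicted$contig_id, predicted$start, predicted$end)
  if (anyDuplicated(key)) stop("duplicate prediction spans")
  n_t <- nrow(truth); n_p <- nrow(predicted)
  if (n_p == 0L) {
    return(structure(list(locus_precision = 0, locus_recall = 0, f1 = 0,
                          classification_accuracy = NA_real_,
                          fraction_error = 1,
                          n_matched = 0L, no_predictions = TRUE,
                          matches = NULL), class = "evaluation_report"))
  }
  cand <- list()
  for (ti in seq_len(n_t)) {
    same <- which(predicted$contig_id == truth$contig_id[ti])
    if (!length(same)) next
    ov <- pmin(predicted$end[same], truth$end[ti]) -
      pmax(predicted$start[same], truth$start[ti])
    wt <- truth$end[ti] - truth$start[ti]
    wp <- predicted$end[same] - predicted$start[same]
    ok <- ov >= min_overlap * wt & ov >= min_overlap * wp
    if (any(ok)) {
      cand[[length(cand) + 1L]] <- data.frame(
        ti = ti, pi = same[ok], ov = ov[ok])
    }
  }
  matches <- NULL
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$ov), , drop = FALSE]
    used_t <- logical(n_t); used_p <- logical(n_p)
    keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      if (!used_t[cand$ti[i]] && !used_p[cand$pi[i]]) {
        keep[i] <- TRUE
        used_t[cand$ti[i]] <- TRUE; used_p[cand$pi[i]] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    matches <- tibble::tibble(
      element_id = truth$element_id[cand$ti],
      truth_type = truth$type[cand$ti],
      predicted_class = predicted$classification[cand$pi],
      truth_n_tdr = truth$n_tdr[cand$ti],
      predicted_n_tdr = predicted$n_tdr[cand$pi],
      overlap = cand$ov)
  }
  n_m <- if (is.null(matches)) 0L else nrow(matches)
  prec <- n_m / n_p; rec <- n_m / n_t
  covered_p <- sum(predicted$end - predicted$start)
  covered_t <- sum(truth$end - truth$start)
  structure(list(
    locus_precision = prec, locus_recall = rec,
    f1 = if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0,
    classification_accuracy = if (n_m)
      mean(matches$predicted_class == matches$truth_type) else NA_real_,
    fraction_error = abs(covered_p - covered_t) / covered_t,
    n_matched = n_m, no_predictions = FALSE,
    matches = matches), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf(
    "precision %.3f recall %.3f F1 %.3f; classification accuracy %s; fraction error %.3f\n",
    x$locus_precision, x$locus_recall, x$f1,
    ifelse(is.na(x$classification_accuracy), "NA",
           sprintf("%.3f", x$classification_accuracy)),
    x$fraction_error))
  invisible(x)
}

#' Write generator truth as BED and TSV
#'
#' @param truth Truth tibble.
#' @param bed_path,tsv_path Output paths (either may be NULL).
#' @return Invisibly, the paths written.
#' @export
write_truth <- function(truth, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    gr <- GenomicRanges::GRanges(
      seqnames = truth$contig_id,
      ranges = IRanges::IRanges(start = truth$start + 1L, end = truth$end))
    S4Vectors::mcols(gr)$name <- paste0(truth$element_id, "_", truth$type)
    rtracklayer::export(gr, bed_path, format = "bed")
  }
  if (!is.null(tsv_path)) {
    utils::write.table(as.data.frame(truth), tsv_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  invisible(c(bed_path, tsv_path))
}
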