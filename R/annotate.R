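## Insertion-locus assembly and structural classification.
##
## Hits against a genome are merged into insertion loci; each locus is
## decomposed into TDR and inner-domain unit matches and classified as
## fragment, solo_TDR, canonical, tandem_array or rearranged. Tandem
## arrays follow the TDR[x] I[x-1] pattern: x TDRs alternating with x-1
## inner domains.

LOCUS_CLASSES <- c("fragment", "solo_TDR", "canonical", "tandem_array",
                   "rearranged")

#' TRIM element model
#'
#' Bundles the TDR and inner-domain consensus sequences with the
#' structural tolerances used for validation: TDR length range, inner
#' domain length range, and the minimum polypurine-tract (PPT) length at
#' the inner-domain 3' terminus.
#'
#' @param tdr_seq TDR consensus sequence.
#' @param inner_seq Inner-domain consensus sequence; its 3' end must carry
#'   a purine run of at least `ppt_min_len` bp.
#' @param tdr_len_range Accepted TDR length range in bp (default 202-218).
#' @param inner_len_range Accepted inner-domain length range in bp
#'   (default 77-80).
#' @param ppt_min_len Minimum PPT length in bp (default 7).
#' @return A `trim_consensus` object with fields `tdr_seq`, `inner_seq`,
#'   `ppt_seq`, `element` (TDR + inner + TDR), and the tolerances.
#' @export
trim_consensus <- function(tdr_seq, inner_seq, tdr_len_range = c(202L, 218L),
                           inner_len_range = c(77L, 80L), ppt_min_len = 7L) {
  tdr <- as_dna(tdr_seq); inner <- as_dna(inner_seq)
  ppt <- find_ppt(inner, min_len = ppt_min_len)
  if (is.null(ppt)) {
    stop("inner domain does not end in a purine run of at least ",
         ppt_min_len, " bp (no PPT)")
  }
  element <- Biostrings::xscat(tdr, inner, tdr)
  if (length(element) >= 1000L) {
    stop("canonical element (TDR + inner + TDR) must be shorter than ",
         "1000 bp; got ", length(element))
  }
  structure(list(tdr_seq = tdr, inner_seq = inner, ppt_seq = ppt$seq,
                 element = element,
                 tdr_len_range = as.integer(tdr_len_range),
                 inner_len_range = as.integer(inner_len_range),
                 ppt_min_len = as.integer(ppt_min_len)),
            class = "trim_consensus")
}

#' @export
print.trim_consensus <- function(x, ...) {
  cat("TRIM consensus: TDR", length(x$tdr_seq), "bp, inner domain",
      length(x$inner_seq), "bp, PPT", x$ppt_seq,
      sprintf("(element %d bp)\n", length(x$element)))
  invisible(x)
}

## vectorised interval merge; returns merged [start,end) intervals.
## Book-ended intervals (gap 0) are contiguous under the half-open
## convention and merge when merge_distance >= 0.
merge_intervals <- function(start, end, merge_distance = 0L) {
  o <- order(start, end)
  start <- start[o]; end <- end[o]
  cummax_end <- cummax(end)
  new_block <- c(TRUE, start[-1] > cummax_end[-length(end)] + merge_distance)
  grp <- cumsum(new_block)
  data.frame(start = tapply(start, grp, min),
             end = tapply(end, grp, max),
             n = as.integer(table(grp)))
}

#' Merge hits into insertion loci
#'
#' Per contig, hits are sorted by start and spans whose gap does not
#' exceed `merge_distance` are merged into a single locus (0 merges
#' overlapping and book-ended hits). Classification is initialised to
#' `fragment` pending [classify_locus()].
#'
#' @param hits A hit tibble ([seeded_search()]); `subject_id` is the
#'   contig.
#' @param merge_distance Maximum gap (bp) between hits merged into one
#'   locus (default 0).
#' @param contig_lengths Optional named vector; when given, a hit span
#'   exceeding its contig length is an error.
#' @return A tibble of loci: `contig_id`, `start`, `end`, `n_hits`,
#'   `classification` (all `fragment`), `n_tdr`, `n_inner`, sorted and
#'   pairwise disjoint within each contig.
#' @export
merge_hits_to_loci <- function(hits, merge_distance = 0L,
                               contig_lengths = NULL) {
  stopifnot(merge_distance >= 0L)
  if (nrow(hits) == 0L) {
    return(tibble::tibble(contig_id = character(), start = integer(),
                          end = integer(), n_hits = integer(),
                          classification = character(),
                          n_tdr = integer(), n_inner = integer()))
  }
  if (!is.null(contig_lengths)) {
    over <- hits$s_end > contig_lengths[hits$subject_id]
    if (any(is.na(over)) || any(over)) {
      bad <- unique(hits$subject_id[is.na(over) | over])
      stop("hit span exceeds contig length (or unknown contig): ",
           paste(bad, collapse = ", "))
    }
  }
  parts <- lapply(split(hits, hits$subject_id), function(h) {
    m <- merge_intervals(h$s_start, h$s_end, merge_distance)
    tibble::tibble(contig_id = h$subject_id[1],
                   start = as.integer(m$start), end = as.integer(m$end),
                   n_hits = m$n,
                   classification = "fragment",
                   n_tdr = 0L, n_inner = 0L)
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$contig_id, out$start), , drop = FALSE]
}

#' Decompose and classify an insertion locus
#'
#' Locates non-overlapping TDR and inner-domain unit matches in the locus
#' sequence by seeded local alignment against the consensus parts (greedy,
#' highest score first), then classifies the locus from the positional
#' layout of complete units: alternating TDR,I,...,TDR with x >= 3 TDRs is
#' a `tandem_array`; TDR,I,TDR is `canonical`; a single TDR is
#' `solo_TDR`; sub-unit coverage is a `fragment`; any other layout (e.g.
#' TDR,TDR, or a TDR interrupted by a foreign insert) is `rearranged`.
#'
#' @param locus_seq The locus sequence (extracted with flank 0).
#' @param consensus A [trim_consensus()].
#' @param complete_frac A unit match is "complete" when its subject span
#'   reaches this fraction of the unit length (default 0.8).
#' @param min_unit_identity,min_unit_length Thresholds for unit matches.
#' @param scoring A [trim_scoring()] scheme.
#' @return A list: `classification`, `n_tdr`, `n_inner`, `unit_layout`
#'   (tibble: `unit_type` in TDR/I/other, `start`, `end`, `strand`,
#'   `identity`, `complete`), and `note` for degenerate inputs.
#' @export
classify_locus <- function(locus_seq, consensus, complete_frac = 0.8,
                           min_unit_identity = 0.65, min_unit_length = 25L,
                           scoring = trim_scoring()) {
  locus <- as_dna(locus_seq)
  t_len <- length(consensus$tdr_seq)
  i_len <- length(consensus$inner_seq)
  units <- list(TDR = consensus$tdr_seq, I = consensus$inner_seq)
  cand <- list()
  for (ut in names(units)) {
    h <- seeded_search(units[[ut]], locus, seed_k = 11L,
                       min_identity = min_unit_identity,
                       min_length = min_unit_length, scoring = scoring,
                       query_id = ut, subject_id = "locus")
    if (nrow(h)) cand[[ut]] <- h
  }
  layout <- tibble::tibble(unit_type = character(), start = integer(),
                           end = integer(), strand = character(),
                           identity = double(), complete = logical())
  note <- NA_character_
  if (length(cand)) {
    cand <- do.call(rbind, cand)
    cand <- cand[order(-cand$score, cand$s_start), , drop = FALSE]
    ## greedy non-overlapping placement, highest score first
    taken_s <- integer(0); taken_e <- integer(0); keep <- logical(nrow(cand))
    for (i in seq_len(nrow(cand))) {
      ov <- FALSE
      if (length(taken_s)) {
        o <- pmin(taken_e, cand$s_end[i]) - pmax(taken_s, cand$s_start[i])
        ov <- any(o > 0.1 * pmin(taken_e - taken_s,
                                 cand$s_end[i] - cand$s_start[i]))
      }
      if (!ov) {
        keep[i] <- TRUE
        taken_s <- c(taken_s, cand$s_start[i])
        taken_e <- c(taken_e, cand$s_end[i])
      }
    }
    cand <- cand[keep, , drop = FALSE]
    cand <- cand[order(cand$s_start), , drop = FALSE]
    unit_len <- ifelse(cand$query_id == "TDR", t_len, i_len)
    layout <- tibble::tibble(
      unit_type = cand$query_id,
      start = cand$s_start, end = cand$s_end, strand = cand$strand,
      identity = cand$identity,
      complete = (cand$s_end - cand$s_start) >= complete_frac * unit_len)
  }
  ## interleave 'other' rows for unannotated stretches >= 50 bp
  layout <- add_other_units(layout, length(locus))
  comp <- layout[layout$complete %in% TRUE & layout$unit_type != "other", ,
                 drop = FALSE]
  x <- sum(comp$unit_type == "TDR")
  ni <- sum(comp$unit_type == "I")
  pattern <- paste(comp$unit_type, collapse = ",")
  alternating <- function(n) paste(rep(c("TDR", "I"), length.out = 2L * n - 1L),
                                   collapse = ",")
  classification <-
    if (x >= 3L && ni == x - 1L && pattern == alternating(x)) "tandem_array"
    else if (x == 2L && ni == 1L && pattern == "TDR,I,TDR") "canonical"
    else if (x == 1L && ni == 0L) "solo_TDR"
    else if (x == 0L && ni == 0L &&
             nrow(layout[layout$unit_type != "other", ]) == 0L) {
      note <- "no unit match against consensus; defaulting to fragment"
      "fragment"
    }
    else if (x == 0L && length(locus) < t_len) "fragment"
    else "rearranged"
  list(classification = classification, n_tdr = x, n_inner = ni,
       unit_layout = layout, note = note)
}

add_other_units <- function(layout, locus_len, min_gap = 50L) {
  bounds <- rbind(c(0L, 0L), cbind(layout$start, layout$end),
                  c(locus_len, locus_len))
  gaps <- data.frame(start = head(bounds[, 2], -1), end = bounds[-1, 1])
  gaps <- gaps[gaps$end - gaps$start >= min_gap, , drop = FALSE]
  if (nrow(gaps)) {
    layout <- rbind(layout,
                    tibble::tibble(unit_type = "other",
                                   start = as.integer(gaps$start),
                                   end = as.integer(gaps$end),
                                   strand = "+", identity = NA_real_,
                                   complete = FALSE))
  }
  layout[order(layout$start, layout$end), , drop = FALSE]
}

#' Classify all loci of a genome
#'
#' Extracts each locus sequence (flank 0) and runs [classify_locus()].
#'
#' @param loci Locus tibble from [merge_hits_to_loci()].
#' @param genome A named `DNAStringSet` of contigs.
#' @param consensus A [trim_consensus()].
#' @param ... Passed to [classify_locus()].
#' @return `loci` with `classification`, `n_tdr`, `n_inner` filled and a
#'   `unit_layout` list-column.
#' @export
classify_loci <- function(loci, genome, consensus, ...) {
  genome <- as_dna_set(genome)
  res <- lapply(seq_len(nrow(loci)), function(i) {
    contig <- genome[[loci$contig_id[i]]]
    classify_locus(Biostrings::subseq(contig, loci$start[i] + 1L,
                                      loci$end[i]),
                   consensus, ...)
  })
  loci$classification <- vapply(res, `[[`, character(1), "classification")
  loci$n_tdr <- vapply(res, `[[`, integer(1), "n_tdr")
  loci$n_inner <- vapply(res, `[[`, integer(1), "n_inner")
  loci$unit_layout <- lapply(res, `[[`, "unit_layout")
  loci
}

#' Genome-contribution statistics of insertion loci
#'
#' @param loci Locus tibble (disjoint per contig).
#' @param genome_bp Total genome size in bp (> 0).
#' @return A `genome_stats` list: `n_loci`, `locus_length_median` (lower
#'   median), `locus_length_min`, `locus_length_max`, `covered_bp`,
#'   `genome_bp`, `fraction`, `class_counts`, `fragment_share`.
#' @export
genome_stats <- function(loci, genome_bp) {
  if (genome_bp <= 0) stop("genome_bp must be positive")
  lens <- loci$end - loci$start
  covered <- sum(lens)
  n <- nrow(loci)
  lower_median <- if (n == 0L) NA_integer_ else
    sort(lens)[floor((n + 1L) / 2L)]
  counts <- table(factor(loci$classification, levels = LOCUS_CLASSES))
  structure(list(
    n_loci = n,
    locus_length_median = lower_median,
    locus_length_min = if (n) min(lens) else NA_integer_,
    locus_length_max = if (n) max(lens) else NA_integer_,
    covered_bp = covered,
    genome_bp = genome_bp,
    fraction = covered / genome_bp,
    class_counts = as.integer(counts) |> setNames(names(counts)),
    fragment_share = if (n) unname(counts["fragment"]) / n else NA_real_),
    class = "genome_stats")
}

#' @export
print.genome_stats <- function(x, ...) {
  cat(sprintf(
    "%d insertion loci; lengths %s-%s bp (median %s); %d bp covered = %.4f%% of %d bp\n",
    x$n_loci, x$locus_length_min, x$locus_length_max,
    x$locus_length_median, x$covered_bp, 100 * x$fraction, x$genome_bp))
  print(x$class_counts)
  invisible(x)
}

#' Validate the structure of a candidate element
#'
#' Checks a unit layout plus sequences against the element model: every
#' TDR length within the TDR range, every inner-domain length within the
#' inner range, a purine run of at least the PPT minimum at each inner
#' domain's 3' terminus, and total element length below 1000 bp.
#'
#' @param unit_seqs Named list/character vector of unit sequences in
#'   element order; names are `TDR` or `I` (suffixes allowed, e.g.
#'   `TDR_1`).
#' @param consensus A [trim_consensus()].
#' @return `list(pass = logical, reasons = character vector)` with one
#'   reason per violated rule.
#' @export
validate_element <- function(unit_seqs, consensus) {
  stopifnot(length(unit_seqs) >= 1L)
  types <- sub("[_.].*$", "", names(unit_seqs))
  stopifnot(all(types %in% c("TDR", "I")))
  seqs <- vapply(unit_seqs, function(s) as.character(as_dna(s)), character(1))
  lens <- nchar(seqs)
  reasons <- character()
  tr <- consensus$tdr_len_range; ir <- consensus$inner_len_range
  for (i in seq_along(seqs)) {
    if (types[i] == "TDR" && (lens[i] < tr[1] || lens[i] > tr[2])) {
      reasons <- c(reasons, sprintf(
        "TDR length %d outside [%d,%d]", lens[i], tr[1], tr[2]))
    }
    if (types[i] == "I") {
      if (lens[i] < ir[1] || lens[i] > ir[2]) {
        reasons <- c(reasons, sprintf(
          "inner-domain length %d outside [%d,%d]", lens[i], ir[1], ir[2]))
      }
      ppt <- find_ppt(seqs[i], min_len = consensus$ppt_min_len)
      if (is.null(ppt)) {
        reasons <- c(reasons, sprintf(
          "no purine run of >= %d bp at inner-domain 3' terminus",
          consensus$ppt_min_len))
      }
    }
  }
  if (sum(lens) >= 1000L) {
    reasons <- c(reasons, sprintf(
      "total element length %d not below 1000 bp", sum(lens)))
  }
  list(pass = length(reasons) == 0L, reasons = reasons)
}

## ---- writers ----------------------------------------------------------

loci_to_granges <- function(loci) {
  gr <- GenomicRanges::GRanges(
    seqnames = loci$contig_id,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end))
  S4Vectors::mcols(gr)$classification <- loci$classification
  S4Vectors::mcols(gr)$n_tdr <- loci$n_tdr
  S4Vectors::mcols(gr)$n_inner <- loci$n_inner
  gr
}

#' Write insertion loci as GFF3 (1-based, closed)
#'
#' @param loci Locus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_gff3 <- function(loci, path) {
  gr <- loci_to_granges(loci)
  S4Vectors::mcols(gr)$type <- "dispersed_repeat"
  S4Vectors::mcols(gr)$source <- "trimscape"
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Write insertion loci as BED (0-based, half-open)
#'
#' @param loci Locus tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loci_bed <- function(loci, path) {
  gr <- loci_to_granges(loci)
  S4Vectors::mcols(gr)$name <- paste0(loci$classification, "_x", loci$n_tdr)
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Write genome statistics as TSV
#'
#' @param stats A `genome_stats` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genome_stats_tsv <- function(stats, path) {
  flat <- c(stats[c("n_loci", "locus_length_median", "locus_length_min",
                    "locus_length_max", "covered_bp", "genome_bp",
                    "fraction", "fragment_share")],
            as.list(setNames(stats$class_counts,
                             paste0("n_", names(stats$class_counts)))))
  df <- data.frame(metric = names(flat),
                   value = vapply(flat, as.numeric, numeric(1)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
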