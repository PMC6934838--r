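## Multiple alignment, p-distances, neighbor-joining trees with column
## bootstrap, intra-/inter-specific divergence summaries and
## horizontal-transfer candidate flagging.
##
## Trees are distance-based (NJ on p-distances) with nodal support from
## column bootstrap; cluster-level reading of the trees is the goal, not
## model-based branch length estimation.

#' Drop sequences below a minimum length
#'
#' Short sequences carry too little signal for alignment-based analyses;
#' the scan convention excludes anything under 80 bp.
#'
#' @param seqs A `DNAStringSet`.
#' @param min_len Minimum length in bp (default 80).
#' @return The retained sequences; the number removed is messaged.
#' @export
length_filter <- function(seqs, min_len = 80L) {
  seqs <- as_dna_set(seqs)
  keep <- Biostrings::width(seqs) >= min_len
  if (sum(!keep) > 0L) {
    message(sum(!keep), " sequence(s) shorter than ", min_len, " bp removed")
  }
  if (!any(keep)) stop("all sequences removed by length filter; nothing to align")
  seqs[keep]
}

#' Multiple sequence alignment
#'
#' Progressive alignment via MAFFT (`--auto`); deterministic for a given
#' input. Row order follows the input; degapping any row reproduces the
#' input sequence.
#'
#' @param seqs A named `DNAStringSet` (>= 2 sequences, unique names).
#' @return A gapped `DNAStringSet` (all rows equal width).
#' @export
align_msa <- function(seqs) {
  seqs <- as_dna_set(seqs)
  stopifnot(length(seqs) >= 2L, all(Biostrings::width(seqs) >= 1L),
            !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  tf <- tempfile(fileext = ".fa"); out <- tempfile(fileext = ".fa")
  on.exit(unlink(c(tf, out)))
  write_fasta(seqs, tf)
  status <- system2("mafft", c("--auto", "--quiet", shQuote(tf)), stdout = out)
  if (!identical(status, 0L)) stop("mafft failed with status ", status)
  aln <- Biostrings::readBStringSet(out)
  names(aln) <- sub("\\s.*$", "", names(aln))
  aln <- Biostrings::DNAStringSet(toupper(as.character(aln)))
  aln <- aln[names(seqs)]
  stopifnot(length(unique(Biostrings::width(aln))) == 1L)
  degapped <- gsub("-", "", as.character(aln), fixed = TRUE)
  if (!identical(unname(degapped), unname(as.character(seqs)))) {
    stop("alignment rows do not degap to the input sequences")
  }
  aln
}

msa_matrix <- function(msa) {
  m <- do.call(rbind, strsplit(as.character(msa), "", fixed = TRUE))
  rownames(m) <- names(msa)
  m
}

#' Pairwise p-distance matrix from an alignment
#'
#' p-distance = mismatched columns / compared columns. With pairwise
#' deletion, columns with a gap (or N) in either row of a pair are
#' excluded for that pair; otherwise columns with any gap are excluded
#' globally.
#'
#' @param msa A gapped `DNAStringSet` (or character matrix) with >= 2 rows.
#' @param pairwise_deletion Exclude gapped columns per pair (default TRUE).
#' @param on_missing What to do with pairs that share no comparable
#'   column: `"error"` (default) or `"impute_max"` (replace by the largest
#'   finite distance; used internally by the bootstrap).
#' @return A `distance_matrix` list: `ids`, symmetric `d` in \[0,1\],
#'   `pairwise_deletion`.
#' @export
pdistance_matrix <- function(msa, pairwise_deletion = TRUE,
                             on_missing = c("error", "impute_max")) {
  on_missing <- match.arg(on_missing)
  m <- if (is.matrix(msa)) msa else msa_matrix(msa)
  stopifnot(nrow(m) >= 2L)
  bin <- ape::as.DNAbin(tolower(m))
  d <- as.matrix(ape::dist.dna(bin, model = "raw",
                               pairwise.deletion = pairwise_deletion))
  diag(d) <- 0
  if (any(!is.finite(d))) {
    if (on_missing == "error") {
      stop("some sequence pairs share no comparable column")
    }
    d[!is.finite(d)] <- max(d[is.finite(d)], 0)
  }
  structure(list(ids = rownames(m), d = d,
                 pairwise_deletion = pairwise_deletion),
            class = "distance_matrix")
}

#' Neighbor-joining tree
#'
#' Canonical NJ on a p-distance matrix. Negative branch-length estimates
#' are clamped to zero with a warning.
#'
#' @param dm A `distance_matrix` ([pdistance_matrix()]) or a symmetric
#'   numeric matrix (>= 3 taxa).
#' @param warn_negative Warn when negative branch estimates are clamped
#'   (silenced inside bootstrap replicates).
#' @return An [ape::phylo] tree (unrooted).
#' @export
nj_tree <- function(dm, warn_negative = TRUE) {
  d <- if (inherits(dm, "distance_matrix")) dm$d else as.matrix(dm)
  stopifnot(nrow(d) >= 3L)
  if (any(!is.finite(d))) stop("non-finite distances; cannot build NJ tree")
  tr <- ape::nj(d)
  neg <- tr$edge.length < 0
  if (any(neg)) {
    if (warn_negative) {
      warning(sum(neg), " negative NJ branch length(s) clamped to 0")
    }
    tr$edge.length[neg] <- 0
  }
  tr
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree per
#' replicate, and reports for each internal edge of the point-estimate
#' tree the percentage of replicates containing the same bipartition.
#' Reproducible under a fixed seed; replicate seeds are drawn once from
#' the master seed, so supports do not depend on taxon input order.
#'
#' @param msa A gapped `DNAStringSet` or character matrix.
#' @param n_reps Number of bootstrap replicates (default 100).
#' @param seed Master seed (mandatory).
#' @return A list: `tree` (point estimate, `node.label` = support), and
#'   `supports` (percent per internal node; NA for the root trifurcation).
#' @export
bootstrap_supports <- function(msa, n_reps = 100L, seed) {
  stopifnot(n_reps >= 1L, !missing(seed))
  m <- if (is.matrix(msa)) msa else msa_matrix(msa)
  point <- nj_tree(pdistance_matrix(m, on_missing = "impute_max"))
  ncols <- ncol(m)
  rep_seeds <- withr::with_seed(seed, sample.int(.Machine$integer.max - 1L,
                                                 n_reps))
  boot <- lapply(rep_seeds, function(s) {
    idx <- withr::with_seed(s, sample.int(ncols, ncols, replace = TRUE))
    nj_tree(pdistance_matrix(m[, idx, drop = FALSE],
                             on_missing = "impute_max"),
            warn_negative = FALSE)
  })
  counts <- ape::prop.clades(point, boot, rooted = FALSE)
  supports <- 100 * counts / n_reps
  point$node.label <- ifelse(is.na(supports), "",
                             format(round(supports, 1), trim = TRUE))
  list(tree = point, supports = supports, n_reps = n_reps)
}

#' Intra- and inter-specific identity summary
#'
#' Mean pairwise identity (100 x (1 - p-distance)) over all intra-species
#' pairs per species and all inter-species pairs per species pair. Cells
#' with no pair are absent from the output.
#'
#' @param msa A gapped `DNAStringSet`, character matrix, or
#'   `distance_matrix`.
#' @param species_of Named character vector mapping every sequence id to a
#'   species.
#' @return A `divergence_summary` list with tibbles `intra` (`species`,
#'   `mean_identity`, `n_pairs`) and `inter` (`species_a`, `species_b`,
#'   `mean_identity`, `n_pairs`).
#' @export
divergence_summary <- function(msa, species_of) {
  dm <- if (inherits(msa, "distance_matrix")) msa else pdistance_matrix(msa)
  ids <- dm$ids
  unmapped <- setdiff(ids, names(species_of))
  if (length(unmapped)) {
    stop("ids not mapped to a species: ", paste(unmapped, collapse = ", "))
  }
  sp <- species_of[ids]
  idm <- 100 * (1 - dm$d)
  species <- sort(unique(sp))
  intra <- list(); inter <- list()
  for (a in species) {
    ia <- which(sp == a)
    if (length(ia) >= 2L) {
      pairs <- utils::combn(ia, 2L)
      vals <- idm[cbind(pairs[1, ], pairs[2, ])]
      intra[[a]] <- tibble::tibble(species = a, mean_identity = mean(vals),
                                   n_pairs = ncol(pairs))
    }
  }
  if (length(species) >= 2L) {
    for (pq in utils::combn(length(species), 2L, simplify = FALSE)) {
      a <- species[pq[1]]; b <- species[pq[2]]
      ia <- which(sp == a); ib <- which(sp == b)
      vals <- idm[ia, ib, drop = FALSE]
      inter[[paste(a, b)]] <- tibble::tibble(
        species_a = a, species_b = b,
        mean_identity = mean(vals), n_pairs = length(vals))
    }
  }
  empty_intra <- tibble::tibble(species = character(),
                                mean_identity = double(), n_pairs = integer())
  empty_inter <- tibble::tibble(species_a = character(),
                                species_b = character(),
                                mean_identity = double(), n_pairs = integer())
  structure(list(
    intra = if (length(intra)) do.call(rbind, intra) else empty_intra,
    inter = if (length(inter)) do.call(rbind, inter) else empty_inter),
    class = "divergence_summary")
}

#' @export
print.divergence_summary <- function(x, ...) {
  cat("Intra-specific identity (%):\n"); print(x$intra)
  cat("Inter-specific identity (%):\n"); print(x$inter)
  invisible(x)
}

#' Flag horizontal-transfer candidate species pairs
#'
#' A pair is flagged when its inter-specific identity matches or exceeds
#' the smaller of the two intra-specific identities minus `delta`
#' percentage points: elements as similar across the species boundary as
#' within species are hard to explain by vertical descent.
#'
#' @param summary A `divergence_summary`.
#' @param delta Margin in percentage points (default 0).
#' @return A tibble: `species_a`, `species_b`, `inter_identity`,
#'   `intra_a`, `intra_b`, `delta`, `flagged` (NA when an intra cell is
#'   absent).
#' @export
flag_ht_candidates <- function(summary, delta = 0) {
  inter <- summary$inter
  if (nrow(inter) == 0L) stop("summary has no inter-species cell")
  intra <- setNames(summary$intra$mean_identity, summary$intra$species)
  out <- tibble::tibble(
    species_a = inter$species_a, species_b = inter$species_b,
    inter_identity = inter$mean_identity,
    intra_a = unname(intra[inter$species_a]),
    intra_b = unname(intra[inter$species_b]),
    delta = delta)
  out$flagged <- out$inter_identity >= pmin(out$intra_a, out$intra_b) - delta
  out
}

#' Write a tree in Newick format
#'
#' Bootstrap supports (if present) are written as internal node labels.
#'
#' @param tree An [ape::phylo] tree, or the list from
#'   [bootstrap_supports()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tree_newick <- function(tree, path) {
  if (is.list(tree) && !inherits(tree, "phylo")) tree <- tree$tree
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Write a distance matrix as TSV
#'
#' @param dm A `distance_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_tsv <- function(dm, path) {
  df <- as.data.frame(dm$d)
  df <- cbind(id = dm$ids, df)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
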