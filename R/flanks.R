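## Flanking-sequence similarity: compare the genomic segments that follow
## (or precede) element insertions across clones. Similar flanks across
## clones indicate shared insertion loci (or segmental duplication);
## dissimilar flanks indicate independent insertion sites.

#' Extract the segment following an element insertion in a clone
#'
#' Locates the element in the clone by seeded search against the
#' consensus, merges the hits into one span, and returns the `flank_len`
#' bases downstream of that span.
#'
#' @param clone Clone sequence.
#' @param consensus A [trim_consensus()] (its full element is the query)
#'   or any element/exemplar sequence to anchor on.
#' @param flank_len Length of the downstream segment (default 116 bp).
#' @param min_identity,min_length Passed to [seeded_search()]
#'   (`min_length` default 50 so truncated elements still anchor).
#' @return A character string of up to `flank_len` bases (shorter when the
#'   clone ends first), or `NA` when the element is not found.
#' @export
downstream_flank <- function(clone, consensus, flank_len = 116L,
                             min_identity = 0.75, min_length = 50L) {
  clone <- as_dna(clone)
  query <- if (inherits(consensus, "trim_consensus")) consensus$element
           else as_dna(consensus)
  hits <- seeded_search(query, clone,
                        min_identity = min_identity,
                        min_length = min_length)
  if (nrow(hits) == 0L) return(NA_character_)
  loci <- merge_hits_to_loci(hits)
  span_end <- max(loci$end)
  if (span_end >= length(clone)) return(NA_character_)
  to <- min(length(clone), span_end + flank_len)
  as.character(Biostrings::subseq(clone, span_end + 1L, to))
}

#' Pairwise identity matrix from global alignment
#'
#' Aligns every pair globally and reports identity (matches over aligned
#' columns) as a percentage.
#'
#' @param seqs A named `DNAStringSet` (>= 2 sequences).
#' @param scoring A [trim_scoring()] scheme.
#' @return A symmetric matrix of identities in percent; diagonal 100.
#' @export
pairwise_identity_matrix <- function(seqs, scoring = trim_scoring()) {
  seqs <- as_dna_set(seqs)
  n <- length(seqs)
  stopifnot(n >= 2L, !is.null(names(seqs)))
  m <- matrix(100, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      aln <- align_global(seqs[[i]], seqs[[j]], scoring)
      m[i, j] <- m[j, i] <- 100 * aln$identity
    }
  }
  m
}

#' Average similarity of the flanks following elements in a clone set
#'
#' Runs [downstream_flank()] on every clone and summarises all pairwise
#' flank identities.
#'
#' @param clones A named `DNAStringSet` of clone sequences.
#' @param consensus A [trim_consensus()] or element sequence.
#' @param flank_len Flank length in bp (default 116).
#' @return A list: `flanks` (named character), `identity` (pairwise
#'   percent matrix), `mean_identity` (mean of off-diagonal pairs).
#' @export
flank_similarity <- function(clones, consensus, flank_len = 116L) {
  clones <- as_dna_set(clones)
  flanks <- vapply(seq_along(clones), function(i)
    downstream_flank(clones[[i]], consensus, flank_len), character(1))
  names(flanks) <- names(clones)
  found <- !is.na(flanks) & nchar(flanks) > 0L
  if (sum(found) < 2L) {
    stop("fewer than two clones with a located element and downstream flank")
  }
  idm <- pairwise_identity_matrix(Biostrings::DNAStringSet(flanks[found]))
  list(flanks = flanks,
       identity = idm,
       mean_identity = mean(idm[upper.tri(idm)]))
}
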