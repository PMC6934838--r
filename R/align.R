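## Pairwise alignment primitives.
##
## Thin, convention-fixing wrappers around Biostrings::pairwiseAlignment.
## Scoring follows a BLASTN-like scheme (match +2, mismatch -3, gap open
## -5, gap extend -2); a gap of length L costs gap_open + L * gap_extend.
## N never matches anything, including another N.

#' Alignment scoring scheme
#'
#' @param match Match score (positive).
#' @param mismatch Mismatch score (negative).
#' @param gap_open Gap opening score (negative); a gap of length L costs
#'   `gap_open + L * gap_extend`.
#' @param gap_extend Gap extension score per gapped column (negative).
#' @return A `trim_scoring` list.
#' @export
trim_scoring <- function(match = 2, mismatch = -3, gap_open = -5,
                         gap_extend = -2) {
  stopifnot(match > 0, mismatch < 0, gap_open <= 0, gap_extend < 0)
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend), class = "trim_scoring")
}

substitution_matrix <- function(scoring) {
  m <- matrix(scoring$mismatch, 5L, 5L,
              dimnames = list(VALID_BASES, VALID_BASES))
  diag(m) <- scoring$match
  m["N", "N"] <- scoring$mismatch  # N is always a non-match
  m
}

align_pair <- function(a, b, scoring, type) {
  a <- as_dna(a); b <- as_dna(b)
  stopifnot(length(a) > 0L, length(b) > 0L)
  aln <- Biostrings::pairwiseAlignment(
    a, b, type = type,
    substitutionMatrix = substitution_matrix(scoring),
    gapOpening = -scoring$gap_open, gapExtension = -scoring$gap_extend)
  pa <- as.character(Biostrings::pattern(aln))
  pb <- as.character(Biostrings::subject(aln))
  if (type == "local" && Biostrings::score(aln) < 0) {
    ## no positive-scoring pair exists: the optimal local alignment is empty
    return(empty_alignment())
  }
  ca <- strsplit(pa, "")[[1]]; cb <- strsplit(pb, "")[[1]]
  ncol <- length(ca)
  ident <- if (ncol == 0L) 0 else
    sum(ca == cb & ca != "-" & ca != "N") / ncol
  structure(list(
    aligned_a = pa, aligned_b = pb,
    score = Biostrings::score(aln),
    identity = ident,
    a_span = c(BiocGenerics::start(Biostrings::pattern(aln)) - 1L,
               BiocGenerics::end(Biostrings::pattern(aln))),
    b_span = c(BiocGenerics::start(Biostrings::subject(aln)) - 1L,
               BiocGenerics::end(Biostrings::subject(aln))),
    strand = "+"), class = "pairwise_alignment")
}

empty_alignment <- function() {
  structure(list(aligned_a = "", aligned_b = "", score = 0, identity = 0,
                 a_span = c(0L, 0L), b_span = c(0L, 0L), strand = "+"),
            class = "pairwise_alignment")
}

#' Global (Needleman-Wunsch) alignment with affine gaps
#'
#' End gaps are penalised. Identity is the fraction of aligned columns that
#' are matches; gap columns count as non-matches.
#'
#' @param a,b Sequences (`DNAString`, length-1 `DNAStringSet` or character).
#' @param scoring A [trim_scoring()] scheme.
#' @return A `pairwise_alignment` list: `aligned_a`, `aligned_b`, `score`,
#'   `identity`, 0-based half-open `a_span` / `b_span`, `strand`.
#' @export
align_global <- function(a, b, scoring = trim_scoring()) {
  align_pair(a, b, scoring, "global")
}

#' Local (Smith-Waterman) alignment with affine gaps
#'
#' The empty alignment (score 0) is returned when no positive-scoring pair
#' of segments exists.
#'
#' @inheritParams align_global
#' @return A `pairwise_alignment` list; `score >= 0`.
#' @export
align_local <- function(a, b, scoring = trim_scoring()) {
  align_pair(a, b, scoring, "local")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("pairwise alignment: score", x$score,
      sprintf("identity %.3f", x$identity),
      sprintf("a[%d,%d) b[%d,%d) strand %s\n",
              x$a_span[1], x$a_span[2], x$b_span[1], x$b_span[2], x$strand))
  invisible(x)
}

alignment_identity <- function(aligned_a, aligned_b) {
  ca <- strsplit(aligned_a, "")[[1]]; cb <- strsplit(aligned_b, "")[[1]]
  if (length(ca) == 0L) return(0)
  sum(ca == cb & ca != "-" & ca != "N") / length(ca)
}
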