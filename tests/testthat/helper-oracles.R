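# Independent oracles used by the tests. These deliberately avoid the
# package's own code paths: plain-R Gotoh dynamic programming for
# alignment scores, direct column recounts for distances, and a naive
# interval sweep for merging.

rand_dna <- function(n, bases = c("A", "C", "G", "T")) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# Affine-gap DP (three-state Gotoh). A gap of length L costs
# open + L * ext. `type` is "global" (end gaps penalised) or "local"
# (empty alignment allowed, score >= 0).
oracle_align_score <- function(a, b, match = 2, mismatch = -3,
                               open = 5, ext = 2, type = "global") {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  if (type == "global") {
    for (i in seq_len(n)) X[i + 1, 1] <- -(open + i * ext)
    for (j in seq_len(m)) Y[1, j + 1] <- -(open + j * ext)
  }
  best_local <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (a[i] == b[j] && a[i] != "N") match else mismatch
      prev <- max(M[i, j], X[i, j], Y[i, j])
      M[i + 1, j + 1] <- if (type == "local") max(prev, 0) + s else prev + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext,
                             Y[i, j + 1] - open - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext,
                             X[i + 1, j] - open - ext)
      if (M[i + 1, j + 1] > best_local) best_local <- M[i + 1, j + 1]
    }
  }
  if (type == "local") best_local
  else max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# direct recount of the p-distance between two gapped rows
oracle_pdist <- function(ra, rb) {
  a <- strsplit(ra, "")[[1]]; b <- strsplit(rb, "")[[1]]
  ok <- a != "-" & b != "-" & a != "N" & b != "N"
  sum(a[ok] != b[ok]) / sum(ok)
}

# naive interval merge by boolean coverage sweep (book-ended intervals
# are contiguous under the half-open convention)
oracle_merge <- function(start, end) {
  if (!length(start)) return(data.frame(start = integer(), end = integer()))
  lim <- max(end) + 1L
  cov <- logical(lim)
  for (i in seq_along(start)) {
    if (end[i] > start[i]) cov[(start[i] + 1L):end[i]] <- TRUE
  }
  r <- rle(cov)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  data.frame(start = starts[r$values], end = ends[r$values])
}

# expected p-distance between two copies independently mutated from a
# shared consensus at substitution rates d1, d2 (uniform alternative base)
expected_pair_pdist <- function(d1, d2) {
  d1 * (1 - d2) + d2 * (1 - d1) + d1 * d2 * 2 / 3
}

make_hits <- function(s_start, s_end, contig = "c1") {
  tibble::tibble(query_id = "q", subject_id = contig,
                 q_start = 0L, q_end = s_end - s_start,
                 s_start = as.integer(s_start), s_end = as.integer(s_end),
                 strand = "+", length = as.integer(s_end - s_start),
                 identity = 1, score = 2 * (s_end - s_start))
}
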