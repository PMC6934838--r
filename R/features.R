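## Inner-domain substructure annotation: polypurine tract, inverted
## repeats / palindromes (hairpin geometry), conserved central motifs,
## and PBS candidates against a user-supplied tRNA collection.

#' Find the polypurine tract at the inner-domain 3' terminus
#'
#' Reports the maximal run of purines (A/G) ending exactly at the 3'
#' terminus, if it reaches `min_len`.
#'
#' @param inner Inner-domain sequence.
#' @param min_len Minimum PPT length (default 7 bp).
#' @return `list(seq, start, end, length)` with a 0-based half-open span
#'   inside the inner domain, or `NULL` when the terminal base is a
#'   pyrimidine/N or the run is too short.
#' @export
find_ppt <- function(inner, min_len = 7L) {
  s <- toupper(as.character(as_dna(inner)))
  m <- regmatches(s, regexpr("[AG]+$", s))
  if (length(m) == 0L || nchar(m) < min_len) return(NULL)
  n <- nchar(s)
  list(seq = m, start = n - nchar(m), end = n, length = nchar(m))
}

## core scan shared by find_inverted_repeats and find_palindromes.
## Geometry: left arm [e-L, e), right arm [r, r+L), spacer = r - e fixed;
## arms grow outward from the (e, r) junctions while the mismatch budget
## holds, then terminal mismatched pairs are trimmed so arms end in a
## paired base.
ir_scan <- function(seq, min_arm, max_spacer, max_mismatch) {
  ch <- dna_chars(seq)
  n <- length(ch)
  comp <- COMPLEMENT[ch]           # comp[p] pairs with ch at the other arm
  rows <- list()
  for (e in seq_len(n - 1L)) {      # e = 0-based exclusive end of left arm
    for (spacer in 0:max_spacer) {
      r <- e + spacer               # 0-based start of right arm
      if (r + 1L > n) break
      mm <- 0L; mm_j <- integer(0); L <- 0L
      while (e - L >= 1L && r + L + 1L <= n) {
        ## next outward pair: left index e-L (1-based e-L), right r+L+1
        is_mm <- ch[e - L] != comp[r + L + 1L] ||
          ch[e - L] == "N" || ch[r + L + 1L] == "N"
        ## arms begin on a paired base: a mismatched innermost pair means
        ## this geometry is the inward-shifted shadow of another (e, r)
        if (is_mm && L == 0L) break
        if (is_mm && mm + 1L > max_mismatch) break
        if (is_mm) { mm <- mm + 1L; mm_j <- c(mm_j, L) }
        L <- L + 1L
      }
      ## trim terminal (outermost) mismatched pairs
      while (L > 0L && length(mm_j) && mm_j[length(mm_j)] == L - 1L) {
        mm_j <- mm_j[-length(mm_j)]
        mm <- mm - 1L
        L <- L - 1L
      }
      if (L < min_arm) next
      left_arm <- ch[(e - L + 1L):e]
      if (length(unique(left_arm)) < 2L) next   # homopolymer suppression
      rows[[length(rows) + 1L]] <- list(
        arm_len = L, left_start = e - L, left_end = e,
        right_start = r, right_end = r + L,
        spacer = spacer, mismatches = mm,
        ## within-arm positions (1-based): pair j joins left position L-j
        ## with right position j+1
        mismatch_positions = if (mm) cbind(left = L - mm_j, right = mm_j + 1L)
                             else cbind(left = integer(0), right = integer(0)),
        palindromic = spacer == 0L)
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(arm_len = integer(), left_start = integer(),
                          left_end = integer(), right_start = integer(),
                          right_end = integer(), spacer = integer(),
                          mismatches = integer(),
                          mismatch_positions = list(),
                          palindromic = logical()))
  }
  out <- tibble::tibble(
    arm_len = vapply(rows, `[[`, integer(1), "arm_len"),
    left_start = vapply(rows, `[[`, integer(1), "left_start"),
    left_end = vapply(rows, `[[`, integer(1), "left_end"),
    right_start = vapply(rows, `[[`, integer(1), "right_start"),
    right_end = vapply(rows, `[[`, integer(1), "right_end"),
    spacer = vapply(rows, `[[`, integer(1), "spacer"),
    mismatches = vapply(rows, `[[`, integer(1), "mismatches"),
    mismatch_positions = lapply(rows, `[[`, "mismatch_positions"),
    palindromic = vapply(rows, `[[`, logical(1), "palindromic"))
  ## drop scans that report a sub-arm of the same maximal pair reached
  ## from a shifted (e, r): keep only rows not contained in a longer row
  ## with identical spacer and arm axis
  out[order(-out$arm_len, out$mismatches, out$left_start), , drop = FALSE]
}

#' Find inverted repeats
#'
#' Scans for arm pairs whose right arm reverse-complements the left arm up
#' to `max_mismatch` positions, separated by at most `max_spacer` bp. Arms
#' are extended maximally while the mismatch budget holds; single-letter
#' (homopolymer) arms are suppressed. Results are sorted by arm length
#' (descending), mismatches (ascending), then left start.
#'
#' @param seq Sequence to scan.
#' @param min_arm Minimum arm length (>= 6).
#' @param max_spacer Maximum distance between the arms (bp).
#' @param max_mismatch Maximum mismatched pairs per arm.
#' @return A tibble: `arm_len`, 0-based half-open `left_start`/`left_end`/
#'   `right_start`/`right_end`, `spacer`, `mismatches`,
#'   `mismatch_positions` (list of 1-based within-arm position pairs),
#'   `palindromic`.
#' @export
find_inverted_repeats <- function(seq, min_arm = 8L, max_spacer = 41L,
                                  max_mismatch = 1L) {
  stopifnot(min_arm >= 6L)
  ir_scan(seq, min_arm, max_spacer, max_mismatch)
}

#' Find palindromes
#'
#' Special case of [find_inverted_repeats()] with spacer 0 and no
#' mismatches: each reported site equals its own reverse complement.
#'
#' @param seq Sequence to scan.
#' @param min_len Minimum palindrome length (even, >= 6); arms are
#'   `min_len / 2`.
#' @return As [find_inverted_repeats()], with `spacer` 0 and
#'   `palindromic` TRUE.
#' @export
find_palindromes <- function(seq, min_len = 6L) {
  stopifnot(min_len >= 6L, min_len %% 2L == 0L)
  ir_scan(seq, min_arm = min_len %/% 2L, max_spacer = 0L, max_mismatch = 0L)
}

#' Find conserved motifs shared across inner domains
#'
#' Sliding k-mer consensus search: for each window size k (largest first),
#' every observed window is a candidate; a sequence supports a candidate
#' when it carries a window within `min_identity` (Hamming). Candidates
#' present in at least `min_share` of the sequences are reported
#' longest-first, skipping candidates overlapping previously reported
#' spans; the reported consensus is the column-majority of the supporting
#' windows.
#'
#' @param inners A named `DNAStringSet` (>= 3 sequences).
#' @param k_range Window sizes `c(min, max)` to scan; clamped to the
#'   shortest sequence.
#' @param min_share Minimum fraction of sequences carrying the motif.
#' @param min_identity Minimum per-sequence window identity.
#' @return A tibble: `consensus`, `k`, `share`, `mean_identity`, `spans`
#'   (list of per-sequence 0-based half-open spans).
#' @export
find_conserved_motif <- function(inners, k_range = c(10L, 20L),
                                 min_share = 0.8, min_identity = 0.85) {
  inners <- as_dna_set(inners)
  stopifnot(length(inners) >= 3L)
  if (is.null(names(inners))) names(inners) <- paste0("seq", seq_along(inners))
  seq_ch <- lapply(seq_along(inners), function(i) dna_chars(inners[[i]]))
  min_len <- min(lengths(seq_ch))
  k_hi <- min(k_range[2], min_len)
  k_lo <- min(k_range[1], k_hi)
  n_seq <- length(inners)
  motifs <- list()
  claimed <- lapply(seq_len(n_seq), function(i) cbind(integer(0), integer(0)))
  for (k in seq(k_hi, k_lo)) {
    win <- lapply(seq_ch, function(ch) {
      if (length(ch) < k) return(NULL)
      st <- seq_len(length(ch) - k + 1L)
      m <- vapply(seq_len(k), function(o) ch[st + o - 1L], character(length(st)))
      matrix(m, nrow = length(st))
    })
    cand <- unique(do.call(rbind, win[!vapply(win, is.null, logical(1))]))
    if (is.null(cand) || nrow(cand) == 0L) next
    max_mm <- floor((1 - min_identity) * k)
    for (ci in seq_len(nrow(cand))) {
      cw <- cand[ci, ]
      ## best window per sequence
      best_pos <- rep(NA_integer_, n_seq); best_mm <- rep(NA_integer_, n_seq)
      for (si in seq_len(n_seq)) {
        w <- win[[si]]
        if (is.null(w)) next
        mm <- rowSums(w != matrix(cw, nrow(w), k, byrow = TRUE))
        b <- which.min(mm)
        if (mm[b] <= max_mm) { best_pos[si] <- b; best_mm[si] <- mm[b] }
      }
      support <- which(!is.na(best_pos))
      if (length(support) / n_seq < min_share) next
      ## skip if overlapping an already reported motif in any supporting seq
      overlaps <- any(vapply(support, function(si) {
        cl <- claimed[[si]]
        if (nrow(cl) == 0L) return(FALSE)
        st <- best_pos[si] - 1L
        any(pmin(cl[, 2], st + k) - pmax(cl[, 1], st) > 0L)
      }, logical(1)))
      if (overlaps) next
      mat <- t(vapply(support, function(si)
        win[[si]][best_pos[si], ], character(k)))
      ## trim weakly conserved edge columns: windows just large enough to
      ## absorb random flanks within the mismatch budget would otherwise
      ## pad the reported consensus
      agree <- apply(mat, 2, function(col) max(table(col)) / length(col))
      lead <- 0L
      while (lead < k && agree[lead + 1L] < 0.6) lead <- lead + 1L
      tail_ <- k
      while (tail_ > lead && agree[tail_] < 0.6) tail_ <- tail_ - 1L
      k_eff <- tail_ - lead
      if (k_eff < k_lo) next
      mat <- mat[, seq.int(lead + 1L, tail_), drop = FALSE]
      consensus <- apply(mat, 2, function(col)
        names(sort(table(col), decreasing = TRUE))[1])
      mm_eff <- vapply(seq_along(support), function(w)
        sum(mat[w, ] != consensus), integer(1))
      spans <- lapply(support, function(si)
        c(start = best_pos[si] - 1L + lead,
          end = best_pos[si] - 1L + lead + k_eff))
      names(spans) <- names(inners)[support]
      motifs[[length(motifs) + 1L]] <- tibble::tibble(
        consensus = paste(consensus, collapse = ""),
        k = k_eff, share = length(support) / n_seq,
        mean_identity = mean(1 - mm_eff / k_eff),
        spans = list(spans))
      for (si in support) {
        claimed[[si]] <- rbind(claimed[[si]],
                               c(best_pos[si] - 1L + lead,
                                 best_pos[si] - 1L + lead + k_eff))
      }
    }
  }
  if (!length(motifs)) {
    return(tibble::tibble(consensus = character(), k = integer(),
                          share = double(), mean_identity = double(),
                          spans = list()))
  }
  do.call(rbind, motifs)
}

#' Scan an inner domain for PBS candidates against a tRNA collection
#'
#' Locally aligns the inner domain (both strands) against every tRNA.
#' A candidate is canonical when its inner-domain span starts within the
#' first 5 bp (immediately downstream of the 5' TDR) and its tRNA span
#' abuts the tRNA 3' end. Positional descriptors place the matched tRNA
#' segment in the 5' / central / 3' third of the tRNA by midpoint.
#'
#' @param inner Inner-domain sequence.
#' @param trnas A named `DNAStringSet` of tRNA sequences (non-empty).
#' @param min_identity Minimum alignment identity (default 0.8).
#' @param min_len Minimum aligned length in bp (default 12).
#' @param scoring A [trim_scoring()] scheme.
#' @return A tibble: `trna_id`, 0-based half-open `inner_start`/`inner_end`
#'   and forward-strand `trna_start`/`trna_end`, `strand`, `identity`,
#'   `canonical`, `trna_position` (5prime/central/3prime).
#' @export
pbs_scan <- function(inner, trnas, min_identity = 0.8, min_len = 12L,
                     scoring = trim_scoring()) {
  trnas <- as_dna_set(trnas)
  if (length(trnas) == 0L) stop("tRNA set is empty")
  if (is.null(names(trnas))) names(trnas) <- paste0("tRNA", seq_along(trnas))
  inner <- as_dna(inner)
  rows <- list()
  for (ti in seq_along(trnas)) {
    trna <- trnas[[ti]]
    tlen <- length(trna)
    for (strand in c("+", "-")) {
      t_use <- if (strand == "+") trna else Biostrings::reverseComplement(trna)
      aln <- align_local(inner, t_use, scoring)
      cols <- nchar(aln$aligned_a)
      if (aln$score <= 0 || cols < min_len || aln$identity < min_identity)
        next
      tspan <- aln$b_span
      if (strand == "-") tspan <- c(tlen - aln$b_span[2], tlen - aln$b_span[1])
      mid <- mean(tspan)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        trna_id = names(trnas)[ti],
        inner_start = aln$a_span[1], inner_end = aln$a_span[2],
        trna_start = tspan[1], trna_end = tspan[2],
        strand = strand, identity = aln$identity,
        canonical = aln$a_span[1] < 5L && tspan[2] == tlen,
        trna_position = if (mid < tlen / 3) "5prime"
                        else if (mid < 2 * tlen / 3) "central"
                        else "3prime")
    }
  }
  if (!length(rows)) {
    return(tibble::tibble(trna_id = character(), inner_start = integer(),
                          inner_end = integer(), trna_start = integer(),
                          trna_end = integer(), strand = character(),
                          identity = double(), canonical = logical(),
                          trna_position = character()))
  }
  out <- do.call(rbind, rows)
  out[order(-out$identity), , drop = FALSE]
}

#' Annotate the full inner-domain feature set
#'
#' Convenience wrapper running [find_ppt()], [find_inverted_repeats()],
#' [find_palindromes()], and (optionally) [pbs_scan()] on one inner
#' domain.
#'
#' @param inner Inner-domain sequence.
#' @param trnas Optional tRNA `DNAStringSet` for the PBS scan.
#' @param ... Passed through to the individual finders.
#' @return A list with elements `ppt`, `inverted_repeats`, `palindromes`,
#'   `pbs`.
#' @export
annotate_inner_domain <- function(inner, trnas = NULL, ...) {
  list(ppt = find_ppt(inner),
       inverted_repeats = find_inverted_repeats(inner, ...),
       palindromes = find_palindromes(inner),
       pbs = if (!is.null(trnas)) pbs_scan(inner, trnas) else NULL)
}

#' Write an inner-domain feature report as TSV
#'
#' One row per feature (type, spans, arm/spacer/mismatch or identity
#' fields).
#'
#' @param features A list from [annotate_inner_domain()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_features_tsv <- function(features, path) {
  rows <- list()
  if (!is.null(features$ppt)) {
    p <- features$ppt
    rows[[1]] <- data.frame(type = "PPT", start = p$start, end = p$end,
                            detail = p$seq, value = p$length)
  }
  ir <- features$inverted_repeats
  if (!is.null(ir) && nrow(ir)) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "inverted_repeat", start = ir$left_start, end = ir$right_end,
      detail = sprintf("arm=%d;spacer=%d;mismatches=%d",
                       ir$arm_len, ir$spacer, ir$mismatches),
      value = ir$arm_len)
  }
  pal <- features$palindromes
  if (!is.null(pal) && nrow(pal)) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "palindrome", start = pal$left_start, end = pal$right_end,
      detail = sprintf("arm=%d", pal$arm_len), value = 2L * pal$arm_len)
  }
  pbs <- features$pbs
  if (!is.null(pbs) && nrow(pbs)) {
    rows[[length(rows) + 1L]] <- data.frame(
      type = "PBS_candidate", start = pbs$inner_start, end = pbs$inner_end,
      detail = sprintf("tRNA=%s;pos=%s;canonical=%s", pbs$trna_id,
                       pbs$trna_position, pbs$canonical),
      value = round(pbs$identity, 4))
  }
  df <- if (length(rows)) do.call(rbind, rows) else
    data.frame(type = character(), start = integer(), end = integer(),
               detail = character(), value = numeric())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
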