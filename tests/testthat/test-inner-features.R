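test_that("the PPT is the maximal purine suffix, or absent", {
  p <- find_ppt(paste0(rand_dna(70), "TGGGGAGA"))
  expect_identical(p$seq, "GGGGAGA")
  expect_identical(p$length, 7L)

  expect_null(find_ppt("ACGTACGTAGGGGAGAC"))   # pyrimidine terminus
  expect_null(find_ppt(paste0(rand_dna(50), "TGGGAGA")))  # run of 6 < 7

  p9 <- find_ppt("ACGTCAAGGGGAGA")
  expect_identical(p9$seq, "AAGGGGAGA")
  expect_identical(p9$length, 9L)
  ## always a suffix of the input
  expect_identical(p9$end, nchar("ACGTCAAGGGGAGA"))
})

make_ir_inner <- function(arm, spacer, mismatch_at = NULL, seed = 1) {
  ## plant arm + spacer + revcomp(arm) inside a poly-A background: A
  ## pairs only with T, so the background can neither extend the planted
  ## arms nor host a competing inverted repeat, and poly-A arms are
  ## suppressed by the homopolymer rule
  set.seed(seed)
  repeat {
    a <- strsplit(rand_dna(arm), "")[[1]]
    if (length(unique(a)) >= 3 && sum(a == "T") <= arm - 4) break
  }
  right <- rev(unname(c(A = "T", C = "G", G = "C", T = "A")[a]))
  if (!is.null(mismatch_at)) {
    j <- arm - mismatch_at            # left position p pairs with right L-p+1
    pos <- j + 1L
    right[pos] <- setdiff(c("A", "C", "G", "T"), right[pos])[1]
  }
  paste0(strrep("A", 20), paste(a, collapse = ""),
         strrep("A", spacer), paste(right, collapse = ""),
         strrep("A", 20))
}

test_that("planted inverted repeats are recovered with their geometry", {
  inner <- make_ir_inner(9, 25, seed = 71)
  ir <- find_inverted_repeats(inner)
  expect_gte(nrow(ir), 1L)
  expect_identical(ir$arm_len[1], 9L)
  expect_identical(ir$spacer[1], 25L)
  expect_identical(ir$mismatches[1], 0L)

  inner10 <- make_ir_inner(10, 25, mismatch_at = 7, seed = 72)
  ir10 <- find_inverted_repeats(inner10)
  expect_identical(ir10$arm_len[1], 10L)
  expect_identical(ir10$spacer[1], 25L)
  expect_identical(ir10$mismatches[1], 1L)
  mp <- ir10$mismatch_positions[[1]]
  expect_identical(unname(mp[, "left"]), 7L)
  expect_identical(unname(mp[, "right"]), 4L)
})

test_that("every reported inverted repeat verifies its mismatch count", {
  set.seed(73)
  for (rep in 1:5) {
    seq <- rand_dna(120)
    ir <- find_inverted_repeats(seq, min_arm = 6, max_spacer = 30,
                                max_mismatch = 1)
    if (nrow(ir) == 0) next
    ch <- strsplit(seq, "")[[1]]
    for (r in seq_len(nrow(ir))) {
      left <- paste(ch[(ir$left_start[r] + 1):ir$left_end[r]], collapse = "")
      right <- paste(ch[(ir$right_start[r] + 1):ir$right_end[r]],
                     collapse = "")
      rc <- strsplit(reverse_complement(right), "")[[1]]
      expect_identical(sum(rc != strsplit(left, "")[[1]]),
                       as.integer(ir$mismatches[r]))
    }
  }
})

test_that("sequences without complementary arms yield no inverted repeat", {
  ## alternating CA cannot pair with itself in reverse complement
  expect_identical(nrow(find_inverted_repeats(strrep("CA", 30))), 0L)
})

test_that("palindromes are self-reverse-complementary sites", {
  pal <- find_palindromes(paste0("TTT", "GAATTC", "TTT"))
  expect_identical(nrow(pal), 1L)
  expect_identical(pal$arm_len[1], 3L)
  expect_true(pal$palindromic[1])

  expect_identical(nrow(find_palindromes(strrep("A", 40))), 0L)

  set.seed(74)
  for (rep in 1:5) {
    seq <- rand_dna(150)
    pal <- find_palindromes(seq)
    ch <- strsplit(seq, "")[[1]]
    for (r in seq_len(nrow(pal))) {
      site <- paste(ch[(pal$left_start[r] + 1):pal$right_end[r]],
                    collapse = "")
      expect_identical(reverse_complement(site), site)
    }
  }
})

test_that("a motif planted in most inner domains is recovered exactly", {
  set.seed(75)
  motif <- "TGATCCCAAAGGAC"
  inners <- vapply(1:11, function(j) {
    bg <- rand_dna(78)
    if (j <= 10) paste0(substr(bg, 1, 30), motif, substr(bg, 45, 78)) else bg
  }, character(1))
  names(inners) <- paste0("sp", 1:11)
  m <- find_conserved_motif(inners, min_share = 10 / 11)
  expect_gte(nrow(m), 1L)
  expect_identical(m$consensus[1], motif)
  expect_equal(m$share[1], 10 / 11)
})

test_that("motif consensus stays within Hamming 1 under 10% per-copy noise", {
  set.seed(76)
  motif <- "TGATCCCAAAGGAC"
  inners <- vapply(1:10, function(j) {
    mm <- mutate_sequence(motif, 0.1, 0, seed = 600 + j)
    bg <- rand_dna(64)
    paste0(substr(bg, 1, 30), mm, substr(bg, 31, 64))
  }, character(1))
  names(inners) <- paste0("sp", 1:10)
  ## at 10% per-copy noise two copies differ at ~2.7 of 14 positions, so
  ## the identity threshold is relaxed to let larger windows absorb it
  m <- find_conserved_motif(inners, min_share = 0.7, min_identity = 0.8)
  expect_gte(nrow(m), 1L)
  cons <- m$consensus[1]
  ## best ungapped placement of the planted motif inside the consensus
  best <- min(vapply(0:(nchar(cons) - nchar(motif)), function(off) {
    sum(strsplit(substr(cons, off + 1, off + nchar(motif)), "")[[1]] !=
          strsplit(motif, "")[[1]])
  }, numeric(1)))
  expect_lte(best, 1)
})

test_that("random inner domains yield no long shared motif", {
  set.seed(77)
  rnd <- vapply(1:10, function(j) rand_dna(78), character(1))
  names(rnd) <- paste0("r", 1:10)
  m <- find_conserved_motif(rnd, k_range = c(12, 20), min_share = 0.9)
  expect_identical(nrow(m), 0L)
})

test_that("identical inner domains return the full sequence as the motif", {
  x <- rand_dna(40)
  m <- find_conserved_motif(setNames(rep(x, 5), paste0("i", 1:5)),
                            k_range = c(10, 100))
  expect_identical(m$consensus[1], x)
  expect_identical(m$share[1], 1)
})

test_that("PBS candidates carry the canonical flag and tRNA position", {
  set.seed(78)
  trna <- rand_dna(72)
  ## complement of the tRNA 3' end planted at inner position 0: canonical
  inner <- paste0(reverse_complement(substr(trna, 55, 72)), rand_dna(60))
  p <- pbs_scan(inner, c(tRNA_A = trna), min_len = 12)
  expect_gte(nrow(p), 1L)
  expect_true(p$canonical[1])
  expect_identical(p$inner_start[1], 0L)
  expect_identical(p$trna_end[1], 72L)

  ## a segment from the tRNA middle planted mid-inner-domain: central,
  ## not canonical
  inner2 <- paste0(rand_dna(30), reverse_complement(substr(trna, 30, 44)),
                   rand_dna(30))
  p2 <- pbs_scan(inner2, c(tRNA_A = trna), min_len = 12)
  expect_gte(nrow(p2), 1L)
  expect_false(p2$canonical[1])
  expect_identical(p2$trna_position[1], "central")

  ## no similarity above threshold: empty result, not an error
  p3 <- pbs_scan(strrep("AC", 40), c(tRNA_A = strrep("G", 72)), min_len = 12)
  expect_identical(nrow(p3), 0L)

  expect_error(pbs_scan(inner, Biostrings::DNAStringSet()), "empty")
})
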