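test_that("the length filter drops sequences under the threshold", {
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(c(79, 80, 210), rand_dna, character(1)), c("a", "b", "c")))
  expect_message(kept <- length_filter(seqs, 80), "1 sequence")
  expect_identical(names(kept), c("b", "c"))
  expect_identical(names(length_filter(seqs, 0)), names(seqs))
  expect_error(suppressMessages(length_filter(seqs, 1000)), "nothing to align")
})

test_that("alignment is gapless for identical inputs and degaps to them", {
  x <- rand_dna(60)
  msa <- align_msa(Biostrings::DNAStringSet(c(a = x, b = x)))
  expect_false(any(grepl("-", as.character(msa), fixed = TRUE)))

  ## a single deletion gives a single-gap column
  msa2 <- align_msa(Biostrings::DNAStringSet(c(a = "ACGTACGT",
                                               b = "ACGACGT")))
  expect_identical(sum(strsplit(as.character(msa2[["b"]]), "")[[1]] == "-"),
                   1L)
  expect_identical(unique(Biostrings::width(msa2)), 8L)

  set.seed(81)
  base <- rand_dna(150)
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(1:10, function(j) mutate_sequence(base, 0.05, 0.01, 700 + j),
           character(1)), paste0("s", 1:10)))
  msa3 <- align_msa(seqs)
  degap <- gsub("-", "", as.character(msa3), fixed = TRUE)
  expect_identical(unname(degap), unname(as.character(seqs)))
})

test_that("p-distances match a direct column recount", {
  m <- rbind(a = strsplit("ACGT", "")[[1]], b = strsplit("ACGT", "")[[1]])
  expect_identical(pdistance_matrix(m)$d["a", "b"], 0)
  m2 <- rbind(a = strsplit("ACGT", "")[[1]], b = strsplit("ACGA", "")[[1]])
  expect_identical(pdistance_matrix(m2)$d["a", "b"], 0.25)

  set.seed(82)
  base <- rand_dna(120)
  seqs <- Biostrings::DNAStringSet(setNames(
    vapply(1:6, function(j) mutate_sequence(base, 0.1, 0.01, 800 + j),
           character(1)), paste0("s", 1:6)))
  msa <- align_msa(seqs)
  dm <- pdistance_matrix(msa)
  rows <- as.character(msa)
  for (i in 1:5) {
    for (j in (i + 1):6) {
      expect_equal(dm$d[i, j], oracle_pdist(rows[i], rows[j]),
                   tolerance = 1e-12)
    }
  }
})

test_that("NJ solves the three-taxon case in closed form", {
  d <- matrix(c(0, .2, .4, .2, 0, .4, .4, .4, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  bl <- setNames(tr$edge.length, tr$tip.label[tr$edge[, 2]])
  expect_equal(unname(bl[c("A", "B", "C")]), c(0.1, 0.1, 0.3))
})

test_that("NJ recovers the generating tree from additive distances", {
  set.seed(83)
  for (n in c(5, 6, 8)) {
    tr0 <- ape::rtree(n, rooted = FALSE,
                      br = function(k) runif(k, 0.05, 0.4))
    d <- cophenetic(tr0)
    tr <- nj_tree(d[tr0$tip.label, tr0$tip.label])
    expect_identical(as.numeric(ape::dist.topo(tr, tr0)), 0)
    ## additivity: the NJ tree reproduces the input distances
    expect_equal(cophenetic(tr)[rownames(d), colnames(d)], d,
                 tolerance = 1e-8)
  }
})

test_that("star-like equal distances give zero internal branches", {
  d <- matrix(0.4, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  tr <- nj_tree(d)
  internal <- tr$edge[, 2] > length(tr$tip.label)
  expect_true(all(abs(tr$edge.length[internal]) < 1e-12))
})

two_clade_msa <- function(seed = 84) {
  set.seed(seed)
  anc1 <- rand_dna(150)
  anc2 <- mutate_sequence(anc1, 0.30, 0, seed = 900)
  seqs <- c(
    setNames(vapply(1:4, function(j)
      mutate_sequence(anc1, 0.02, 0, 910 + j), character(1)),
      paste0("p", 1:4)),
    setNames(vapply(1:4, function(j)
      mutate_sequence(anc2, 0.02, 0, 920 + j), character(1)),
      paste0("q", 1:4)))
  align_msa(Biostrings::DNAStringSet(seqs))
}

test_that("bootstrap gives full support to a clean bipartition, reproducibly", {
  msa <- two_clade_msa()
  bs <- bootstrap_supports(msa, n_reps = 50, seed = 42)
  ## the edge separating p* from q* must be at 100%
  tr <- bs$tree
  clades <- ape::prop.part(tr)
  labs <- attr(clades, "labels")
  support_of_split <- function(bs) {
    tr <- bs$tree
    for (node in seq_along(bs$supports)) {
      tips <- ape::extract.clade(tr, node + length(tr$tip.label))$tip.label
      if (setequal(tips, paste0("p", 1:4)) ||
          setequal(tips, paste0("q", 1:4))) {
        return(bs$supports[node])
      }
    }
    NA_real_
  }
  expect_identical(support_of_split(bs), 100)

  bs2 <- bootstrap_supports(msa, n_reps = 50, seed = 42)
  expect_identical(bs$supports, bs2$supports)

  ## single replicate: supports are 0 or 100 (root may be NA)
  bs1 <- bootstrap_supports(msa, n_reps = 1, seed = 5)
  expect_true(all(bs1$supports %in% c(0, 100) | is.na(bs1$supports)))

  ## taxon input order does not change the support of the split
  perm <- rev(seq_along(msa))
  bsr <- bootstrap_supports(msa[perm], n_reps = 50, seed = 42)
  expect_identical(support_of_split(bsr), 100)
})

test_that("divergence summaries follow the pair-counting conventions", {
  x <- rand_dna(100)
  m <- rbind(a1 = strsplit(x, "")[[1]], a2 = strsplit(x, "")[[1]],
             b1 = strsplit(mutate_sequence(x, 0.2, 0, 1), "")[[1]])
  sp <- c(a1 = "A", a2 = "A", b1 = "B")
  ds <- divergence_summary(m, sp)
  expect_identical(ds$intra$species, "A")        # single-sequence B absent
  expect_identical(ds$intra$mean_identity, 100)
  expect_identical(nrow(ds$inter), 1L)
  expect_identical(ds$inter$n_pairs, 2L)

  expect_error(divergence_summary(m, sp[1:2]), "not mapped")

  ## invariant under relabeling within a species
  m2 <- m[c(2, 1, 3), ]; rownames(m2) <- c("a1", "a2", "b1")
  ds2 <- divergence_summary(m2, sp)
  expect_equal(ds$inter$mean_identity, ds2$inter$mean_identity)
})

test_that("HT flagging compares inter- to minimum intra-specific identity", {
  fake <- structure(list(
    intra = tibble::tibble(species = c("A", "B"),
                           mean_identity = c(94, 96), n_pairs = c(10L, 10L)),
    inter = tibble::tibble(species_a = "A", species_b = "B",
                           mean_identity = 97, n_pairs = 20L)),
    class = "divergence_summary")
  expect_true(flag_ht_candidates(fake)$flagged)

  fake$inter$mean_identity <- 70
  expect_false(flag_ht_candidates(fake)$flagged)
  expect_true(flag_ht_candidates(fake, delta = 100)$flagged)
})

test_that("trees serialise to Newick with supports as node labels", {
  msa <- two_clade_msa(85)
  bs <- bootstrap_supports(msa, n_reps = 10, seed = 3)
  nwk <- withr::local_tempfile(fileext = ".nwk")
  write_tree_newick(bs, nwk)
  txt <- readLines(nwk)
  expect_match(txt, "^\\(")
  reread <- ape::read.tree(nwk)
  expect_setequal(reread$tip.label, names(msa))
})
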