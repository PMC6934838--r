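test_that("hit merging joins overlapping and book-ended spans", {
  h <- rbind(make_hits(100, 300), make_hits(250, 500), make_hits(600, 700))
  loci <- merge_hits_to_loci(h, merge_distance = 0)
  expect_identical(loci$start, c(100L, 600L))
  expect_identical(loci$end, c(500L, 700L))

  ## touching intervals are contiguous under the half-open convention
  h2 <- rbind(make_hits(0, 100), make_hits(100, 200))
  loci2 <- merge_hits_to_loci(h2, merge_distance = 0)
  expect_identical(nrow(loci2), 1L)
  expect_identical(c(loci2$start, loci2$end), c(0L, 200L))

  ## merge distance bridges small gaps
  h3 <- rbind(make_hits(0, 100), make_hits(130, 200))
  expect_identical(nrow(merge_hits_to_loci(h3, merge_distance = 0)), 2L)
  expect_identical(nrow(merge_hits_to_loci(h3, merge_distance = 30)), 1L)
})

test_that("merging is idempotent, sorted and disjoint on random inputs", {
  set.seed(61)
  for (rep in 1:50) {
    n <- sample(2:40, 1)
    s <- sample.int(5000, n, replace = TRUE)
    h <- make_hits(s, s + sample.int(300, n, replace = TRUE))
    loci <- merge_hits_to_loci(h)
    expect_true(all(diff(loci$start) > 0))
    expect_true(all(loci$start[-1] > loci$end[-nrow(loci)]))
    again <- merge_hits_to_loci(make_hits(loci$start, loci$end))
    expect_identical(again$start, loci$start)
    expect_identical(again$end, loci$end)
    om <- oracle_merge(h$s_start, h$s_end)
    expect_identical(loci$start, as.integer(om$start))
    expect_identical(loci$end, as.integer(om$end))
  }
})

test_that("hits beyond the contig end are rejected by name", {
  h <- make_hits(100, 400, contig = "ctgA")
  expect_error(merge_hits_to_loci(h, contig_lengths = c(ctgA = 300)), "ctgA")
  expect_silent(merge_hits_to_loci(h, contig_lengths = c(ctgA = 400)))
})

test_that("locus classification recovers each structural class", {
  cons <- build_consensus(3)
  t <- as.character(cons$tdr_seq); i <- as.character(cons$inner_seq)
  el <- paste0(t, i, t)

  can <- classify_locus(el, cons)
  expect_identical(can$classification, "canonical")
  expect_identical(c(can$n_tdr, can$n_inner), c(2L, 1L))

  solo <- classify_locus(t, cons)
  expect_identical(solo$classification, "solo_TDR")
  expect_identical(c(solo$n_tdr, solo$n_inner), c(1L, 0L))

  frag <- classify_locus(substr(el, 150, 275), cons)  # 126 bp sub-unit piece
  expect_identical(frag$classification, "fragment")

  arr <- classify_locus(paste0(t, strrep(paste0(i, t), 2)), cons)
  expect_identical(arr$classification, "tandem_array")
  expect_identical(c(arr$n_tdr, arr$n_inner), c(3L, 2L))
  ## divergence-0 length identity: |locus| = x*t + (x-1)*i
  expect_identical(nchar(paste0(t, strrep(paste0(i, t), 2))),
                   3L * nchar(t) + 2L * nchar(i))

  ## a TDR interrupted by a foreign insert is rearranged, whether the
  ## rest of the element follows or not
  set.seed(62)
  ins <- rand_dna(300)
  dtc7 <- paste0(substr(t, 1, 100), ins, substr(t, 101, nchar(t)))
  expect_identical(classify_locus(dtc7, cons)$classification, "rearranged")
  full <- paste0(substr(t, 1, 70), ins, substr(t, 71, nchar(t)), i, t)
  expect_identical(classify_locus(full, cons)$classification, "rearranged")
})

test_that("tandem decomposition reports x from the layout up to x = 58", {
  cons <- build_consensus(23)
  t <- as.character(cons$tdr_seq); i <- as.character(cons$inner_seq)
  big <- classify_locus(paste0(t, strrep(paste0(i, t), 57)), cons)
  expect_identical(big$classification, "tandem_array")
  expect_identical(big$n_tdr, 58L)
  expect_identical(big$n_inner, 57L)
})

test_that("the tandem identity n_inner = n_tdr - 1 holds for classified arrays", {
  cons <- build_consensus(29)
  t <- as.character(cons$tdr_seq); i <- as.character(cons$inner_seq)
  for (x in c(3L, 5L, 9L)) {
    arr <- paste0(t, strrep(paste0(i, t), x - 1L))
    cl <- classify_locus(mutate_sequence(arr, 0.05, 0.002, seed = x), cons)
    expect_identical(cl$classification, "tandem_array")
    expect_identical(cl$n_tdr, x)
    expect_identical(cl$n_inner, x - 1L)
  }
})

test_that("element validation enforces the printed structural ranges", {
  cons <- build_consensus(3)
  ok <- validate_element(list(TDR = as.character(cons$tdr_seq),
                              I = as.character(cons$inner_seq),
                              TDR_2 = as.character(cons$tdr_seq)), cons)
  expect_true(ok$pass)

  long_inner <- paste0(rand_dna(113), "GGGGAGA")   # 120 bp inner
  bad <- validate_element(list(I = long_inner), cons)
  expect_false(bad$pass)
  expect_match(bad$reasons, "inner-domain length 120", all = FALSE)

  ## TDR length boundary: 218 passes, 219 fails
  set.seed(63)
  expect_true(validate_element(list(TDR = rand_dna(218)), cons)$pass)
  r219 <- validate_element(list(TDR = rand_dna(219)), cons)
  expect_false(r219$pass)
  expect_match(r219$reasons, "TDR length 219", all = FALSE)

  ## missing PPT is reported
  noppt <- validate_element(list(I = paste0(rand_dna(70), "GGGGAGC")), cons)
  expect_false(noppt$pass)
  expect_match(noppt$reasons, "purine run", all = FALSE)
})

test_that("genome statistics follow the lower-median and fraction conventions", {
  empty <- genome_stats(merge_hits_to_loci(make_hits(integer(0), integer(0))),
                        1e6)
  expect_identical(empty$n_loci, 0L)
  expect_identical(empty$fraction, 0)

  one <- merge_hits_to_loci(make_hits(1000, 3600))
  st <- genome_stats(one, 1e6)
  expect_equal(st$fraction, 0.0026)

  four <- merge_hits_to_loci(make_hits(c(0, 500, 1000, 2000),
                                       c(100, 626, 1150, 2300)))
  st4 <- genome_stats(four, 1e6)
  expect_identical(st4$locus_length_median, 126L)  # lower median of 4
  expect_identical(sum(st4$class_counts), st4$n_loci)
  expect_error(genome_stats(four, 0), "positive")
})

test_that("loci export as valid GFF3 and BED with classification attributes", {
  loci <- merge_hits_to_loci(rbind(make_hits(100, 300), make_hits(600, 700)))
  loci$classification <- c("canonical", "solo_TDR")
  loci$n_tdr <- c(2L, 1L); loci$n_inner <- c(1L, 0L)
  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_loci_gff3(loci, gff)
  write_loci_bed(loci, bed)
  gl <- readLines(gff)
  expect_match(gl[1], "gff-version 3")
  body <- grep("^[^#]", gl, value = TRUE)
  expect_length(body, 2L)
  expect_match(body[1], "\t101\t300\t")          # 1-based closed
  expect_match(body[1], "classification=canonical")
  bl <- read.table(bed, sep = "\t")
  expect_identical(bl$V2, c(100L, 600L))          # 0-based half-open
})
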