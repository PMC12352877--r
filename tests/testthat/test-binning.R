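# Window geometry and signal binning around the TSS.

test_that("bin_spec enforces exact division and positivity", {
  spec <- bin_spec()
  expect_equal(spec$n_bins, 50L)
  expect_equal(bin_spec(1000, 50)$n_bins, 40L)
  expect_error(bin_spec(2500, 300), "divide")
  expect_error(bin_spec(-10, 100), "positive")
})

test_that("windows span tss +- half_width and the TSS falls in bin 25", {
  g <- data.frame(gene_id = "g", chrom = "chr1", tss = 10000, strand = "+")
  w <- make_window(g)
  expect_equal(w$start, 7500)
  expect_equal(w$end, 12500)
  expect_false(w$clipped)
  # an event exactly at the TSS of a "+" gene lands in 0-based bin 25
  tr <- track_from_events("H3K27Ac", data.frame(chrom = "chr1", pos = 10000))
  v <- bin_counts(tr, w)
  expect_equal(which(v == 1) - 1, 25)
})

test_that("event binning matches an independent per-base histogram", {
  set.seed(41)
  g <- data.frame(gene_id = "g", chrom = "chr7", tss = 100000, strand = "+")
  w <- make_window(g)
  pos <- sort(sample(seq(w$start, w$end - 1), 1000, replace = TRUE))
  tr <- track_from_events("ATAC", data.frame(chrom = "chr7", pos = pos))
  v <- bin_counts(tr, w)
  # oracle: per-base tally aggregated in 100-base groups
  perbase <- tabulate(pos - w$start + 1, nbins = 5000)
  oracle <- colSums(matrix(perbase, nrow = 100))
  expect_identical(as.numeric(v), as.numeric(oracle))
  expect_equal(sum(v), 1000)  # conservation
})

test_that("minus-strand bins are the exact reversal of plus-strand bins", {
  set.seed(42)
  pos <- sample(seq(7500, 12499), 300, replace = TRUE)
  tr <- track_from_events("RNAPII", data.frame(chrom = "chr1", pos = pos))
  gp <- data.frame(gene_id = "gp", chrom = "chr1", tss = 10000, strand = "+")
  gm <- data.frame(gene_id = "gm", chrom = "chr1", tss = 10000, strand = "-")
  vp <- bin_counts(tr, make_window(gp))
  vm <- bin_counts(tr, make_window(gm))
  expect_identical(vm, rev(vp))
  # disabling orientation restores genome order
  vm_genome <- bin_counts(tr, make_window(gm), oriented = FALSE)
  expect_identical(vm_genome, vp)
})

test_that("empty tracks give zeros; missing chromosomes error", {
  g <- data.frame(gene_id = "g", chrom = "chr1", tss = 10000, strand = "+")
  w <- make_window(g)
  empty <- track_from_events("CTCF", data.frame(chrom = character(0),
                                                pos = numeric(0)))
  expect_identical(bin_counts(empty, w), numeric(50))
  other <- track_from_events("CTCF", data.frame(chrom = "chr9", pos = 5))
  expect_error(bin_counts(other, w), "chr1")
})

test_that("windows clipped at the chromosome start zero-fill silently", {
  g <- data.frame(gene_id = "g", chrom = "chr1", tss = 1000, strand = "+")
  w <- make_window(g)
  expect_true(w$clipped)
  tr <- track_from_events("H3K27Ac",
                          data.frame(chrom = "chr1", pos = c(0, 500, 999)))
  v <- bin_counts(tr, w)
  expect_equal(sum(v), 3)  # all in-window events counted, nothing dropped
  expect_equal(length(v), 50)
})

test_that("base-coverage binning sums per-base values over each bin", {
  gr <- GenomicRanges::GRanges("chr3",
                               IRanges::IRanges(c(7501, 7601), width = 100),
                               score = c(2, 0.5))
  tr <- track_from_coverage(gr, "H3K27Ac")
  g <- data.frame(gene_id = "g", chrom = "chr3", tss = 10000, strand = "+")
  v <- bin_counts(tr, make_window(g))
  expect_equal(v[1], 200)   # 100 bases at coverage 2
  expect_equal(v[2], 50)
  expect_equal(sum(v), 250)
  expect_error(track_from_coverage(
    GenomicRanges::GRanges("chr3", IRanges::IRanges(1, 10), score = -1),
    "H3K27Ac"), "negative")
})

test_that("BAM alignments are counted by their 5'-most coordinate", {
  sam <- c("@HD\tVN:1.6\tSO:coordinate",
           "@SQ\tSN:chr1\tLN:50000",
           # + read starting at 1-based 7501 (0-based 7500) -> bin 0
           "r1\t0\tchr1\t7501\t60\t10M\t*\t0\t0\tACGTACGTAC\t*",
           # - read spanning 1-based 9991..10000; 5' end 0-based 9999 -> bin 24
           "r2\t16\tchr1\t9991\t60\t10M\t*\t0\t0\tACGTACGTAC\t*")
  samfile <- tempfile(fileext = ".sam")
  writeLines(sam, samfile)
  bamfile <- Rsamtools::asBam(samfile, tempfile(), overwrite = TRUE,
                              indexDestination = TRUE)
  tr <- track_from_bam(bamfile, "RNAPII")
  g <- data.frame(gene_id = "g", chrom = "chr1", tss = 10000, strand = "+")
  v <- bin_counts(tr, make_window(g))
  expect_equal(which(v > 0) - 1, c(0, 24))
  expect_equal(sum(v), 2)
})
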