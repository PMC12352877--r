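# Labels, standardization, flattening, splits, subset partitions.

test_that("expression labels follow the TPM -> log2(x+1) pipeline", {
  expect_identical(as.numeric(expression_labels(c(0, 0, 0))), c(0, 0, 0))
  expect_true(attr(expression_labels(c(0, 0)), "degenerate"))
  # a single expressed gene owns the whole library: TPM = 1e6
  expect_equal(expression_labels(42), 19.9315700120184936, tolerance = 1e-12)
  # counts [3, 1]: TPM (750000, 250000); frozen arbitrary-precision values
  expect_equal(expression_labels(c(3, 1)),
               c(19.5165329936374357, 17.9315743400927961),
               tolerance = 1e-12)
  expect_error(expression_labels(c(-1, 2)), "non-negative")
})

test_that("TPM mass sums to 1e6 whenever any count is positive", {
  set.seed(9)
  for (i in 1:20) {
    counts <- rpois(200, rexp(200, 1 / 50))
    if (sum(counts) == 0) next
    lab <- expression_labels(counts)
    tpm <- 2^lab - 1
    expect_equal(sum(tpm), 1e6, tolerance = 1e-6)
  }
})

test_that("standardization yields pooled mean 0, population sd 1 per feature", {
  co <- small_cohort(n_genes = 300)
  std <- standardize(co$patient_1)
  for (f in seq_along(std$feature_names)) {
    v <- std$tensor[, , f]
    expect_lt(abs(mean(v)), 1e-8)
    expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-6)
    expect_false(std$records$degenerate[f])
  }
  # {0, 2} in equal proportion -> mean 1, population sd 1, outputs -1/+1
  tens <- array(rep(c(0, 2), each = 1), c(2, 1, 1))
  ds <- patient_dataset("p", c("a", "b"), tens, c(0, 0),
                        feature_names = "X", spec = bin_spec(50, 100))
  s <- standardize(ds)
  expect_identical(as.numeric(s$tensor), c(-1, 1))
})

test_that("degenerate features standardize to zero and are flagged", {
  tens <- array(5, c(3, 2, 1))
  ds <- patient_dataset("p", letters[1:3], tens, c(0, 0, 0),
                        feature_names = "X", spec = bin_spec(100, 100))
  s <- standardize(ds)
  expect_true(all(s$tensor == 0))
  expect_true(s$records$degenerate[1])
  expect_error(standardize(ds, integer(0)), "empty")
})

test_that("flatten is a bijection with contiguous feature blocks", {
  co <- small_cohort(n_genes = 40)
  std <- standardize(co$patient_1)
  mat <- flatten(std)
  cm <- attr(mat, "column_map")
  expect_equal(ncol(mat), 200)
  expect_equal(sort(cm$column), 1:200)  # covers every column exactly once
  # each feature block is contiguous
  for (f in unique(cm$feature))
    expect_equal(diff(range(cm$column[cm$feature == f])), 49)
  # entry at column_map(f, b) equals tensor[g, b, f]
  expect_equal(mat[7, cm$column[cm$feature == "ATAC" & cm$bin == 13]],
               unname(std$tensor[7, 14, 3]))
  expect_identical(unname(unflatten(mat)), unname(std$tensor))
})

test_that("train/val splits are disjoint, exhaustive and scheme-aware", {
  co <- small_cohort(n_genes = 500)
  ds <- co$patient_1
  sp <- split_train_val(ds, 0.7, "random_genes", seed = 1)
  expect_length(intersect(sp$train, sp$val), 0)
  expect_setequal(c(sp$train, sp$val), seq_along(ds$gene_ids))
  expect_length(split_train_val(ds, 1.0, "random_genes")$val, 0)
  cc <- split_train_val(ds, 0.7, "cross_chromosomal", seed = 2)
  shared <- intersect(unique(ds$gene_chrom[cc$train]),
                      unique(ds$gene_chrom[cc$val]))
  expect_length(shared, 0)  # no chromosome spans both sets
  expect_gte(length(cc$train), 0.7 * 500)
  expect_error(split_train_val(ds, 1.3), "train_fraction")
})

test_that("subset partition reproduces the ceiling rule and printed sizes", {
  p1 <- partition_subsets(20015, 10)
  expect_equal(p1$sizes, c(rep(2002, 9), 1997))
  p2 <- partition_subsets(18524, 10)
  expect_equal(p2$sizes, c(rep(1853, 9), 1847))
  p3 <- partition_subsets(10, 10)
  expect_equal(p3$sizes, rep(1, 10))
  # disjoint and exhaustive
  all_idx <- unlist(p1$indices)
  expect_equal(sort(all_idx), 1:20015)
  expect_equal(length(all_idx), length(unique(all_idx)))
  expect_error(partition_subsets(5, 10), "k must satisfy")
})

test_that("dataset container round-trips through the text format", {
  co <- small_cohort(n_genes = 25)
  dir <- tempfile()
  write_patient_dataset(co$patient_1, dir)
  back <- read_patient_dataset(dir)
  expect_equal(back$patient_id, co$patient_1$patient_id)
  expect_equal(unname(back$tensor), unname(co$patient_1$tensor))
  expect_equal(back$labels, co$patient_1$labels, tolerance = 1e-12)
  expect_equal(back$gene_chrom, co$patient_1$gene_chrom)
})
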