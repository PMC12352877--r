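# Metrics, cross-patient runs, subset evaluation, category errors.

test_that("metrics agree with closed forms and a textbook oracle", {
  r <- regression_metrics(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(c(r$pcc, r$scc, r$mse), c(1, 1, 0))
  # one adjacent transposition: rho = 1 - 6*2/(4*15) = 0.8; PCC also 0.8
  r2 <- regression_metrics(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(r2$pcc, 0.8, tolerance = 1e-12)
  expect_equal(r2$scc, 0.8, tolerance = 1e-12)
  # brute-force product-moment oracle on random data
  set.seed(23)
  y <- rnorm(200); yh <- y + rnorm(200)
  r3 <- regression_metrics(y, yh)
  pcc_oracle <- sum((y - mean(y)) * (yh - mean(yh))) /
    sqrt(sum((y - mean(y))^2) * sum((yh - mean(yh))^2))
  expect_equal(r3$pcc, pcc_oracle, tolerance = 1e-12)
  expect_equal(r3$scc, cor(rank(y), rank(yh)), tolerance = 1e-12)
  expect_equal(r3$mse, sum((y - yh)^2) / 200, tolerance = 1e-12)
})

test_that("constant inputs flag undefined correlations but keep MSE", {
  r <- regression_metrics(rep(2, 5), c(1, 2, 3, 2, 2))
  expect_true(r$undefined)
  expect_true(is.na(r$pcc))
  expect_equal(r$mse, mean((rep(2, 5) - c(1, 2, 3, 2, 2))^2))
  expect_error(regression_metrics(1:3, 1:4), "length mismatch")
})

test_that("expression categories follow the high/low thresholds", {
  ce <- category_error(c(10, 5, 7.3, 0, 12, 3), rep(0, 6))
  counts <- setNames(ce$n, ce$stratum)
  expect_equal(unname(counts["high"]), 2)   # 10 and 12
  expect_equal(unname(counts["low"]), 2)    # 5 and 3
  expect_equal(unname(counts["other"]), 2)  # 7.3 and 0
  expect_equal(sum(ce$n), 6)
  perfect <- category_error(c(11, 3, 7), c(11, 3, 7))
  expect_true(all(perfect$mse == 0))
})

test_that("stratum MSEs recombine to the overall MSE", {
  set.seed(31)
  y <- c(runif(40, 0, 5), runif(10, 10, 14), runif(20, 6, 9))
  yh <- y + rnorm(70)
  ce <- category_error(y, yh)
  overall <- sum(ce$n * ce$mse, na.rm = TRUE) / sum(ce$n)
  expect_equal(overall, mean((y - yh)^2), tolerance = 1e-12)
})

test_that("raw-count correlations identify coupled and noise features", {
  co <- small_cohort(n_genes = 600)
  cors <- correlate_features_with_expression(co$patient_1)
  expect_named(cors, c("H3K27Ac", "RNAPII", "ATAC", "CTCF"))
  expect_true(all(cors > 0))
  # a feature whose per-gene sum equals the label correlates perfectly
  n <- 50
  tens <- array(0, c(n, 1, 1)); tens[, 1, 1] <- seq_len(n)
  ds <- patient_dataset("p", sprintf("g%02d", 1:n), tens, seq_len(n),
                        feature_names = "X", spec = bin_spec(50, 100))
  expect_equal(unname(correlate_features_with_expression(ds)), 1.0)
  # pure independent noise decorrelates at large n
  set.seed(12)
  n <- 5000
  tens <- array(rpois(n, 5), c(n, 1, 1))
  ds <- patient_dataset("p", sprintf("g%04d", 1:n), tens,
                        abs(rnorm(n, 5)), feature_names = "X",
                        spec = bin_spec(50, 100))
  expect_lt(abs(correlate_features_with_expression(ds)), 0.05)
})

test_that("cross-patient run is self-consistent when test = train", {
  co <- small_cohort(n_genes = 400)
  res <- run_cross_patient(co$patient_1, co$patient_1, fast_tree_spec(),
                           n_seeds = 1)
  fit <- attr(res, "models")[[1]]
  Xtr <- flatten(standardize(co$patient_1))
  expect_equal(res$patient_1$mean[["pcc"]],
               cor(co$patient_1$labels, predict(fit, Xtr)),
               tolerance = 1e-12)
  # bin-spec mismatch is rejected
  other <- co$patient_2; other$spec <- bin_spec(1000, 100)
  expect_error(run_cross_patient(co$patient_1, other, fast_tree_spec(),
                                 n_seeds = 1), "bin spec mismatch")
})

test_that("features absent from a test patient are exactly zero after layout", {
  co <- small_cohort(n_genes = 200)
  only_h3k <- co$patient_2
  only_h3k$tensor <- only_h3k$tensor[, , 1, drop = FALSE]
  only_h3k$feature_names <- "H3K27Ac"
  X <- chromexpr:::design_for_features(
    only_h3k, c("H3K27Ac", "RNAPII", "ATAC", "CTCF"))
  cm <- attr(X, "column_map")
  absent <- cm$column[cm$feature != "H3K27Ac"]
  expect_equal(ncol(X), 200)
  expect_true(all(X[, absent] == 0))
  expect_false(all(X[, cm$column[cm$feature == "H3K27Ac"]] == 0))
})

test_that("multi-seed summaries are exactly recomputable from per-seed values", {
  co <- small_cohort(n_genes = 300)
  res <- run_cross_patient(co$patient_1, co$patient_2, fast_tree_spec(),
                           n_seeds = 3)
  s <- res$patient_2
  expect_identical(unname(s$mean["pcc"]), mean(s$per_seed$pcc))
  expect_identical(unname(s$sd["mse"]), sd(s$per_seed$mse))
  expect_equal(s$per_seed$seed, 0:2)
})

test_that("subset evaluation covers every gene once and matches k = 1", {
  co <- small_cohort(n_genes = 400)
  res <- run_cross_patient(co$patient_1, co$patient_2, fast_tree_spec(),
                           n_seeds = 1)
  fit <- attr(res, "models")[[1]]
  whole <- evaluate_subsets(fit, co$patient_2, partition_subsets(400, 1))
  expect_equal(whole$per_part$pcc, res$patient_2$mean[["pcc"]],
               tolerance = 1e-12)
  parts <- partition_subsets(400, 7)
  sub <- evaluate_subsets(fit, co$patient_2, parts)
  expect_equal(sum(sub$per_part$n), 400)
  expect_equal(sort(unlist(parts$indices)), 1:400)
  expect_error(evaluate_subsets(fit, co$patient_2, partition_subsets(300, 3)),
               "partition built for")
})
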