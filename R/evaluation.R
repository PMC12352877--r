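# Metrics, multi-seed cross-patient experiments, subset evaluation and
# per-expression-category error analysis.

#' Regression metrics: Pearson, Spearman, MSE
#'
#' Spearman is the Pearson correlation of average-ranked values (average
#' ranks for ties). When either vector is constant the correlations are
#' undefined and reported as `NA` with `undefined = TRUE`; the MSE is still
#' computed.
#'
#' @param y True labels.
#' @param yhat Predictions, same length.
#' @param keep_predictions Store `yhat` in the result (default `FALSE`).
#' @return Object of class `eval_result`: list with `pcc`, `scc`, `mse`,
#'   `n`, `undefined` and optionally `predictions`.
#' @export
regression_metrics <- function(y, yhat, keep_predictions = FALSE) {
  if (length(y) != length(yhat))
    stop("length mismatch: y has ", length(y), ", yhat has ", length(yhat))
  if (length(y) == 0) stop("empty input")
  constant <- stats::sd(y) == 0 || stats::sd(yhat) == 0
  out <- list(
    pcc = if (constant) NA_real_ else stats::cor(y, yhat),
    scc = if (constant) NA_real_
          else stats::cor(rank(y), rank(yhat)),  # average ranks for ties
    mse = mean((y - yhat)^2),
    n = length(y),
    undefined = constant)
  if (keep_predictions) out$predictions <- yhat
  structure(out, class = "eval_result")
}

summarize_seed_metrics <- function(per_seed) {
  met <- c("pcc", "scc", "mse")
  df <- as.data.frame(lapply(met, function(m)
    vapply(per_seed, function(r) r[[m]], numeric(1))))
  names(df) <- met
  df$seed <- vapply(per_seed, function(r) r$seed, numeric(1))
  structure(
    list(per_seed = df[, c("seed", met)],
         mean = vapply(df[met], mean, numeric(1)),
         sd = vapply(df[met], stats::sd, numeric(1)),
         seeds = df$seed),
    class = "multi_seed_summary")
}

#' @export
print.multi_seed_summary <- function(x, ...) {
  cat("<multi_seed_summary> ", nrow(x$per_seed), " seeds\n", sep = "")
  cat(sprintf("  PCC %.4f +- %.4f | SCC %.4f +- %.4f | MSE %.4f +- %.4f\n",
              x$mean["pcc"], x$sd["pcc"], x$mean["scc"], x$sd["scc"],
              x$mean["mse"], x$sd["mse"]))
  invisible(x)
}

# Standardize a test patient with its own statistics and lay its features
# out over the training feature set; features the patient lacks become
# all-zero blocks (zero = the standardization mean).
design_for_features <- function(dataset, feature_names, genes = NULL) {
  std <- standardize(dataset, genes)
  nb <- dataset$spec$n_bins
  cm <- column_map(feature_names, nb)
  mat <- matrix(0, length(std$gene_ids), nrow(cm),
                dimnames = list(std$gene_ids, cm$name))
  for (f in intersect(feature_names, dataset$feature_names)) {
    fi <- match(f, dataset$feature_names)
    mat[, cm$column[cm$feature == f]] <- std$tensor[, , fi]
  }
  structure(mat, column_map = cm,
            class = c("flat_design_matrix", "matrix", "array"))
}

restrict_features <- function(mat, features) {
  cm <- attr(mat, "column_map")
  unknown <- setdiff(features, unique(cm$feature))
  if (length(unknown) > 0)
    stop("unknown feature(s) in subset: ", paste(unknown, collapse = ", "))
  keep <- cm$column[cm$feature %in% features]
  out <- mat[, keep, drop = FALSE]
  cm2 <- cm[cm$feature %in% features, , drop = FALSE]
  cm2$column <- seq_len(nrow(cm2))
  structure(out, column_map = cm2,
            class = c("flat_design_matrix", "matrix", "array"))
}

#' Multi-seed cross-patient experiment
#'
#' For each seed: standardize the training patient with its own statistics,
#' fit the model on 100% of its genes, then for every test patient
#' standardize with that patient's own statistics, zero-fill any feature the
#' patient lacks (0.0 being the post-standardization mean), predict and
#' score. With `feature_subset` both training and test matrices are
#' restricted to those feature blocks before fitting — the
#' "single-mark retraining" design.
#'
#' @param train Training [patient_dataset()].
#' @param tests List of test `patient_dataset`s (a single dataset is
#'   accepted).
#' @param spec A [regressor_spec()]; its seed field is replaced by each run
#'   seed.
#' @param n_seeds Number of repeated runs (default 10).
#' @param feature_subset Optional character vector of features to train on.
#' @param seeds Explicit seed vector overriding `0:(n_seeds-1)`.
#' @return Named list (one per test patient) of `multi_seed_summary`.
#' @export
run_cross_patient <- function(train, tests, spec, n_seeds = 10,
                              feature_subset = NULL, seeds = NULL) {
  if (inherits(tests, "patient_dataset")) tests <- list(tests)
  if (is.null(seeds)) seeds <- seq_len(n_seeds) - 1L
  for (te in tests) {
    if (!identical(unclass(te$spec), unclass(train$spec)))
      stop("bin spec mismatch between train and test dataset '",
           te$patient_id, "'")
  }
  feats <- train$feature_names
  Xtr <- flatten(standardize(train))
  Xte <- lapply(tests, design_for_features, feature_names = feats)
  if (!is.null(feature_subset)) {
    Xtr <- restrict_features(Xtr, feature_subset)
    Xte <- lapply(Xte, restrict_features, features = feature_subset)
  }
  results <- lapply(tests, function(.) list())
  names(results) <- vapply(tests, function(t) t$patient_id, character(1))
  models <- list()
  for (s in seq_along(seeds)) {
    spec_s <- regressor_spec(spec$family, spec$hyperparameters,
                             seed = seeds[s])
    fit <- fit_regressor(spec_s, Xtr, train$labels)
    models[[s]] <- fit
    for (t in seq_along(tests)) {
      r <- regression_metrics(tests[[t]]$labels,
                              stats::predict(fit, Xte[[t]]))
      r$seed <- seeds[s]
      results[[t]][[s]] <- r
    }
  }
  out <- lapply(results, summarize_seed_metrics)
  attr(out, "models") <- models
  attr(out, "feature_subset") <- feature_subset
  out
}

#' Evaluate a trained model on non-overlapping subsets of a test patient
#'
#' The partition's contiguous index ranges cover every gene exactly once;
#' metrics are reported per part together with their across-part mean/sd.
#'
#' @param model A `trained_regressor`.
#' @param test Test [patient_dataset()].
#' @param partition A [partition_subsets()] built for `test`'s gene count.
#' @param feature_names Feature layout the model was trained on (defaults to
#'   the test patient's features).
#' @return List with `per_part` (data frame: part, n, pcc, scc, mse) and
#'   `mean`/`sd` over parts.
#' @export
evaluate_subsets <- function(model, test, partition,
                             feature_names = test$feature_names) {
  stopifnot(inherits(partition, "subset_partition"))
  if (sum(partition$sizes) != length(test$gene_ids))
    stop("partition built for ", sum(partition$sizes),
         " genes but test dataset has ", length(test$gene_ids))
  X <- design_for_features(test, feature_names)
  yhat <- stats::predict(model, X)
  rows <- lapply(seq_len(partition$k), function(p) {
    idx <- partition$indices[[p]]
    r <- regression_metrics(test$labels[idx], yhat[idx])
    data.frame(part = p, n = r$n, pcc = r$pcc, scc = r$scc, mse = r$mse)
  })
  per_part <- do.call(rbind, rows)
  list(per_part = per_part,
       mean = colMeans(per_part[c("pcc", "scc", "mse")]),
       sd = vapply(per_part[c("pcc", "scc", "mse")], stats::sd, numeric(1)))
}

#' Correlate raw per-gene feature totals with expression
#'
#' The classical first-pass analysis: for each feature, the Pearson
#' correlation between the per-gene summed raw window counts and the
#' log2(TPM+1) label.
#'
#' @param dataset A [patient_dataset()].
#' @return Named numeric vector, one correlation per feature (`NA` for a
#'   constant feature).
#' @export
correlate_features_with_expression <- function(dataset) {
  vapply(seq_along(dataset$feature_names), function(f) {
    tot <- rowSums(dataset$tensor[, , f, drop = FALSE])
    if (stats::sd(tot) == 0 || stats::sd(dataset$labels) == 0)
      return(NA_real_)
    stats::cor(tot, dataset$labels)
  }, numeric(1)) |> stats::setNames(dataset$feature_names)
}

#' Per-expression-category prediction error
#'
#' Genes are stratified by their true label: high (>= 10), low (0 < label
#' <= 5) and other (0, or strictly between 5 and 10); MSE and counts are
#' reported per stratum.
#'
#' @param y True labels.
#' @param yhat Predictions.
#' @return Data frame with columns `stratum`, `n`, `mse`.
#' @export
category_error <- function(y, yhat) {
  if (length(y) != length(yhat)) stop("length mismatch")
  stratum <- ifelse(y >= 10, "high", ifelse(y > 0 & y <= 5, "low", "other"))
  out <- do.call(rbind, lapply(c("high", "low", "other"), function(s) {
    idx <- stratum == s
    data.frame(stratum = s, n = sum(idx),
               mse = if (any(idx)) mean((y[idx] - yhat[idx])^2) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}
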