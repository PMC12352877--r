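# Feature attribution: split-gain importance aggregation and zero-fill
# in-silico ablation.

#' Aggregate split-gain importance per column and per feature
#'
#' For tree-ensemble families, per-column importance is the total split gain
#' attributed to that column, normalized so all columns sum to 1 (maximum
#' possible per-feature share 1.0). Per-feature sums are block sums over
#' each feature's contiguous columns. Non-tree families do not expose split
#' gain and are rejected.
#'
#' @param model A `trained_regressor` of a tree-ensemble family.
#' @param cmap Column map (defaults to the one captured at fit time).
#' @return Object of class `importance_profile`: list with `per_column`
#'   (data frame: column, feature, bin, importance), `feature_sums` (named
#'   numeric), and `normalization` note.
#' @export
aggregate_importance <- function(model, cmap = NULL) {
  stopifnot(inherits(model, "trained_regressor"))
  if (is.null(cmap)) cmap <- model$column_map
  if (is.null(cmap)) stop("no column map available")
  fam <- model$spec$family
  raw <- switch(fam,
    gradient_boosted_trees = xgb_column_gain(model, nrow(cmap)),
    classic_gradient_boosting = rpart_column_gain(model, nrow(cmap)),
    stop("split-gain importance unsupported for family '", fam, "'"))
  total <- sum(raw)
  imp <- if (total > 0) raw / total else raw
  per_column <- data.frame(column = cmap$column, feature = cmap$feature,
                           bin = cmap$bin, importance = imp,
                           stringsAsFactors = FALSE)
  sums <- vapply(split(imp, cmap$feature), sum, numeric(1))
  feats <- unique(cmap$feature)
  structure(
    list(per_column = per_column, feature_sums = sums[feats],
         normalization = "total split gain, normalized to sum 1 over columns"),
    class = "importance_profile")
}

xgb_column_gain <- function(model, n_cols) {
  imp <- xgboost::xgb.importance(model = model$model)
  raw <- numeric(n_cols)
  # xgboost names unnamed columns f0..f{p-1}
  idx <- if (all(grepl("^f[0-9]+$", imp$Feature)))
    as.integer(sub("^f", "", imp$Feature)) + 1L
  else match(imp$Feature, model$fingerprint$col_names)
  raw[idx] <- imp$Gain
  raw
}

rpart_column_gain <- function(model, n_cols) {
  raw <- numeric(n_cols)
  for (tr in model$model$trees) {
    sp <- tr$splits
    if (is.null(sp) || nrow(sp) == 0) next
    gain <- sp[, "improve"]
    vars <- as.integer(sub("^V", "", rownames(sp)))
    for (i in seq_along(vars)) raw[vars[i]] <- raw[vars[i]] + gain[i]
  }
  raw
}

#' Zero-fill one feature block of a standardized design matrix
#'
#' Replaces every value of the feature's columns with exactly 0.0 — the
#' post-standardization mean — leaving all other entries untouched. The
#' operation is idempotent.
#'
#' @param X A `flat_design_matrix` (standardized).
#' @param feature Feature name to ablate.
#' @return The perturbed matrix (same shape, same column map).
#' @export
perturb_feature <- function(X, feature) {
  cm <- attr(X, "column_map")
  if (is.null(cm)) stop("X carries no column map")
  if (!feature %in% cm$feature)
    stop("unknown feature '", feature, "'")
  X[, cm$column[cm$feature == feature]] <- 0
  X
}

#' Zero-fill perturbation experiment
#'
#' For each run seed a model is fitted on the training patient and evaluated
#' on the test patient both intact and with one feature block zero-filled at
#' a time; the PCC drop (baseline − perturbed) quantifies that feature's
#' contribution at test time.
#'
#' @param train Training [patient_dataset()].
#' @param test Test [patient_dataset()].
#' @param spec A [regressor_spec()].
#' @param n_seeds Number of repeated runs (default 10).
#' @param seeds Explicit seeds overriding `0:(n_seeds-1)`.
#' @return Object of class `perturbation_result`: data frame `summary` (one
#'   row per feature: baseline/perturbed mean and sd PCC, delta) plus
#'   per-seed matrices.
#' @export
perturbation_experiment <- function(train, test, spec, n_seeds = 10,
                                    seeds = NULL) {
  if (is.null(seeds)) seeds <- seq_len(n_seeds) - 1L
  feats <- train$feature_names
  Xtr <- flatten(standardize(train))
  Xte <- design_for_features(test, feats)
  base <- numeric(length(seeds))
  pert <- matrix(NA_real_, length(seeds), length(feats),
                 dimnames = list(NULL, feats))
  for (s in seq_along(seeds)) {
    fit <- fit_regressor(
      regressor_spec(spec$family, spec$hyperparameters, seed = seeds[s]),
      Xtr, train$labels)
    base[s] <- suppressWarnings(
      stats::cor(test$labels, stats::predict(fit, Xte)))
    for (f in feats) {
      yp <- stats::predict(fit, perturb_feature(Xte, f))
      pert[s, f] <- if (stats::sd(yp) == 0) NA_real_
                    else stats::cor(test$labels, yp)
    }
  }
  summary <- data.frame(
    feature = feats,
    baseline_mean = mean(base), baseline_sd = stats::sd(base),
    perturbed_mean = colMeans(pert), perturbed_sd = apply(pert, 2, stats::sd),
    stringsAsFactors = FALSE)
  summary$delta <- summary$baseline_mean - summary$perturbed_mean
  rownames(summary) <- NULL
  structure(list(summary = summary, baseline_per_seed = base,
                 perturbed_per_seed = pert, seeds = seeds),
            class = "perturbation_result")
}
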