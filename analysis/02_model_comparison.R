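#!/usr/bin/env Rscript
# Compare the regression families in a within-patient cross-chromosomal
# 70/30 split (the hyperparameter-selection setting) and then in the
# cross-patient setting, at a reduced problem size (2,000 genes) so every
# family - including SVR and the perceptron - fits in seconds to minutes.

library(chromexpr)

dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(synthetic_config(n_genes = 2000, seed = 1))
train_ds <- cohort$patient_1
test_ds <- cohort$patient_2

split <- split_train_val(train_ds, 0.7, "cross_chromosomal", seed = 0)
cat(sprintf("cross-chromosomal split: %d train / %d validation genes\n",
            length(split$train), length(split$val)))

Xtr <- flatten(standardize(train_ds, split$train))
Xva <- flatten(standardize(train_ds, split$val))
ytr <- train_ds$labels[split$train]
yva <- train_ds$labels[split$val]

families <- c("gradient_boosted_trees", "classic_gradient_boosting",
              "linear_least_squares", "support_vector",
              "multilayer_perceptron")

rows <- lapply(families, function(fam) {
  t0 <- Sys.time()
  fit <- fit_regressor(regressor_spec(fam, seed = 0), Xtr, ytr)
  within <- regression_metrics(yva, predict(fit, Xva))
  xp <- run_cross_patient(train_ds, test_ds, regressor_spec(fam, seed = 0),
                          n_seeds = 1)
  secs <- as.numeric(difftime(Sys.time(), t0, units = "secs"))
  cat(sprintf("%-26s within-patient PCC %.3f | cross-patient PCC %.3f (%.0fs)\n",
              fam, within$pcc, xp$patient_2$mean[["pcc"]], secs))
  data.frame(family = fam, within_patient_pcc = within$pcc,
             within_patient_scc = within$scc,
             cross_patient_pcc = xp$patient_2$mean[["pcc"]],
             cross_patient_scc = xp$patient_2$mean[["scc"]])
})
tab <- do.call(rbind, rows)
write.table(tab, "results/model_comparison.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

best <- tab$family[which.max(tab$cross_patient_pcc)]
gap <- max(tab$cross_patient_pcc) -
  tab$cross_patient_pcc[tab$family == "linear_least_squares"]
cat(sprintf("\nBest cross-patient family: %s; margin over the linear baseline: %.3f PCC.\n",
            best, gap))
cat("The linear gap shows the saturating, non-additive signal-expression\n",
    "link; trees capture it without feature engineering.\n", sep = "")

## small grid refinement for the boosted-tree family on the validation split
gs <- grid_search(regressor_spec("gradient_boosted_trees", seed = 0),
                  list(max_depth = c(4, 6), eta = c(0.05, 0.1)),
                  list(X = Xtr, y = ytr), list(X = Xva, y = yva))
cat("\ngrid search (validation PCC per point):\n")
print(gs$table)
write.table(gs$table, "results/grid_search.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
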