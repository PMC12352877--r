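# chromexpr

Cross-patient prediction of gene expression from binned epigenomic signals
around transcription start sites.

## The problem

Active enhancers and promoters leave quantitative chromatin fingerprints —
H3K27Ac, bound RNA polymerase II, open chromatin (ATAC), CTCF occupancy —
that track how strongly each gene is transcribed. `chromexpr` asks how much
of a gene's expression can be read off those marks alone, and whether a
model fitted on one patient's chromatin transfers to another patient
*without refitting*. It is aimed at computational epigenomics groups
working with patient-derived samples (the motivating setting is
glioblastoma stem cell cultures) where per-patient training data is scarce
and cross-sample generalization is the question of interest.

## The method

For each gene *g*, the ±2.5 kb window around its TSS is divided into 50
bins of 100 bp, and each of the four marks is counted per bin, giving a
50 × 4 matrix per gene. Expression labels are window RNA-seq counts
normalized to transcripts per million and transformed as

    y_g = log2(TPM_g + 1),    TPM_g = 10^6 · (c_g / L) / Σ_h (c_h / L).

Each feature is z-scored with its own pooled mean and population SD
*within* each set (after splitting, so no statistics leak between sets),
the tensor is flattened to a genes × 200 matrix with each feature's 50
bins contiguous, and a gradient-boosted tree ensemble is fitted to
minimize MSE = (1/n) Σ (y_i − ŷ_i)². Transfer means: fit on 100% of
patient A's genes, standardize patient B with B's own statistics, predict,
and score by Pearson correlation (PCC; Spearman as a secondary metric).

Feature contribution is quantified three ways:

- **importance aggregation** — per-column split gain, normalized to sum
  to 1, then summed over each feature's 50-column block;
- **zero-fill ablation** — one feature's standardized block is set to 0.0
  (its mean) at test time and the PCC drop recorded;
- **stratified landscapes** — bin-wise mean standardized H3K27Ac for
  high- (y ≥ 10) vs low- (0 < y ≤ 5) expression genes.

A seeded synthetic cohort generator (shared per-gene latent expression,
two-peak enhancer template flanking the TSS, weaker single-peak
RNAPII/ATAC coupling, mostly expression-independent CTCF, patient-level
scale factors, negative-binomial counts) makes the whole pipeline testable
without sequencing data. See `vignettes/chromatin-expression-workflow.Rmd`
for the full model and its assumptions.

## Worked example

```r
library(chromexpr)
cohort <- generate_cohort(synthetic_config(n_genes = 2000, seed = 42))
res <- run_cross_patient(cohort$patient_1, cohort$patient_2,
                         regressor_spec("gradient_boosted_trees"),
                         n_seeds = 3)
print(res$patient_2)
#> <multi_seed_summary> 3 seeds
#>   PCC 0.8822 +- 0.0000 | SCC 0.8650 +- 0.0000 | MSE 3.0105 +- 0.0000
imp <- aggregate_importance(attr(res, "models")[[1]])
round(imp$feature_sums, 3)
#> H3K27Ac  RNAPII    ATAC    CTCF
#>   0.761   0.139   0.058   0.043
```

A model trained on patient 1 predicts patient 2's expression at PCC 0.88
(the zero seed-to-seed SD reflects the deterministic full-subsample tree
fit), and three quarters of the normalized split gain sits in the H3K27Ac
block — the enhancer mark dominates, with RNAPII/ATAC carrying redundant
signal and CTCF almost none.

The numbered scripts under `analysis/` walk the full study: cohort
simulation and correlation analysis, model-family comparison with a
cross-chromosomal validation split, the ten-seed transfer experiment with
subset and per-category errors, feature attribution, and stratified
landscapes. Each writes its tables under `results/`.

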