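---
title: "Predicting expression from TSS-proximal chromatin: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting expression from TSS-proximal chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromexpr)
```

`chromexpr` regresses per-gene expression on the spatial profile of four
epigenomic marks (H3K27Ac, RNAPII, ATAC, CTCF) in the ±2.5 kb window
around the TSS, and studies how that regression transfers between
patients. This vignette is the package's own account of the method: the
statistical model, every tunable that matters, the design choices that
were genuinely open, and what the synthetic cohort used by the test suite
does and does not establish about real data.

## From reads to a design matrix

**Windows and bins.** A `bin_spec()` fixes the geometry: `half_width`
(bases, default 2500) and `bin_width` (bases, default 100) give
`n_bins = 2·half_width / bin_width` = 50 bins per gene per mark. The
division must be exact; there are no partial bins. Coordinates are 0-based
half-open throughout, matching BAM/BED semantics. For a "+"-strand gene
the TSS is the annotated feature start; for a "−"-strand gene it is
`end − 1`, the last covered base. The annotation format itself never
states this convention, so it is fixed here once and used consistently;
with 50 bins the TSS coordinate is then the left edge of bin 25 for every
gene.

**Orientation.** Bins are reported 5'→3' of the gene: the genomic bin
order is reversed for "−"-strand genes. This is what lets TSS-proximal
structure (the central dip, the flanking peaks) pool at the same bin
indices when profiles are averaged over genes of both strands. Strict
genome-order binning is available via `oriented = FALSE` for callers that
want to overlay external genome-browser tracks.

**Counting modes.** Whether a "count" is a read 5' end or per-base
coverage is an open choice in this kind of pipeline, and the two differ
by a factor of read length on real data. Both are implemented and the
mode is recorded in dataset provenance: alignment files (BAM) count
event starts (each alignment's 5'-most coordinate increments one bin);
coverage tracks (bedGraph/bigWig) sum per-base values over each bin's 100
bases. Event-start mode conserves mass exactly — the bin vector sums to
the number of in-window events — which is what the conservation tests
assert. Windows that run past a chromosome edge are kept and the
out-of-range bases contribute zero, so the gene count always matches the
annotation.

**Labels.** Expression is the window sum of RNA-seq counts, normalized to
transcripts per million and transformed as `log2(TPM + 1)`. Because every
gene uses the same fixed window length L, the length correction cancels:
`TPM_g = 1e6 · c_g / Σ c`. TPM over the fixed window (rather than
genome-wide transcript models) keeps the label and the predictors on the
same genomic support; it is also the only version computable from the
window data alone. An all-zero library yields all-zero labels, flagged
rather than erroring, so degenerate simulations stay analyzable.

**Standardization.** Each feature is z-scored with the pooled mean and
*population* (divide-by-n) SD over all genes × bins of that feature
within one set. Population SD is a bit-reproducibility decision — at
n = genes × 50 the sample/population distinction is numerically
irrelevant, but it must be fixed for the determinism tests to be exact.
Two further points matter:

- Statistics are computed *after* splitting and *per set* — the training
  patient uses its own mean/SD, and so does every test patient. Nothing
  from the training distribution leaks into test preprocessing, and the
  model must survive whatever scale shift remains after each patient is
  normalized to itself. That is the sense in which "cross-patient"
  transfer is tested.
- Mean-centering makes 0.0 the post-standardization mean of every
  feature. Both the zero-fill ablation and the handling of marks a test
  patient never assayed exploit this: writing 0.0 into a feature block is
  imputation at the feature mean, the least-informative value.

A zero-variance feature standardizes to all zeros with a `degenerate`
flag instead of dividing by zero.

**Flattening.** The genes × 50 × 4 tensor becomes a genes × 200 matrix;
each feature's 50 bins stay contiguous, and the column ↔ (feature, bin)
map travels with the matrix (`column_map` attribute, `FEATURE_binNN`
column names). `unflatten()` inverts it exactly; trained models
fingerprint the column layout and refuse mismatched inputs.

## Models

Five families sit behind one `regressor_spec()` / `fit_regressor()` /
`predict()` surface, all minimizing MSE:

| family | backing | key defaults |
|---|---|---|
| gradient_boosted_trees | xgboost | 300 rounds, depth 6, eta 0.05, subsample 1.0 |
| classic_gradient_boosting | stagewise rpart boosting | 100 rounds, depth 3, shrinkage 0.1 |
| linear_least_squares | QR least squares | — |
| support_vector | e1071 ε-SVR | radial kernel, C = 1, ε = 0.1 |
| multilayer_perceptron | nnet, one hidden layer | 32 units, weight decay 1e-4 |

The boosted-tree defaults are the package's own (they live in config and
`grid_search()` can refit them); 300 rounds at eta 0.05 is past the
point where validation PCC plateaus on the reference cohort sizes used
here. With `subsample = 1` and one thread the tree fit is fully
deterministic, so repeated seeds give identical predictions — multi-seed
SDs of exactly zero are expected and honest, and become nonzero as soon
as row subsampling is enabled. The classic-boosting family is a plain
stagewise least-squares booster over rpart trees (fit the residuals, add
a shrunken tree); it exists to separate "boosting as an algorithm" from
xgboost's regularized implementation. The perceptron is deliberately a
single hidden layer — the package's scope ends before convolutional or
recurrent architectures — with optional warm-started early stopping on
validation PCC. A constant training target short-circuits every family
to an exact constant model, since that is each family's MSE minimizer
and several backends fail or approximate needlessly in that degenerate
case.

One integer seed per fit feeds every stochastic component
(`set.seed` + xgboost's own seed). `grid_search()` scores each grid
point by validation PCC and breaks ties by first occurrence in
lexicographic order over name-sorted hyperparameters, so re-runs are
reproducible.

## Transfer, attribution, landscapes

`run_cross_patient()` implements the central design: fit on 100% of the
training patient's genes (once per seed), evaluate on each test patient
standardized with its own statistics. Marks a test patient lacks are
laid out as all-zero blocks; `feature_subset` restricts both sides to
chosen feature blocks before fitting (the single-mark retraining
design). `evaluate_subsets()` scores ten contiguous, non-overlapping
gene parts — sized `ceiling(n/k)` with the remainder in the last part,
deterministic in stored gene order, so every gene is evaluated exactly
once and nothing is silently dropped by random subsetting.

**Importance.** Tree ensembles report per-column split gain, normalized
to sum to 1 over all 200 columns, then block-summed per feature. Gain
(not split frequency or cover) is the conventional attribution for
regression trees; the choice is recorded in the profile's
`normalization` note rather than asserted as the only option.

**Ablation.** `perturb_feature()` zeroes one standardized block — mean
imputation, see above — and `perturbation_experiment()` reports
baseline vs perturbed PCC per seed. The ablation deltas and the gain
shares answer different questions (what the model *uses at test time* vs
where it *found splits during training*) and are computed independently.

**Landscapes.** `landscape_table()` pools bin-wise means of standardized
counts over expression strata. The default strata are high = [10, ∞) and
low = (0, 5] on the log2(TPM+1) scale; exact zeros and the (5, 10) band
fall into "other". Bounds are inclusive exactly as written — a gene at
5.0 is "low", a gene at 0 is not. Profiles use standardized counts so
patients with different sequencing depths are comparable; raw-count
profiles just mean skipping `standardize()`.

## The synthetic cohort

`generate_cohort()` draws multi-patient cohorts with the statistical
structure the analysis assumes, so every pipeline stage is testable
without sequencing data.

Per gene: latent expression `e_g` is 0 with probability 0.15 (silent
genes) and lognormal(meanlog 1.5, sdlog 1.8) otherwise — a heavy-tailed
distribution putting many genes in the low label stratum and few above
label 10, as real RNA-seq does. An independent exponential "site
strength" drives CTCF. Per patient and track, a lognormal scale factor
(log-SD 0.2) models depth/efficiency differences around the *shared*
gene-level landscape; that sharing is the premise that makes transfer
learnable, and it shows up as cross-patient label correlation above 0.9.

Per feature, bin intensities are
`λ = γ_patient · (α_f · e^0.7 · w_f(b) + β_f)` where `w_H3K27Ac` is a
two-Gaussian template (centers at bins 20 and 30, width 3 bins, floor
0.05, max-normalized — equal peaks flanking a strict dip at bin 25) and
RNAPII/ATAC/CTCF share a single narrow TSS-centered peak. Coupling
strengths α = (3.0, 1.2, 0.8, 0.2) order the features; the exponent 0.7
makes the signal–expression link saturating, which is exactly what
separates the tree families from the linear baseline. RNAPII and ATAC
thus carry genuine but *redundant* signal — the mechanism by which a
dominant enhancer mark can absorb most of the split gain while ablating
the others still costs a little accuracy.

Counts are gene-level gamma mixtures of per-bin Poisson draws —
marginally negative binomial, with the overdispersion shared across a
gene's bins the way sequencing enrichment noise is. This matters: purely
bin-level noise averages out over 50 bins and would make the per-gene
sums almost noiseless, driving raw mark–expression correlations far
above anything seen in practice. The per-feature dispersions
(1.3, 0.5, 0.22, 0.5), backgrounds (0.2, 0.15, 0.3, 0.3) and the CTCF
site coefficient (5.0) were calibrated once, against the target
correlation profile ≈ (0.40, 0.35, 0.21, 0.14) with the ordering
H3K27Ac > RNAPII > ATAC > CTCF, and then frozen; they are config fields,
not tuning dials. RNA window counts are negative binomial (size 8) with
mean proportional to patient depth × `e_g` over a 2×10⁵ library mass.

What the generator does *not* emulate: genome sequence, fragment-length
and GC bias, peak-shape heterogeneity across genes, chromatin-state
switching between patients, or any dependence structure between
neighboring genes. Passing tests on this cohort therefore demonstrate
that the pipeline's machinery is correct and that its conclusions hold
*under the stated generative assumptions* — not that real patient data
meets those assumptions. Conversely, genes get chromosome assignments
and evenly spaced synthetic coordinates, and any feature can be emitted
as a bedGraph track, so the annotation/binning layer is exercised by a
full round trip rather than mocked.

## Numerical choices and degenerate inputs

- Correlations of constant vectors are reported `NA` with an
  `undefined` flag, never coerced to 0 — a perturbation run that
  flattens all predictions is detectable, not silently "uncorrelated".
- Ablation is idempotent and bitwise-preserves untouched columns; tests
  assert identity, not tolerance.
- Cross-chromosomal splits assign whole chromosomes greedily, largest
  remaining first with seed-shuffled ties, until the training fraction
  is first reached; no chromosome ever spans both sets.
- The TPM mass identity (Σ TPM = 10⁶) is checked to 10⁻⁶ relative;
  standardization moments to |mean| < 10⁻⁸, SD within 10⁻⁶ of 1;
  landscape recombination (count-weighted stratum means reconstructing
  the pooled profile) to 10⁻¹⁰.

## Problem sizes

The reference cohort for the headline experiments is 2 patients × 5,000
genes; unit tests use 150–800 genes and the workflow scripts 2,000 where
every family (including the ε-SVR and the perceptron, whose cost grows
fastest) is compared. These sizes were chosen so the full suite and the
acceptance script each run in minutes on a single core while keeping the
stochastic contracts (correlation targets, transfer PCC, importance
ordering) stable across seeds.

## Known limitations

- Real ±2.5 kb windows of neighboring genes overlap; the synthetic
  coordinates space genes 10 kb apart, so the round-trip tests never
  exercise shared signal between genes.
- The single-TSS-per-gene reduction ignores alternative promoters; the
  first record per gene id wins, with a warning.
- Standardizing each test patient with its own statistics is a design
  commitment (it matches the per-set phrasing of the protocol this
  package follows); the conventional alternative — freezing training
  statistics — is a one-line change in `standardize()` callers but is
  not the tested default.
- Importance shares from tree ensembles are attribution, not causality;
  the redundancy built into the generator is a live demonstration of how
  a correlated mark can be near-zero in gain yet carry real signal.
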