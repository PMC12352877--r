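# Shared fixtures, generated in code.

# Small cohort for fast unit tests (contracts that do not depend on the
# reference cohort size).
small_cohort <- function(n_genes = 800, seed = 3, n_patients = 2) {
  generate_cohort(synthetic_config(n_genes = n_genes, seed = seed,
                                   n_patients = n_patients))
}

fast_tree_spec <- function(nrounds = 60, seed = 0) {
  regressor_spec("gradient_boosted_trees",
                 list(nrounds = nrounds, max_depth = 4), seed = seed)
}

# Minimal BED6 annotation text
bed6_lines <- function() c(
  "chr1\t1000\t2000\tgeneA\t0\t+",
  "chr1\t1000\t2000\tgeneB\t0\t-",
  "chr2\t50000\t60000\tgeneC\t0\t+")
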