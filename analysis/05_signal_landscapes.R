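#!/usr/bin/env Rscript
# Bin-wise mean H3K27Ac landscapes around the TSS, pooled over expression
# strata (high >= 10, low (0, 5]): the interpretable readout of what the
# transfer model keys on.

library(chromexpr)

dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(synthetic_config())

tabs <- lapply(names(cohort), function(p) {
  std <- standardize(cohort[[p]])
  cbind(dataset = p, landscape_table(std, "H3K27Ac"))
})
tab <- do.call(rbind, tabs)
write.table(tab, "results/landscape_h3k27ac.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

for (p in unique(tab$dataset)) {
  hi <- tab[tab$dataset == p & tab$stratum == "high", ]
  lo <- tab[tab$dataset == p & tab$stratum == "low", ]
  cat(sprintf(
    "%s: high-stratum peaks at bins %d/%d, dip at bin 25 (%.2f vs peak %.2f); low stratum below high at all 50 bins: %s\n",
    p, hi$bin[which.max(hi$mean[1:26])],
    hi$bin[26 + which.max(hi$mean[27:50])],
    hi$mean[hi$bin == 25], max(hi$mean),
    all(hi$mean > lo$mean)))
}
cat("\nHigh-expressing genes carry the two-peak enhancer flank with a\n",
    "nucleosome-depleted dip over the TSS; low-expressing genes are flat.\n",
    sep = "")
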