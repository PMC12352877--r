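Package: chromexpr
Title: Cross-Patient Prediction of Gene Expression from Binned Epigenomic Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-gene matrices of epigenomic signal (H3K27Ac, RNAPII,
    ATAC, CTCF) binned in fixed-width windows around transcription start
    sites, trains regression models mapping those matrices to log2(TPM+1)
    expression, and transfers trained models across patients without
    refitting. Includes split-gain feature-importance aggregation, zero-fill
    in-silico ablation, expression-stratified signal landscapes, and a
    seeded multi-patient synthetic cohort generator so the whole pipeline is
    testable without sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost,
    rpart,
    e1071,
    nnet,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomicAlignments,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
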