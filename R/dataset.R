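# Per-patient dataset assembly: tensors, labels, standardization, flattening,
# splits and subset partitions.

#' Construct a per-patient dataset
#'
#' Bundles the raw genes × bins × features count tensor with its
#' log2(TPM+1) expression labels and provenance metadata. Features are kept
#' in the order given by `feature_names` (canonical order: H3K27Ac, RNAPII,
#' ATAC, CTCF).
#'
#' @param patient_id Patient identifier.
#' @param gene_ids Character vector of gene ids (tensor row order).
#' @param tensor 3-d array, genes × n_bins × n_features, raw non-negative
#'   counts.
#' @param labels Numeric vector of per-gene log2(TPM+1) labels.
#' @param feature_names Feature names, one per tensor slice.
#' @param spec The [bin_spec()] the tensor was binned with.
#' @param gene_chrom Optional chromosome per gene (needed for
#'   cross-chromosomal splits).
#' @param meta Optional list of extra provenance (counting mode, annotation
#'   hash, ...).
#' @return Object of class `patient_dataset`.
#' @export
patient_dataset <- function(patient_id, gene_ids, tensor, labels,
                            feature_names = CANONICAL_FEATURES,
                            spec = bin_spec(), gene_chrom = NULL,
                            meta = list()) {
  stopifnot(length(dim(tensor)) == 3)
  if (dim(tensor)[1] != length(gene_ids) ||
      dim(tensor)[2] != spec$n_bins ||
      dim(tensor)[3] != length(feature_names))
    stop("tensor dimensions (", paste(dim(tensor), collapse = "x"),
         ") inconsistent with gene_ids/bin spec/feature_names")
  if (length(labels) != length(gene_ids))
    stop("labels length != number of genes")
  if (any(tensor < 0)) stop("tensor entries must be non-negative")
  if (any(labels < 0)) stop("labels must be non-negative")
  if (!is.null(gene_chrom) && length(gene_chrom) != length(gene_ids))
    stop("gene_chrom length != number of genes")
  structure(
    list(patient_id = patient_id, gene_ids = as.character(gene_ids),
         tensor = tensor, labels = as.numeric(labels),
         feature_names = feature_names, spec = spec,
         gene_chrom = gene_chrom, meta = meta),
    class = "patient_dataset")
}

#' @export
print.patient_dataset <- function(x, ...) {
  cat("<patient_dataset> ", x$patient_id, ": ", length(x$gene_ids),
      " genes x ", x$spec$n_bins, " bins x ",
      length(x$feature_names), " features (",
      paste(x$feature_names, collapse = ", "), ")\n", sep = "")
  cat("  labels: log2(TPM+1) in [", round(min(x$labels), 3), ", ",
      round(max(x$labels), 3), "]\n", sep = "")
  invisible(x)
}

#' Expression labels from windowed RNA counts
#'
#' Converts per-gene RNA counts summed over the TSS window into
#' log2(TPM+1) labels. With a constant region length L for every gene, TPM
#' reduces to `1e6 * c_g / sum(c)`. An all-zero count vector yields all-zero
#' labels (flagged via the `"degenerate"` attribute).
#'
#' @param counts Non-negative per-gene counts.
#' @param region_length_bases Window length in bases (identical for all
#'   genes; the default pipeline uses `2 * half_width`).
#' @return Numeric labels, same length as `counts`.
#' @export
#' @examples
#' expression_labels(c(3, 1))  # log2(TPM+1) for TPM 750000 and 250000
expression_labels <- function(counts, region_length_bases = 5000) {
  if (any(counts < 0)) stop("counts must be non-negative")
  total <- sum(counts / region_length_bases)
  if (total == 0) {
    return(structure(numeric(length(counts)), degenerate = TRUE))
  }
  tpm <- 1e6 * (counts / region_length_bases) / total
  log2(tpm + 1)
}

#' Standardize a patient dataset feature-by-feature
#'
#' Each feature is z-scored with its pooled mean and population standard
#' deviation over all genes × bins of the given gene set (statistics are
#' always those of the set being standardized — applied after any split so
#' no statistics leak across sets). A feature with zero variance is output
#' as all zeros and flagged degenerate; its post-standardization values then
#' coincide with the feature mean, which is the zero-fill value used by
#' perturbation and missing-feature imputation.
#'
#' @param dataset A [patient_dataset()].
#' @param genes Optional integer indices restricting to one gene set.
#' @return List with `tensor` (standardized array over the selected genes),
#'   `records` (data frame: feature, mean, sd, degenerate), plus the
#'   dataset's `labels`, `gene_ids` and `feature_names` restricted to the
#'   same genes.
#' @export
standardize <- function(dataset, genes = NULL) {
  stopifnot(inherits(dataset, "patient_dataset"))
  if (is.null(genes)) genes <- seq_along(dataset$gene_ids)
  if (length(genes) == 0) stop("cannot standardize an empty gene set")
  tens <- dataset$tensor[genes, , , drop = FALSE]
  nf <- length(dataset$feature_names)
  rec <- data.frame(feature = dataset$feature_names,
                    mean = numeric(nf), sd = numeric(nf),
                    degenerate = logical(nf), stringsAsFactors = FALSE)
  for (f in seq_len(nf)) {
    v <- tens[, , f]
    m <- mean(v)
    s <- sqrt(mean((v - m)^2))  # population form
    rec$mean[f] <- m; rec$sd[f] <- s
    if (s == 0) {
      tens[, , f] <- 0
      rec$degenerate[f] <- TRUE
    } else {
      tens[, , f] <- (v - m) / s
    }
  }
  list(tensor = tens, records = rec,
       labels = dataset$labels[genes],
       gene_ids = dataset$gene_ids[genes],
       feature_names = dataset$feature_names,
       spec = dataset$spec)
}

#' Column map for a flattened design matrix
#'
#' @param feature_names Feature names in block order.
#' @param n_bins Bins per feature.
#' @return Data frame with `column` (1-based), `feature`, `bin` (0-based)
#'   and `name` (`FEATURE_binNN`); each feature's bins occupy one contiguous
#'   block.
#' @export
column_map <- function(feature_names = CANONICAL_FEATURES, n_bins = 50L) {
  data.frame(
    column = seq_len(length(feature_names) * n_bins),
    feature = rep(feature_names, each = n_bins),
    bin = rep(seq_len(n_bins) - 1L, length(feature_names)),
    name = paste0(rep(feature_names, each = n_bins), "_bin",
                  sprintf("%02d", rep(seq_len(n_bins) - 1L,
                                      length(feature_names)))),
    stringsAsFactors = FALSE)
}

#' Flatten a standardized tensor into the model design matrix
#'
#' Row g holds the feature blocks in order, bins 5'→3' within each block, so
#' a genes × 50 × 4 tensor becomes a genes × 200 matrix. The mapping is
#' invertible; see [unflatten()].
#'
#' @param std Output of [standardize()] (or any list with `tensor` and
#'   `feature_names`).
#' @return A `flat_design_matrix`: numeric matrix with the column map in
#'   `attr(, "column_map")` and gene ids as rownames.
#' @export
flatten <- function(std) {
  tens <- std$tensor
  nf <- dim(tens)[3]; nb <- dim(tens)[2]
  mat <- do.call(cbind, lapply(seq_len(nf), function(f) tens[, , f]))
  cm <- column_map(std$feature_names, nb)
  dimnames(mat) <- list(std$gene_ids, cm$name)
  structure(mat, column_map = cm, class = c("flat_design_matrix", "matrix",
                                            "array"))
}

#' Invert [flatten()]
#'
#' @param mat A `flat_design_matrix`.
#' @return 3-d array genes × bins × features.
#' @export
unflatten <- function(mat) {
  cm <- attr(mat, "column_map")
  stopifnot(!is.null(cm))
  feats <- unique(cm$feature)
  nb <- sum(cm$feature == feats[1])
  tens <- array(0, c(nrow(mat), nb, length(feats)),
                dimnames = list(rownames(mat), NULL, feats))
  for (f in seq_along(feats))
    tens[, , f] <- mat[, cm$column[cm$feature == feats[f]], drop = FALSE]
  tens
}

#' Train/validation gene split
#'
#' `random_genes` samples genes uniformly; `cross_chromosomal` assigns whole
#' chromosomes to the training set — largest remaining chromosome first,
#' seed-shuffled ties — until the training gene count first reaches
#' `train_fraction * n`, so no chromosome spans both sets.
#'
#' @param dataset A [patient_dataset()]; needs `gene_chrom` for the
#'   cross-chromosomal scheme.
#' @param train_fraction Fraction of genes for training, in (0, 1].
#' @param scheme `"random_genes"` or `"cross_chromosomal"`.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `val`.
#' @export
split_train_val <- function(dataset, train_fraction = 0.7,
                            scheme = c("random_genes", "cross_chromosomal"),
                            seed = 0L) {
  scheme <- match.arg(scheme)
  if (!(train_fraction > 0 && train_fraction <= 1))
    stop("train_fraction must lie in (0, 1]")
  n <- length(dataset$gene_ids)
  target <- train_fraction * n
  set.seed(seed)
  if (scheme == "random_genes") {
    train <- sort(sample.int(n, min(n, ceiling(target))))
  } else {
    if (is.null(dataset$gene_chrom))
      stop("cross_chromosomal split requires gene_chrom metadata")
    sizes <- table(dataset$gene_chrom)
    ord <- names(sizes)[order(-as.integer(sizes),
                              sample.int(length(sizes)))]
    train_chroms <- character(0); got <- 0
    for (ch in ord) {
      if (got >= target) break
      train_chroms <- c(train_chroms, ch)
      got <- got + sizes[[ch]]
    }
    train <- which(dataset$gene_chrom %in% train_chroms)
  }
  list(train = train, val = setdiff(seq_len(n), train))
}

#' Contiguous k-part partition of the gene index
#'
#' Parts 1..k-1 hold `ceiling(n/k)` genes each; part k takes the remainder.
#' Partitioning is contiguous in stored gene order and deterministic. At
#' n = 20,015 and k = 10 this yields nine parts of 2,002 and one of 1,997.
#'
#' @param n_genes Number of genes.
#' @param k Number of parts (default 10).
#' @return Object of class `subset_partition`: list with `k`, `sizes` and
#'   `indices` (list of integer index vectors).
#' @export
partition_subsets <- function(n_genes, k = 10L) {
  n_genes <- as.integer(n_genes); k <- as.integer(k)
  if (k < 1 || k > n_genes) stop("k must satisfy 1 <= k <= n_genes")
  s <- ceiling(n_genes / k)
  last <- n_genes - (k - 1L) * s
  if (last < 1) stop("ceiling rule yields an empty final part for n = ",
                     n_genes, ", k = ", k)
  sizes <- c(rep(s, k - 1L), last)
  ends <- cumsum(sizes)
  starts <- c(1L, utils::head(ends, -1) + 1L)
  structure(list(k = k, sizes = sizes,
                 indices = Map(seq, starts, ends)),
            class = "subset_partition")
}

#' Assemble a patient dataset from annotation + signal tracks
#'
#' Bins each feature track and the RNA track over every gene's TSS window,
#' sums the RNA window counts into expression labels and returns the raw
#' (unstandardized) dataset.
#'
#' @param patient_id Patient identifier.
#' @param genes Gene records from [parse_gene_annotation()].
#' @param tracks Named list of `signal_track`s, one per feature; names define
#'   the feature order.
#' @param rna_track `signal_track` with the RNA-seq signal.
#' @param spec A [bin_spec()].
#' @return A [patient_dataset()].
#' @export
build_patient_dataset <- function(patient_id, genes, tracks, rna_track,
                                  spec = bin_spec()) {
  if (nrow(genes) == 0) stop("no genes parsed from annotation")
  feats <- names(tracks)
  tens <- array(0, c(nrow(genes), spec$n_bins, length(feats)),
                dimnames = list(genes$gene_id, NULL, feats))
  for (f in seq_along(feats))
    tens[, , f] <- bin_matrix(tracks[[f]], genes, spec)
  rna <- rowSums(bin_matrix(rna_track, genes, spec))
  labels <- expression_labels(rna, 2 * spec$half_width)
  patient_dataset(patient_id, genes$gene_id, tens, labels,
                  feature_names = feats, spec = spec,
                  gene_chrom = genes$chrom,
                  meta = list(counting_mode = rna_track$mode,
                              rna_window_counts = rna))
}
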