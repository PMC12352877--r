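# On-disk dataset container and flat exports (plain-text: TSV + JSON).

#' Write a patient dataset to a directory container
#'
#' The container is a directory of plain-text files: `tensor.tsv` (gene_id,
#' feature, bin_0..bin_{n-1}), `labels.tsv` (gene_id, chrom, label) and
#' `meta.json` (patient id, bin spec, feature order, provenance).
#'
#' @param dataset A [patient_dataset()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_patient_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nb <- dataset$spec$n_bins
  rows <- do.call(rbind, lapply(seq_along(dataset$feature_names), function(f)
    data.frame(gene_id = dataset$gene_ids,
               feature = dataset$feature_names[f],
               dataset$tensor[, , f], stringsAsFactors = FALSE)))
  names(rows)[-(1:2)] <- paste0("bin_", seq_len(nb) - 1)
  utils::write.table(rows, file.path(dir, "tensor.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(gene_id = dataset$gene_ids,
               chrom = if (is.null(dataset$gene_chrom)) NA
                       else dataset$gene_chrom,
               label = dataset$labels),
    file.path(dir, "labels.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  meta <- list(patient_id = dataset$patient_id,
               feature_names = dataset$feature_names,
               half_width = dataset$spec$half_width,
               bin_width = dataset$spec$bin_width,
               n_genes = length(dataset$gene_ids),
               meta = dataset$meta[setdiff(names(dataset$meta),
                                           "rna_window_counts")])
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(dir)
}

#' Read a patient dataset container written by [write_patient_dataset()]
#'
#' @param dir Container directory.
#' @return A [patient_dataset()].
#' @export
read_patient_dataset <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  spec <- bin_spec(meta$half_width, meta$bin_width)
  tens_tab <- utils::read.table(file.path(dir, "tensor.tsv"), sep = "\t",
                                header = TRUE, stringsAsFactors = FALSE)
  lab_tab <- utils::read.table(file.path(dir, "labels.tsv"), sep = "\t",
                               header = TRUE, stringsAsFactors = FALSE)
  feats <- meta$feature_names
  gene_ids <- lab_tab$gene_id
  tens <- array(0, c(length(gene_ids), spec$n_bins, length(feats)),
                dimnames = list(gene_ids, NULL, feats))
  for (f in feats) {
    block <- tens_tab[tens_tab$feature == f, , drop = FALSE]
    block <- block[match(gene_ids, block$gene_id), , drop = FALSE]
    tens[, , f] <- as.matrix(block[, -(1:2)])
  }
  chrom <- if (all(is.na(lab_tab$chrom))) NULL else lab_tab$chrom
  patient_dataset(meta$patient_id, gene_ids, tens, lab_tab$label,
                  feature_names = feats, spec = spec, gene_chrom = chrom,
                  meta = if (is.null(meta$meta)) list() else meta$meta)
}

#' Export the standardized flat design matrix as TSV
#'
#' One row per gene: `gene_id`, `label`, then the 200 standardized columns
#' named `FEATURE_binNN`.
#'
#' @param std A standardized dataset from [standardize()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_flat_tsv <- function(std, path) {
  mat <- flatten(std)
  out <- data.frame(gene_id = std$gene_ids, label = std$labels,
                    as.data.frame(unclass_matrix(mat)),
                    check.names = FALSE, stringsAsFactors = FALSE)
  names(out)[-(1:2)] <- colnames(mat)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Export an importance profile as TSV (+ JSON feature sums)
#'
#' @param profile An `importance_profile` from [aggregate_importance()].
#' @param path Output TSV path; feature sums go to `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
write_importance <- function(profile, path) {
  utils::write.table(profile$per_column, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(as.list(profile$feature_sums),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
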