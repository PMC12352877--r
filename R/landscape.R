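# Expression-stratified, bin-wise mean signal landscapes around the TSS.

#' Define an expression stratum
#'
#' Bounds apply to log2(TPM+1) labels.
#'
#' @param name Stratum name.
#' @param lower,upper Bounds (may be `-Inf` / `Inf`).
#' @param lower_inclusive,upper_inclusive Bound inclusivity.
#' @return Object of class `stratum_spec`.
#' @export
stratum_spec <- function(name, lower, upper, lower_inclusive = TRUE,
                         upper_inclusive = TRUE) {
  if (is.finite(lower) && is.finite(upper) && !(lower < upper))
    stop("stratum '", name, "': lower bound must be below upper bound")
  structure(list(name = name, lower = lower, upper = upper,
                 lower_inclusive = lower_inclusive,
                 upper_inclusive = upper_inclusive),
            class = "stratum_spec")
}

#' Default expression strata
#'
#' `high` = labels >= 10; `low` = 0 < label <= 5. Everything else
#' (exact zeros and the (5, 10) band) falls into "other" at assignment
#' time.
#'
#' @return List of two [stratum_spec()]s.
#' @export
default_strata <- function() {
  list(stratum_spec("high", 10, Inf, lower_inclusive = TRUE),
       stratum_spec("low", 0, 5, lower_inclusive = FALSE,
                    upper_inclusive = TRUE))
}

in_stratum <- function(labels, s) {
  lo <- if (s$lower_inclusive) labels >= s$lower else labels > s$lower
  hi <- if (s$upper_inclusive) labels <= s$upper else labels < s$upper
  lo & hi
}

#' Assign genes to expression strata
#'
#' Strata must be pairwise non-overlapping; unmatched genes are labelled
#' `"other"`.
#'
#' @param labels Numeric label vector.
#' @param specs List of [stratum_spec()]s (default [default_strata()]).
#' @return Character vector of stratum names, one per gene.
#' @export
stratify <- function(labels, specs = default_strata()) {
  members <- vapply(specs, function(s) in_stratum(labels, s),
                    logical(length(labels)))
  members <- matrix(members, nrow = length(labels))
  if (any(rowSums(members) > 1)) {
    probe <- labels[which(rowSums(members) > 1)[1]]
    stop("overlapping strata: label ", probe, " matches more than one")
  }
  out <- rep("other", length(labels))
  for (i in seq_along(specs)) out[members[, i]] <- specs[[i]]$name
  out
}

#' Bin-wise mean signal profile over a gene subset
#'
#' Entry b is the arithmetic mean over the subset's genes of the
#' standardized counts at bin b for the chosen feature (bins run 5'→3' of
#' each gene, so TSS-proximal structure pools at the window midpoint).
#'
#' @param std A standardized dataset from [standardize()].
#' @param feature Feature name.
#' @param genes Integer indices of the genes to pool (default: all).
#' @param stratum Optional stratum name recorded in the result (used in
#'   error messages for empty subsets).
#' @return Object of class `landscape_profile`: list with `feature`,
#'   `stratum`, `profile` (length n_bins) and `n`.
#' @export
mean_bin_profile <- function(std, feature, genes = NULL, stratum = "all") {
  fi <- match(feature, std$feature_names)
  if (is.na(fi)) stop("unknown feature '", feature, "'")
  if (is.null(genes)) genes <- seq_along(std$gene_ids)
  if (length(genes) == 0)
    stop("empty gene subset for stratum '", stratum, "'")
  prof <- colMeans(std$tensor[genes, , fi, drop = FALSE])
  structure(list(feature = feature, stratum = stratum,
                 profile = as.numeric(prof), n = length(genes)),
            class = "landscape_profile")
}

#' Stratified landscape table for one feature
#'
#' Computes the all-gene profile plus one profile per stratum and returns a
#' long-format table ready for plotting or TSV export.
#'
#' @param std A standardized dataset from [standardize()].
#' @param feature Feature name.
#' @param specs Stratum specs (default [default_strata()]).
#' @return Data frame with columns `feature`, `stratum`, `bin`, `mean`,
#'   `n_genes`.
#' @export
landscape_table <- function(std, feature, specs = default_strata()) {
  strata <- stratify(std$labels, specs)
  groups <- c(list(all = seq_along(std$labels)),
              split(seq_along(std$labels), strata))
  rows <- lapply(names(groups), function(g) {
    if (length(groups[[g]]) == 0) return(NULL)
    p <- mean_bin_profile(std, feature, groups[[g]], stratum = g)
    data.frame(feature = feature, stratum = g,
               bin = seq_along(p$profile) - 1L, mean = p$profile,
               n_genes = p$n, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
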