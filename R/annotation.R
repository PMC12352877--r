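# Gene annotation parsing: GTF / BED -> strand-aware 0-based TSS records.

#' Parse a gene annotation into TSS records
#'
#' Reads GTF (records of type `"gene"`, identified by their `gene_id`
#' attribute) or BED6/BED12 and reduces each gene to a single strand-aware
#' transcription start site in 0-based coordinates: for "+"-strand genes the
#' TSS is the feature start, for "-"-strand genes it is `end - 1` (the last
#' covered base under 0-based half-open semantics). Duplicated gene ids keep
#' the first record seen, with a warning; records without a usable strand
#' are rejected with a warning.
#'
#' @param x Path to an annotation file, or a character vector of annotation
#'   lines.
#' @param dialect `"gtf"`, `"bed"`, or `"auto"` to infer from the file
#'   extension.
#' @return Data frame with columns `gene_id`, `chrom`, `tss` (0-based),
#'   `strand`.
#' @export
parse_gene_annotation <- function(x, dialect = c("auto", "gtf", "bed")) {
  dialect <- match.arg(dialect)
  path <- annotation_path(x)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, gtf = "gtf", gff = "gtf",
                      bed = "bed",
                      stop("cannot infer annotation dialect from '", ext, "'"))
  }
  lines <- readLines(path)
  body <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  if (!any(body)) return(empty_gene_records())
  validate_annotation_lines(lines, body, dialect)

  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "gtf") "gtf" else "bed"),
    error = function(e) stop("failed to parse ", dialect, " annotation: ",
                             conditionMessage(e), call. = FALSE))
  if (dialect == "gtf") {
    if (!is.null(gr$type) && any(gr$type == "gene")) gr <- gr[gr$type == "gene"]
    ids <- as.character(gr$gene_id)
  } else {
    ids <- if (is.null(gr$name)) paste0("gene_", seq_along(gr))
           else as.character(gr$name)
  }
  strand <- as.character(GenomicRanges::strand(gr))
  unstranded <- !strand %in% c("+", "-")
  if (any(unstranded)) {
    warning(sum(unstranded), " record(s) without strand rejected")
    gr <- gr[!unstranded]; ids <- ids[!unstranded]
    strand <- strand[!unstranded]
  }
  if (length(gr) == 0) return(empty_gene_records())
  tss <- ifelse(strand == "+",
                GenomicRanges::start(gr) - 1,  # 1-based start -> 0-based
                GenomicRanges::end(gr) - 1)    # 0-based coordinate of last base
  out <- data.frame(gene_id = ids,
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    tss = as.numeric(tss),
                    strand = strand,
                    stringsAsFactors = FALSE)
  dup <- duplicated(out$gene_id)
  if (any(dup)) {
    warning("duplicate gene_id(s) ",
            paste(unique(out$gene_id[dup]), collapse = ", "),
            "; keeping first record of each")
    out <- out[!dup, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

empty_gene_records <- function() {
  data.frame(gene_id = character(0), chrom = character(0), tss = numeric(0),
             strand = character(0), stringsAsFactors = FALSE)
}

annotation_path <- function(x) {
  if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) return(x)
  path <- tempfile(fileext = ".annotation")
  writeLines(unlist(strsplit(x, "\n", fixed = TRUE)), path)
  path
}

# Cheap structural pre-scan so malformed lines are reported by number.
validate_annotation_lines <- function(lines, body, dialect) {
  need <- if (dialect == "gtf") 8L else 3L
  for (i in which(body)) {
    f <- strsplit(lines[i], if (dialect == "gtf") "\t" else "[ \t]+")[[1]]
    bad <- length(f) < need ||
      anyNA(suppressWarnings(as.numeric(f[if (dialect == "gtf") 4:5 else 2:3])))
    if (bad)
      stop("malformed ", toupper(dialect), " line ", i, ": ",
           substr(lines[i], 1, 60), call. = FALSE)
  }
  invisible(TRUE)
}
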