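#' Read a differential-expression results table
#'
#' Reads the TSV results dialect of the usual DE callers: one row per gene
#' with columns \code{gene_id}, \code{baseMean}, \code{log2FoldChange} and
#' \code{padj}. Missing adjusted p-values (\code{"NA"}) are preserved as
#' \code{NA}; downstream filters treat them as non-significant.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A \code{de_table}: data.frame with columns \code{gene_id},
#'   \code{base_mean}, \code{lfc}, \code{padj}.
#' @export
read_de_table <- function(path) {
  stopifnot(file.exists(path))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("gene_id", "baseMean", "log2FoldChange", "padj")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("DE table ", path, " lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  tab <- data.frame(
    gene_id   = as.character(raw$gene_id),
    base_mean = parse_numeric(raw$baseMean, "baseMean", allow_na = FALSE),
    lfc       = parse_numeric(raw$log2FoldChange, "log2FoldChange", allow_na = FALSE),
    padj      = parse_numeric(raw$padj, "padj", allow_na = TRUE),
    stringsAsFactors = FALSE
  )
  de_table(tab)
}

#' Construct and validate a DE table
#'
#' @param df Data.frame with columns \code{gene_id}, \code{base_mean},
#'   \code{lfc}, \code{padj}.
#' @return The validated data.frame with class \code{de_table}.
#' @export
de_table <- function(df) {
  stopifnot(all(c("gene_id", "base_mean", "lfc", "padj") %in% names(df)))
  dup <- unique(df$gene_id[duplicated(df$gene_id)])
  if (length(dup) > 0L) {
    stop("duplicate gene id(s) in DE table: ", paste(dup, collapse = ", "))
  }
  if (any(df$base_mean < 0, na.rm = TRUE)) stop("negative base_mean")
  bad_p <- !is.na(df$padj) & (df$padj < 0 | df$padj > 1)
  if (any(bad_p)) stop("padj outside [0,1] for: ", paste(df$gene_id[bad_p], collapse = ", "))
  class(df) <- c("de_table", "data.frame")
  df
}

#' Write a DE table in the reader's dialect
#'
#' @param tab A \code{de_table}.
#' @param path Output path.
#' @export
write_de_table <- function(tab, path) {
  out <- data.frame(
    gene_id = tab$gene_id,
    baseMean = tab$base_mean,
    log2FoldChange = tab$lfc,
    padj = tab$padj
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Strict numeric parser: names the offending 1-based data row on failure.
parse_numeric <- function(x, col, allow_na = TRUE) {
  x <- as.character(x)
  is_na <- is.na(x) | x %in% c("NA", "")
  out <- suppressWarnings(as.numeric(x))
  bad <- is.na(out) & !is_na
  if (any(bad)) {
    stop("malformed numeric in column '", col, "' at row(s): ",
         paste(which(bad), collapse = ", "))
  }
  if (!allow_na && any(is_na)) {
    stop("missing value not allowed in column '", col, "' at row(s): ",
         paste(which(is_na), collapse = ", "))
  }
  out
}

#' Construct a paired tumor/normal expression object
#'
#' Couples a genes-by-samples matrix of normalized log2 expression with
#' sample metadata. Every patient must contribute exactly one tumor and one
#' normal column, and every sample carries a cohort label
#' (\code{"early"} or \code{"late"}).
#'
#' @param values Numeric matrix, genes in rows, samples in columns (column
#'   names are sample ids).
#' @param meta Data.frame with columns \code{sample_id}, \code{patient_id},
#'   \code{tissue} (\code{"tumor"}/\code{"normal"}), \code{cohort}
#'   (\code{"early"}/\code{"late"}).
#' @return An object of class \code{paired_expr} (list with \code{values},
#'   \code{meta}).
#' @export
paired_expr <- function(values, meta) {
  stopifnot(is.matrix(values), !is.null(colnames(values)))
  need <- c("sample_id", "patient_id", "tissue", "cohort")
  stopifnot(all(need %in% names(meta)))
  if (!setequal(colnames(values), meta$sample_id) ||
      anyDuplicated(meta$sample_id) > 0L) {
    stop("metadata sample ids must match matrix columns one-to-one")
  }
  meta <- meta[match(colnames(values), meta$sample_id), , drop = FALSE]
  if (!all(meta$tissue %in% c("tumor", "normal"))) stop("tissue must be tumor/normal")
  if (!all(meta$cohort %in% c("early", "late"))) stop("cohort must be early/late")
  counts <- table(meta$patient_id, meta$tissue)
  bad <- rownames(counts)[counts[, "tumor"] != 1L | counts[, "normal"] != 1L]
  if (length(bad) > 0L) {
    stop("patient(s) without exactly one tumor and one normal sample: ",
         paste(bad, collapse = ", "))
  }
  structure(list(values = values, meta = meta), class = "paired_expr")
}

#' Read an expression matrix with paired metadata
#'
#' @param values_path TSV of normalized log2 expression, first column
#'   \code{gene_id}, remaining columns one per sample.
#' @param meta_path TSV with \code{sample_id}, \code{patient_id},
#'   \code{tissue}, \code{cohort}.
#' @return A \code{paired_expr}.
#' @export
read_expression <- function(values_path, meta_path) {
  raw <- utils::read.delim(values_path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(names(raw)[1] == "gene_id")
  values <- as.matrix(raw[, -1, drop = FALSE])
  rownames(values) <- raw$gene_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  paired_expr(values, meta)
}

#' Write an expression matrix and its metadata
#'
#' @param expr A \code{paired_expr}.
#' @param values_path,meta_path Output paths.
#' @export
write_expression <- function(expr, values_path, meta_path) {
  out <- data.frame(gene_id = rownames(expr$values), expr$values,
                    check.names = FALSE)
  utils::write.table(out, values_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(expr$meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(values_path)
}

#' Read a survival table
#'
#' @param path TSV with columns \code{sample_id}, \code{time} (days, >= 0),
#'   \code{event} (0/1, 1 = death observed).
#' @return Data.frame with those columns; \code{event} logical.
#' @export
read_survival <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("sample_id", "time", "event") %in% names(tab)))
  if (any(tab$time < 0)) stop("negative survival time")
  tab$event <- as.logical(as.integer(tab$event))
  tab
}

#' Write a survival table
#' @param surv Data.frame with \code{sample_id}, \code{time}, \code{event}.
#' @param path Output path.
#' @export
write_survival <- function(surv, path) {
  out <- data.frame(sample_id = surv$sample_id, time = surv$time,
                    event = as.integer(surv$event))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a cell-type score table
#'
#' @param path TSV with first column \code{cell_type} and one column per
#'   sample; scores are nonnegative deconvolution enrichment scores.
#' @return Numeric matrix, cell types in rows.
#' @export
read_cell_scores <- function(path) {
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  stopifnot(names(raw)[1] == "cell_type")
  m <- as.matrix(raw[, -1, drop = FALSE])
  rownames(m) <- raw$cell_type
  if (any(m < 0)) stop("negative cell score")
  m
}

#' Write a cell-type score table
#' @param scores Matrix, cell types in rows.
#' @param path Output path.
#' @export
write_cell_scores <- function(scores, path) {
  out <- data.frame(cell_type = rownames(scores), scores, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Default pipeline configuration
#'
#' All thresholds the pipeline applies, in one place. Values mirror the
#' published filter cascade: DE significance padj < 0.05, |LFC| > 1,
#' base mean > 50; cohort non-significance padj > 0.2, |LFC| < 0.7,
#' base mean > 50; LFC-difference rule > 1.5; event-level splice filter
#' FDR < 0.05, |dPSI| > 0.1, mean tumor junction coverage > 20; node-level
#' filter |dPSI| > 0.1, probability > 0.7; 27-nt junction flanks; strong
#' binder percent-rank <= 0.5 against four common HLA-A alleles.
#'
#' @param ... Named overrides for any default.
#' @return A named list of class \code{pipeline_config}.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    de_padj = 0.05, de_lfc = 1, de_base_mean = 50,
    ns_padj = 0.2, ns_lfc = 0.7, ns_base_mean = 50,
    lfc_difference = 1.5,
    wilcoxon_sig = 0.05, wilcoxon_nonsig = 0.25,
    splice_fdr = 0.05, splice_dpsi = 0.1, splice_coverage = 20,
    node_dpsi = 0.1, node_probability = 0.7,
    flank_nt = 27L,
    hla_alleles = c("HLA-A*01:01", "HLA-A*02:01", "HLA-A*03:01", "HLA-A*24:02"),
    strong_rank = 0.5,
    age_cutoff_days = 18250,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0L) stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  num <- vapply(cfg, is.numeric, logical(1))
  if (!all(vapply(cfg[num], function(x) all(is.finite(x)), logical(1)))) {
    stop("all numeric thresholds must be finite")
  }
  if (cfg$flank_nt < 0 || cfg$flank_nt != round(cfg$flank_nt)) {
    stop("flank_nt must be a nonnegative integer")
  }
  class(cfg) <- "pipeline_config"
  cfg
}
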