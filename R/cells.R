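# Aggregation and comparison of cell-type deconvolution scores.
#
# The deconvolution tool itself is upstream; this module consumes its
# 64-type score table, aggregates types into lymphoid/myeloid/other
# proportions, compares scores between groups and embeds samples by PCA.

#' Read a cell-type grouping file
#'
#' @param path Two-column TSV (\code{cell_type}, \code{group}) mapping each
#'   type to \code{lymphoid}, \code{myeloid} or \code{other}.
#' @return Named character vector: groups indexed by cell type.
#' @export
read_cell_grouping <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cell_type", "group") %in% names(tab)))
  if (anyDuplicated(tab$cell_type) > 0L) stop("duplicate cell type in grouping")
  if (!all(tab$group %in% c("lymphoid", "myeloid", "other"))) {
    stop("groups must be lymphoid/myeloid/other")
  }
  stats::setNames(tab$group, tab$cell_type)
}

#' Default 64-type grouping
#'
#' A lymphoid/myeloid/other assignment for the 64 cell types of the usual
#' bulk deconvolution panel, following its published category annotations
#' (stem, stromal and epithelial categories map to \code{other}).
#' Fully user-overridable via \code{\link{read_cell_grouping}}.
#'
#' @return Named character vector of 64 group labels.
#' @export
default_cell_grouping <- function() {
  read_cell_grouping(system.file("extdata", "cell_type_groups.tsv",
                                 package = "crconset", mustWork = TRUE))
}

#' Per-sample lymphoid/myeloid/other proportions
#'
#' Each group proportion is the sum of that group's cell scores divided by
#' the total sum of all cell scores for the sample; the triple sums to 1.
#' Composite aggregate scores must be excluded from the input (they are
#' sums of the 64 types and would double-count).
#'
#' @param scores Cell-type score matrix, types by samples.
#' @param grouping Named group vector covering every row (default the
#'   shipped 64-type grouping).
#' @return Matrix 3 x samples with rows lymphoid, myeloid, other.
#' @export
group_proportions <- function(scores, grouping = default_cell_grouping()) {
  uncovered <- setdiff(rownames(scores), names(grouping))
  if (length(uncovered) > 0L) {
    stop("cell type(s) not covered by the grouping: ",
         paste(uncovered, collapse = ", "))
  }
  totals <- colSums(scores)
  if (any(totals == 0)) {
    stop("all-zero sample(s): ", paste(colnames(scores)[totals == 0], collapse = ", "))
  }
  g <- grouping[rownames(scores)]
  out <- rbind(
    lymphoid = colSums(scores[g == "lymphoid", , drop = FALSE]),
    myeloid  = colSums(scores[g == "myeloid", , drop = FALSE]),
    other    = colSums(scores[g == "other", , drop = FALSE])
  )
  sweep(out, 2, totals, "/")
}

#' Compare cell scores between groups
#'
#' Per row of the score table, either a paired Wilcoxon signed-rank test of
#' tumor versus matched normal samples, or an unpaired Wilcoxon rank-sum
#' test between the two onset cohorts (tumor samples). Two-sided.
#'
#' @param scores Score matrix (cell types, or group proportions, by samples).
#' @param meta Sample metadata with \code{sample_id}, \code{patient_id},
#'   \code{tissue}, \code{cohort}.
#' @param contrast \code{"paired_tumor_normal"} or \code{"unpaired_cohort"}.
#' @param cohort For the paired contrast, which cohort to test (default
#'   both pooled).
#' @return Data.frame: \code{feature}, \code{p}, \code{median_diff}
#'   (tumor - normal, or early - late).
#' @export
compare_scores <- function(scores, meta,
                           contrast = c("paired_tumor_normal", "unpaired_cohort"),
                           cohort = NULL) {
  contrast <- match.arg(contrast)
  meta <- meta[match(colnames(scores), meta$sample_id), ]
  if (contrast == "paired_tumor_normal") {
    if (!is.null(cohort)) {
      keep <- meta$cohort == cohort
      scores <- scores[, keep, drop = FALSE]
      meta <- meta[keep, , drop = FALSE]
    }
    patients <- intersect(meta$patient_id[meta$tissue == "tumor"],
                          meta$patient_id[meta$tissue == "normal"])
    if (length(patients) < 3L) stop("fewer than 3 complete tumor/normal pairs")
    t_idx <- match(patients, ifelse(meta$tissue == "tumor", meta$patient_id, NA))
    n_idx <- match(patients, ifelse(meta$tissue == "normal", meta$patient_id, NA))
    p <- apply(scores, 1, function(v) paired_wilcoxon_p(v[t_idx] - v[n_idx]))
    md <- apply(scores, 1, function(v) stats::median(v[t_idx] - v[n_idx]))
  } else {
    e <- meta$cohort == "early"
    l <- meta$cohort == "late"
    if (!any(e) || !any(l)) stop("both cohorts must be present")
    p <- apply(scores, 1, function(v) {
      suppressWarnings(stats::wilcox.test(v[e], v[l])$p.value)
    })
    md <- apply(scores, 1, function(v) stats::median(v[e]) - stats::median(v[l]))
  }
  data.frame(feature = rownames(scores), p = unname(p),
             median_diff = unname(md), stringsAsFactors = FALSE)
}

#' Rank the most differential cell types between cohorts
#'
#' Cell types ranked by unpaired rank-sum p (ascending), ties broken by the
#' absolute median score difference (descending); the top \code{k} are
#' returned with a per-type significance flag.
#'
#' @param scores Cell-type score matrix (tumor samples).
#' @param meta Sample metadata (must contain both cohorts).
#' @param k Number of types to return (clamped to the table size with a
#'   warning).
#' @param alpha Flag threshold (default 0.05).
#' @return Data.frame: \code{cell_type}, \code{p}, \code{median_diff},
#'   \code{significant}, best first.
#' @export
top_differential_cells <- function(scores, meta, k = 5L, alpha = 0.05) {
  if (k > nrow(scores)) {
    warning("k exceeds the number of cell types; clamped")
    k <- nrow(scores)
  }
  cmp <- compare_scores(scores, meta, contrast = "unpaired_cohort")
  ord <- order(cmp$p, -abs(cmp$median_diff))
  out <- cmp[ord, , drop = FALSE][seq_len(k), , drop = FALSE]
  names(out)[1] <- "cell_type"
  out$significant <- out$p < alpha
  rownames(out) <- NULL
  out
}

#' PCA embedding of samples over the most variable features
#'
#' Selects the \code{n_top} rows with the largest variance, centers each
#' row, and projects samples onto the leading principal components.
#'
#' @param m Numeric matrix, features by samples.
#' @param n_top Number of most-variable features to keep (clamped).
#' @param impute_missing Mean-impute missing values per feature before PCA
#'   (for PSI matrices); the imputed fraction is reported via a message.
#' @return List: \code{scores} (samples by components), \code{var_explained}
#'   (fraction per component, non-increasing, sums to <= 1).
#' @export
pca_embed <- function(m, n_top = 5000L, impute_missing = FALSE) {
  stopifnot(ncol(m) >= 2)
  if (impute_missing && anyNA(m)) {
    frac <- mean(is.na(m))
    message(sprintf("mean-imputing %.1f%% missing values", 100 * frac))
    for (i in which(rowSums(is.na(m)) > 0)) {
      mu <- mean(m[i, ], na.rm = TRUE)
      m[i, is.na(m[i, ])] <- ifelse(is.nan(mu), 0, mu)
    }
  }
  v <- apply(m, 1, stats::var)
  if (all(v == 0)) stop("constant matrix; PCA undefined")
  n_top <- min(n_top, nrow(m))
  keep <- order(v, decreasing = TRUE)[seq_len(n_top)]
  x <- m[keep, , drop = FALSE]
  pc <- stats::prcomp(t(x), center = TRUE, scale. = FALSE)
  list(scores = pc$x,
       var_explained = pc$sdev^2 / sum(pc$sdev^2))
}
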