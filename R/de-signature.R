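# Cohort-specific differential-expression signature calling.
#
# The cascade runs on DE results tables (one per cohort, tumor vs normal)
# and on normalized paired expression: (1) cohort-level significance calls,
# (2) "unique to early-onset" calls against the later-onset cohort, and
# (3) a paired-Wilcoxon refinement on per-patient fold changes that yields
# the final signature.

#' Median-of-ratios normalization to log2 scale
#'
#' Stand-in normalizer: size factors by the median-of-ratios method (median,
#' per sample, of counts over the per-gene geometric mean reference) and
#' values reported as log2(normalized count + 1). This is not the variance
#' stabilizing transformation of a full DE model fit; the downstream filter
#' rules operate on whatever normalized matrix they are given.
#'
#' @param raw Nonnegative integer count matrix, genes by samples.
#' @param meta Sample metadata (see \code{\link{paired_expr}}).
#' @return A \code{paired_expr} of log2 normalized expression, with
#'   attributes \code{size_factors} and \code{all_zero_genes} (flagged, not
#'   dropped).
#' @export
normalize_counts <- function(raw, meta) {
  stopifnot(is.matrix(raw), all(raw >= 0), ncol(raw) >= 2)
  if (any(colSums(raw) == 0)) {
    stop("all-zero sample(s): ",
         paste(colnames(raw)[colSums(raw) == 0], collapse = ", "))
  }
  sf <- size_factors_mor(raw)
  norm <- sweep(raw, 2, sf, "/")
  out <- log2(norm + 1)
  expr <- paired_expr(out, meta)
  attr(expr, "size_factors") <- sf
  attr(expr, "all_zero_genes") <- rownames(raw)[rowSums(raw) == 0]
  expr
}

# Median-of-ratios size factors over genes with all-positive counts.
size_factors_mor <- function(raw) {
  log_geo <- rowMeans(log(raw))
  use <- is.finite(log_geo)
  if (!any(use)) stop("no gene with all-positive counts; cannot form reference")
  sf <- apply(raw[use, , drop = FALSE], 2, function(cnt) {
    exp(stats::median(log(cnt) - log_geo[use]))
  })
  sf
}

#' Per-patient log2 fold change
#'
#' For every patient, the tumor column minus the matched normal column of
#' log2 normalized expression.
#'
#' @param expr A \code{paired_expr}.
#' @return Matrix genes by patients of per-patient LFC.
#' @export
per_patient_lfc <- function(expr) {
  meta <- expr$meta
  patients <- unique(meta$patient_id)
  out <- matrix(NA_real_, nrow(expr$values), length(patients),
                dimnames = list(rownames(expr$values), patients))
  for (p in patients) {
    t_id <- meta$sample_id[meta$patient_id == p & meta$tissue == "tumor"]
    n_id <- meta$sample_id[meta$patient_id == p & meta$tissue == "normal"]
    if (length(t_id) != 1L || length(n_id) != 1L) {
      stop("patient without a complete tumor/normal pair: ", p)
    }
    out[, p] <- expr$values[, t_id] - expr$values[, n_id]
  }
  out
}

#' Call cohort-level significant genes
#'
#' A gene is significantly deregulated when padj < 0.05, |LFC| > 1 (sign
#' gives the direction) and the mean of normalized counts exceeds 50. All
#' comparisons are strict; missing padj is non-significant.
#'
#' @param tab A \code{de_table}.
#' @param config A \code{\link{pipeline_config}}.
#' @return List with character vectors \code{up} and \code{down}.
#' @export
call_significant <- function(tab, config = pipeline_config()) {
  ok <- !is.na(tab$padj) & tab$padj < config$de_padj &
    tab$base_mean > config$de_base_mean
  list(up   = tab$gene_id[ok & tab$lfc > config$de_lfc],
       down = tab$gene_id[ok & tab$lfc < -config$de_lfc])
}

#' Call genes uniquely differentially expressed in the early-onset cohort
#'
#' A gene qualifies when it is significant in the early-onset (EO) table and
#' the later-onset (LO) cohort either shows no signal (padj > 0.2,
#' |LFC| < 0.7, base mean > 50; rule \code{locrc_not_significant}) or shows
#' a robustly weaker/opposite signal (|LFC difference| > 1.5 with the EO
#' magnitude larger, or significant calls in opposite directions; rule
#' \code{lfc_difference}). Genes present in only one table are excluded
#' with a message.
#'
#' @param eo,lo \code{de_table}s for the early- and later-onset cohorts.
#' @param config A \code{\link{pipeline_config}}.
#' @return Data.frame of class \code{unique_gene_calls}: \code{gene_id},
#'   \code{direction}, \code{rule_fired}, and both cohorts' statistics.
#' @export
call_unique_degs <- function(eo, lo, config = pipeline_config()) {
  shared <- intersect(eo$gene_id, lo$gene_id)
  only <- c(setdiff(eo$gene_id, lo$gene_id), setdiff(lo$gene_id, eo$gene_id))
  if (length(only) > 0L) {
    message(length(only), " gene(s) present in one table only were excluded")
  }
  eo <- eo[match(shared, eo$gene_id), ]
  lo <- lo[match(shared, lo$gene_id), ]
  eo_sig <- call_significant(eo, config)
  lo_sig <- call_significant(lo, config)
  dir <- ifelse(shared %in% eo_sig$up, "up",
                ifelse(shared %in% eo_sig$down, "down", NA))

  lo_padj_ns <- is.na(lo$padj) | lo$padj > config$ns_padj
  lo_not_sig <- lo_padj_ns & abs(lo$lfc) < config$ns_lfc &
    lo$base_mean > config$ns_base_mean
  opposite <- (shared %in% eo_sig$up & shared %in% lo_sig$down) |
    (shared %in% eo_sig$down & shared %in% lo_sig$up)
  lfc_diff <- abs(eo$lfc - lo$lfc) > config$lfc_difference &
    (abs(eo$lfc) > abs(lo$lfc) | opposite)

  keep <- !is.na(dir) & (lo_not_sig | lfc_diff)
  out <- data.frame(
    gene_id = shared[keep],
    direction = dir[keep],
    rule_fired = ifelse(lo_not_sig[keep], "locrc_not_significant", "lfc_difference"),
    eo_lfc = eo$lfc[keep], eo_padj = eo$padj[keep], eo_base_mean = eo$base_mean[keep],
    lo_lfc = lo$lfc[keep], lo_padj = lo$padj[keep], lo_base_mean = lo$base_mean[keep],
    stringsAsFactors = FALSE
  )
  class(out) <- c("unique_gene_calls", "data.frame")
  out
}

# Paired signed-rank p for one vector of per-patient differences.
# Matches R's default: zero differences dropped, exact null for small
# tie-free samples, normal approximation with continuity correction
# otherwise. All differences zero gives p = 1 (no evidence).
paired_wilcoxon_p <- function(d) {
  d <- d[is.finite(d)]
  if (all(d == 0)) return(1)
  suppressWarnings(stats::wilcox.test(d)$p.value)
}

#' Refine unique-gene candidates into the final signature
#'
#' For each candidate, a paired Wilcoxon signed-rank test of tumor versus
#' matched normal expression is run within each cohort. A gene is retained
#' when it is significant in the early-onset cohort (p < 0.05) and either
#' clearly unchanged in the later-onset cohort (p > 0.25), or significant
#' in both with per-patient median LFCs in opposite directions or differing
#' by more than 1.5.
#'
#' @param candidates A \code{unique_gene_calls} data.frame (or a character
#'   vector of gene ids).
#' @param eo_expr,lo_expr \code{paired_expr} objects for the two cohorts.
#' @param config A \code{\link{pipeline_config}}.
#' @return Data.frame of class \code{signature_genes}: \code{gene_id},
#'   \code{eo_wilcoxon_p}, \code{lo_wilcoxon_p}, \code{eo_median_lfc},
#'   \code{lo_median_lfc}, \code{qualifying_rule} (one of \code{lo_nonsig},
#'   \code{opposite_direction}, \code{lfc_difference}).
#' @export
refine_signature <- function(candidates, eo_expr, lo_expr,
                             config = pipeline_config()) {
  genes <- if (is.character(candidates)) candidates else candidates$gene_id
  eo_lfc <- per_patient_lfc(eo_expr)
  lo_lfc <- per_patient_lfc(lo_expr)
  if (ncol(eo_lfc) < 5L || ncol(lo_lfc) < 5L) {
    stop("fewer than 5 tumor/normal pairs in a cohort; paired test unreliable")
  }
  missing <- setdiff(genes, intersect(rownames(eo_lfc), rownames(lo_lfc)))
  if (length(missing) > 0L) {
    stop("candidate gene(s) absent from expression: ", paste(missing, collapse = ", "))
  }
  rows <- lapply(genes, function(g) {
    p_eo <- paired_wilcoxon_p(eo_lfc[g, ])
    p_lo <- paired_wilcoxon_p(lo_lfc[g, ])
    m_eo <- stats::median(eo_lfc[g, ])
    m_lo <- stats::median(lo_lfc[g, ])
    rule <- NA_character_
    if (p_eo < config$wilcoxon_sig) {
      if (p_lo > config$wilcoxon_nonsig) {
        rule <- "lo_nonsig"
      } else if (p_lo < config$wilcoxon_sig) {
        if (sign(m_eo) != sign(m_lo) && m_eo != 0 && m_lo != 0) {
          rule <- "opposite_direction"
        } else if (abs(m_eo - m_lo) > config$lfc_difference) {
          rule <- "lfc_difference"
        }
      }
    }
    data.frame(gene_id = g, eo_wilcoxon_p = p_eo, lo_wilcoxon_p = p_lo,
               eo_median_lfc = m_eo, lo_median_lfc = m_lo,
               qualifying_rule = rule, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[!is.na(out$qualifying_rule), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("signature_genes", "data.frame")
  out
}

#' Build a DE results table from paired counts
#'
#' Stand-in single-cohort DE caller connecting simulated (or otherwise
#' pre-counted) data to the filter cascade: median-of-ratios normalization,
#' per-patient LFC, paired Wilcoxon p-values with Benjamini-Hochberg
#' adjustment, LFC summarized as the per-patient median, and base mean as
#' the mean of normalized counts over all samples.
#'
#' @param raw Count matrix, genes by samples (one cohort, tumor + normal).
#' @param meta Sample metadata for those samples.
#' @return A \code{de_table}.
#' @export
de_table_from_counts <- function(raw, meta) {
  expr <- normalize_counts(raw, meta)
  lfc <- per_patient_lfc(expr)
  pvals <- apply(lfc, 1, paired_wilcoxon_p)
  norm <- sweep(raw, 2, attr(expr, "size_factors"), "/")
  de_table(data.frame(
    gene_id = rownames(raw),
    base_mean = rowMeans(norm),
    lfc = apply(lfc, 1, stats::median),
    padj = stats::p.adjust(pvals, "BH"),
    stringsAsFactors = FALSE
  ))
}
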