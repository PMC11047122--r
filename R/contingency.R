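# 2x2 contingency statistics for gene-set overlap validation and clinical
# correlates, plus the Pearson age-correlation filter.

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p by summing hypergeometric probabilities no larger than the
#' observed table's; odds ratio as the conditional maximum-likelihood
#' estimate under the noncentral hypergeometric likelihood; 95% CI by
#' inverting the one-sided tail probabilities at 0.025 each side (so tables
#' with a zero cell get a 0 or infinite bound). The sample odds ratio
#' (ad/bc) is reported alongside for transparency.
#'
#' @param a,b,c_,d Nonnegative integer cell counts; row 1 = feature present,
#'   column 1 = condition present.
#' @return List: \code{p_two_sided}, \code{or_cmle}, \code{ci_low},
#'   \code{ci_high}, \code{or_sample}, \code{table}.
#' @export
fisher_exact_2x2 <- function(a, b, c_, d) {
  cells <- c(a, b, c_, d)
  if (any(cells < 0)) stop("negative cell count")
  if (sum(cells) == 0) stop("empty table")
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  ft <- stats::fisher.test(m, conf.level = 0.95)
  ci <- c(ft$conf.int[1], ft$conf.int[2])
  # polish the tail inversion: the generic root finder behind the exact test
  # stops around 1e-4; re-solve each 0.025 tail to high precision
  if (ci[1] > 0) ci[1] <- invert_tail(a, b, c_, d, upper = TRUE, start = ci[1])
  if (is.finite(ci[2])) ci[2] <- invert_tail(a, b, c_, d, upper = FALSE, start = ci[2])
  list(p_two_sided = ft$p.value,
       or_cmle = unname(ft$estimate),
       ci_low = ci[1],
       ci_high = ci[2],
       or_sample = (a * d) / (b * c_),
       table = m)
}

# Tail probability of the noncentral hypergeometric distribution with the
# table's margins at odds ratio `or`, at or beyond the observed cell a.
nchyper_tail <- function(or, a, b, c_, d, upper) {
  r1 <- a + b; r2 <- c_ + d; k1 <- a + c_
  k <- max(0, k1 - r2):min(k1, r1)
  lw <- stats::dhyper(k, r1, r2, k1, log = TRUE) + k * log(or)
  w <- exp(lw - max(lw)); w <- w / sum(w)
  if (upper) sum(w[k >= a]) else sum(w[k <= a])
}

invert_tail <- function(a, b, c_, d, upper, start, alpha = 0.025) {
  f <- function(logor) nchyper_tail(exp(logor), a, b, c_, d, upper) - alpha
  lo <- log(start) - 1; hi <- log(start) + 1
  while (f(lo) * f(hi) > 0 && hi - lo < 60) { lo <- lo - 2; hi <- hi + 2 }
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-12)$root)
}

#' Yates-corrected chi-square test for a 2x2 table
#'
#' Pearson chi-square with continuity correction on 1 degree of freedom;
#' the correction clamps |ad - bc| - n/2 at zero. A zero margin yields
#' statistic 0 and p 1 with a warning.
#'
#' @param a,b,c_,d Cell counts as in \code{\link{fisher_exact_2x2}}.
#' @param correct Apply the continuity correction (default TRUE).
#' @return List: \code{statistic}, \code{p}.
#' @export
chi_square_2x2 <- function(a, b, c_, d, correct = TRUE) {
  cells <- c(a, b, c_, d)
  if (any(cells < 0)) stop("negative cell count")
  if (sum(cells) == 0) stop("empty table")
  m <- matrix(cells, nrow = 2, byrow = TRUE)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    warning("zero margin; no association testable")
    return(list(statistic = 0, p = 1))
  }
  ct <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ct$statistic), p = ct$p.value)
}

#' Gene-set overlap test
#'
#' Builds the 2x2 table (|A intersect B|, |A \\ B|, |B \\ A|,
#' |universe \\ (A union B)|) and delegates to
#' \code{\link{fisher_exact_2x2}}.
#'
#' @param set_a,set_b Character vectors, subsets of \code{universe}.
#' @param universe Character vector of all genes considered.
#' @return The \code{fisher_exact_2x2} result plus \code{table} cells.
#' @export
overlap_test <- function(set_a, set_b, universe) {
  outside <- c(setdiff(set_a, universe), setdiff(set_b, universe))
  if (length(outside) > 0L) {
    stop("element(s) outside the universe: ", paste(unique(outside), collapse = ", "))
  }
  set_a <- unique(set_a); set_b <- unique(set_b); universe <- unique(universe)
  a <- length(intersect(set_a, set_b))
  b <- length(setdiff(set_a, set_b))
  c_ <- length(setdiff(set_b, set_a))
  d <- length(universe) - a - b - c_
  fisher_exact_2x2(a, b, c_, d)
}

#' Genes linearly correlated with age
#'
#' Per-gene Pearson correlation of tumor expression with age, two-sided
#' test, keeping genes with p below \code{alpha}. Constant-expression genes
#' are excluded with a warning (the correlation is undefined).
#'
#' @param expr Matrix of tumor expression, genes by samples.
#' @param age_days Nonnegative ages in days, one per sample.
#' @param alpha Significance cutoff (default 0.05).
#' @return Character vector of gene ids.
#' @export
pearson_age_correlation <- function(expr, age_days, alpha = 0.05) {
  stopifnot(ncol(expr) == length(age_days), ncol(expr) >= 3)
  if (stats::sd(age_days) == 0) stop("ages do not vary")
  const <- apply(expr, 1, stats::sd) == 0
  if (any(const)) {
    warning(sum(const), " constant-expression gene(s) excluded")
  }
  keep <- rownames(expr)[!const]
  p <- vapply(keep, function(g) {
    stats::cor.test(expr[g, ], age_days)$p.value
  }, numeric(1))
  keep[p < alpha]
}
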