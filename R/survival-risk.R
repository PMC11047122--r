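# Eight-gene Cox risk score: fit, score, median split, log-rank comparison,
# and the day-based age classification used to define the cohorts.

#' Classify age at diagnosis into onset cohorts
#'
#' Early onset is an age at diagnosis at or under 18,250 days
#' (approximately 50 years); above that is later onset.
#'
#' @param age_days Nonnegative age(s) in days.
#' @param cutoff_days Boundary, inclusive on the early side (default 18250).
#' @return Character vector, \code{"early"} or \code{"late"}.
#' @export
classify_age_days <- function(age_days, cutoff_days = 18250) {
  if (any(age_days < 0)) stop("negative age")
  ifelse(age_days <= cutoff_days, "early", "late")
}

#' Fit a Cox proportional hazards model for a gene signature
#'
#' Partial-likelihood fit with Breslow tie handling. Errors on
#' non-convergence, on singular information (e.g. duplicated covariate
#' columns) and on apparent separation (runaway coefficients).
#'
#' @param expr Tumor expression for the signature genes, genes by samples.
#' @param surv Data.frame with \code{sample_id}, \code{time}, \code{event};
#'   sample ids must match the expression columns.
#' @return A \code{risk_model}: list with \code{gene_ids},
#'   \code{coefficients} and the fitted \code{survival::coxph} object.
#' @export
fit_cox <- function(expr, surv) {
  stopifnot(is.matrix(expr), !anyDuplicated(rownames(expr)))
  idx <- match(colnames(expr), surv$sample_id)
  if (anyNA(idx)) stop("samples missing survival records")
  surv <- surv[idx, ]
  if (sum(surv$event) < 10L) stop("fewer than 10 observed events")
  if (any(apply(expr, 1, stats::sd) == 0)) stop("constant gene expression")
  x <- t(expr)
  fit <- tryCatch(
    survival::coxph(survival::Surv(surv$time, as.integer(surv$event)) ~ x,
                    ties = "breslow",
                    control = survival::coxph.control(eps = 1e-9, iter.max = 100)),
    error = function(e) stop("Cox fit failed: ", conditionMessage(e)),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w))
  )
  beta <- unname(stats::coef(fit))
  if (anyNA(beta)) stop("singular information matrix (collinear genes)")
  if (any(abs(beta) > 50)) stop("apparent separation: runaway coefficient")
  structure(list(gene_ids = rownames(expr),
                 coefficients = beta,
                 fit = fit),
            class = "risk_model")
}

#' Compute per-sample risk scores
#'
#' The risk score is the linear combination sum_i C_i * E_i of each gene's
#' expression with its Cox coefficient.
#'
#' @param model A \code{risk_model} (or list with \code{gene_ids} and
#'   \code{coefficients}).
#' @param expr Tumor expression matrix containing all model genes.
#' @return Named numeric vector of scores, one per sample.
#' @export
compute_risk_score <- function(model, expr) {
  missing <- setdiff(model$gene_ids, rownames(expr))
  if (length(missing) > 0L) {
    stop("gene(s) missing from expression: ", paste(missing, collapse = ", "))
  }
  drop(model$coefficients %*% expr[model$gene_ids, , drop = FALSE])
}

#' Split samples at the median score
#'
#' Scores greater than or equal to the median go to the high-risk group;
#' scores below it to the low-risk group. For an even number of samples the
#' median is the midpoint of the two central order statistics.
#'
#' @param scores Numeric vector (>= 2 samples).
#' @return Character vector of \code{"high"}/\code{"low"}, same names.
#' @export
median_split <- function(scores) {
  stopifnot(length(scores) >= 2)
  m <- stats::median(scores)
  out <- ifelse(scores >= m, "high", "low")
  names(out) <- names(scores)
  out
}

#' Two-group log-rank test
#'
#' Standard log-rank chi-square on one degree of freedom: the sum of
#' observed-minus-expected events over event times, scaled by the
#' hypergeometric variance of the risk sets.
#'
#' @param groups Character/factor vector of two group labels.
#' @param surv Data.frame with \code{time} and \code{event}, aligned with
#'   \code{groups}.
#' @return List: \code{statistic}, \code{p}.
#' @export
logrank_test <- function(groups, surv) {
  groups <- as.character(groups)
  stopifnot(length(groups) == nrow(surv))
  if (length(unique(groups)) != 2L) stop("exactly two non-empty groups required")
  if (sum(surv$event) == 0L) stop("no observed events in either group")
  sd <- survival::survdiff(
    survival::Surv(surv$time, as.integer(surv$event)) ~ groups, rho = 0)
  list(statistic = unname(sd$chisq),
       p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}
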