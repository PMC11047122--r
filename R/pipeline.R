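# End-to-end run on synthetic data: simulate every input, push it through
# all pipeline stages, and collect the headline quantities.

#' Run the full pipeline on synthetic data
#'
#' Simulates paired counts, splice tables, a toy genome and survival data
#' under \code{spec}, then runs every stage: stand-in DE calling and the
#' cohort-unique cascade, signature refinement, dual-caller splice
#' reconciliation with cohort-unique set arithmetic, junction-peptide
#' construction with a deterministic mock binding predictor, Cox risk-score
#' fitting with median split and log-rank test, and cell-score aggregation.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @param seed Random seed (defaults to \code{spec$seed}).
#' @param dir Directory for the simulated splice tables.
#' @param config A \code{\link{pipeline_config}}.
#' @return Nested list with per-stage results; see the sections of the
#'   methods vignette for what each element is.
#' @export
run_pipeline <- function(spec = sim_spec(), seed = spec$seed,
                         dir = tempfile("crconset"), config = pipeline_config()) {
  ## differential expression ------------------------------------------------
  sim <- simulate_paired_counts(spec, seed)
  is_early <- sim$meta$cohort == "early"
  eo_counts <- sim$counts[, sim$meta$sample_id[is_early], drop = FALSE]
  lo_counts <- sim$counts[, sim$meta$sample_id[!is_early], drop = FALSE]
  eo_meta <- sim$meta[is_early, ]
  lo_meta <- sim$meta[!is_early, ]
  eo_tab <- de_table_from_counts(eo_counts, eo_meta)
  lo_tab <- de_table_from_counts(lo_counts, lo_meta)
  unique_calls <- call_unique_degs(eo_tab, lo_tab, config)
  eo_expr <- normalize_counts(eo_counts, eo_meta)
  lo_expr <- normalize_counts(lo_counts, lo_meta)
  signature <- refine_signature(unique_calls, eo_expr, lo_expr, config)

  ## splice reconciliation --------------------------------------------------
  sp <- simulate_splice_tables(spec, dir, seed)
  read_cohort <- function(cohort) {
    ev <- do.call(rbind, lapply(names(sp$rmats[[cohort]]), function(et) {
      read_rmats_table(sp$rmats[[cohort]][[et]], et)
    }))
    node <- read_whippet_diff(sp$whippet[[cohort]])
    list(event = splice_events(ev), node = node)
  }
  early <- read_cohort("early")
  late <- read_cohort("late")
  eo_sig <- filter_rmats_events(early$event, config)
  lo_sig <- filter_rmats_events(late$event, config)
  eo_rec <- match_events(eo_sig, filter_whippet_events(early$node, config))
  lo_rec <- match_events(lo_sig, filter_whippet_events(late$node, config))
  eo_unique <- cohort_unique_events(eo_rec, lo_rec)
  concordance <- caller_concordance_rate(eo_sig, early$node)

  ## neoantigen candidates --------------------------------------------------
  enriched <- select_tumor_enriched(eo_unique)
  gen <- simulate_genome_with_events(spec, events = enriched, seed = seed)
  bed <- build_bed12_blocks(enriched, config$flank_nt)
  cand <- build_peptide_candidates(gen$genome, bed)
  cand <- drop_stop_peptides(cand)
  planted_strong <- character(0)
  if (nrow(cand) > 0L) {
    pick <- seq(1L, nrow(cand), by = 4L)
    planted_strong <- substr(cand$peptide[pick], 1, 9)
    planted_strong <- planted_strong[nchar(planted_strong) == 9L]
  }
  ranked <- rank_9mers(cand, mock_rank_predictor(strong = planted_strong),
                       config$hla_alleles, config$strong_rank)

  ## survival risk score ----------------------------------------------------
  set.seed(seed + 5L)
  k <- length(spec$true_beta)
  surv_expr <- matrix(stats::rnorm(k * spec$n_survival), nrow = k,
                      dimnames = list(paste0("sig_gene", seq_len(k)),
                                      sprintf("t%04d", seq_len(spec$n_survival))))
  true_scores <- drop(spec$true_beta %*% surv_expr)
  names(true_scores) <- colnames(surv_expr)
  surv <- simulate_survival(spec, true_scores, seed)
  model <- fit_cox(surv_expr, surv)
  risk <- compute_risk_score(model, surv_expr)
  groups <- median_split(risk)
  logrank <- logrank_test(groups, surv)

  ## cell-type scores -------------------------------------------------------
  cells <- simulate_cell_scores(spec, seed = seed)
  props <- group_proportions(cells$scores)
  tumor_cols <- cells$meta$sample_id[cells$meta$tissue == "tumor"]
  top_cells <- top_differential_cells(cells$scores[, tumor_cols, drop = FALSE],
                                      cells$meta, k = 5L)

  list(
    de = list(eo_table = eo_tab, lo_table = lo_tab,
              unique_calls = unique_calls, signature = signature,
              truth = sim$truth, eo_expr = eo_expr, lo_expr = lo_expr),
    splice = list(early_reconciled = eo_rec, late_reconciled = lo_rec,
                  early_unique = eo_unique, concordance = concordance,
                  truth = sp$truth),
    neoantigen = list(bed = bed, candidates = ranked,
                      planted_strong = planted_strong,
                      oracle_peptides = gen$peptides),
    survival = list(model = model, risk = risk, groups = groups,
                    logrank = logrank, true_beta = spec$true_beta,
                    surv = surv),
    cells = list(proportions = props, top_cells = top_cells,
                 truth = cells$truth)
  )
}
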