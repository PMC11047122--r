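test_that("median-of-ratios normalization matches the 5-gene oracle", {
  # col2 = 2 x col1: size factors in ratio 2, normalized columns identical
  raw <- matrix(c(10, 20, 40, 100, 7,
                  20, 40, 80, 200, 14), ncol = 2,
                dimnames = list(paste0("g", 1:5), c("s1_tumor", "s1_normal")))
  meta <- data.frame(sample_id = colnames(raw), patient_id = "s1",
                     tissue = c("tumor", "normal"), cohort = "early")
  expr <- normalize_counts(raw, meta)
  sf <- attr(expr, "size_factors")
  expect_equal(unname(sf[2] / sf[1]), 2)
  expect_equal(expr$values[, 1], expr$values[, 2])
  # hand-computed oracle: geometric means, then median of ratios
  geo <- exp(rowMeans(log(raw)))
  sf_oracle <- apply(raw, 2, function(col) stats::median(col / geo))
  expect_equal(unname(sf), unname(sf_oracle))
})

test_that("normalization flags all-zero genes and rejects all-zero samples", {
  raw <- matrix(c(0, 5, 9, 0, 10, 18), ncol = 2,
                dimnames = list(c("z", "a", "b"), c("p_tumor", "p_normal")))
  meta <- data.frame(sample_id = colnames(raw), patient_id = "p",
                     tissue = c("tumor", "normal"), cohort = "early")
  expr <- normalize_counts(raw, meta)
  expect_equal(attr(expr, "all_zero_genes"), "z")
  expect_equal(unname(expr$values["z", ]), c(0, 0))
  raw[, 1] <- 0
  expect_error(normalize_counts(raw, meta), "all-zero sample")
})

test_that("size factors agree with the reference DE implementation", {
  skip_if_not_installed("DESeq2")
  set.seed(13)
  raw <- matrix(rnbinom(200 * 6, mu = 100, size = 5), nrow = 200)
  colnames(raw) <- paste0("s", 1:6)
  ours <- crconset:::size_factors_mor(raw)
  ref <- DESeq2::estimateSizeFactorsForMatrix(raw)
  expect_equal(unname(ours), unname(ref), tolerance = 1e-8)
})

test_that("per-patient LFC is tumor minus normal, matching a loop oracle", {
  set.seed(3)
  n_pat <- 6
  vals <- matrix(stats::rnorm(10 * 2 * n_pat, mean = 8), nrow = 10)
  ids <- as.vector(vapply(seq_len(n_pat),
                          function(i) paste0("p", i, c("_tumor", "_normal")),
                          character(2)))
  colnames(vals) <- ids
  rownames(vals) <- paste0("g", 1:10)
  meta <- data.frame(sample_id = ids, patient_id = rep(paste0("p", 1:n_pat), each = 2),
                     tissue = rep(c("tumor", "normal"), n_pat), cohort = "early")
  expr <- paired_expr(vals, meta)
  lfc <- per_patient_lfc(expr)
  expect_equal(dim(lfc), c(10L, n_pat))
  for (i in seq_len(n_pat)) {
    expect_equal(lfc[, paste0("p", i)],
                 vals[, paste0("p", i, "_tumor")] - vals[, paste0("p", i, "_normal")])
  }
  # identical tumor and normal gives an all-zero column
  vals[, "p1_tumor"] <- vals[, "p1_normal"]
  expr <- paired_expr(vals, meta)
  expect_true(all(per_patient_lfc(expr)[, "p1"] == 0))
})

test_that("significance calls apply strict thresholds on padj, LFC and base mean", {
  tab <- make_de_table(
    gene_id = c("up", "at_mean_boundary", "down", "na_padj", "weak_lfc"),
    lfc = c(2.0, 2.0, -1.5, 3.0, 0.5),
    padj = c(0.01, 0.01, 0.04, NA, 0.001),
    base_mean = c(100, 50, 60, 100, 100))
  sig <- call_significant(tab)
  expect_equal(sig$up, "up")           # boundary base_mean 50 excluded (strict >)
  expect_equal(sig$down, "down")
  expect_false("na_padj" %in% c(sig$up, sig$down))
})

test_that("cohort-unique calls fire the documented rules", {
  eo <- make_de_table(c("gA", "gB", "gC", "gD"),
                      lfc = c(2.0, 2.0, 1.2, 1.2),
                      padj = c(0.01, 0.01, 0.01, 0.01),
                      base_mean = c(100, 100, 60, 60))
  lo <- make_de_table(c("gA", "gB", "gC", "gD"),
                      lfc = c(0.1, 1.6, -1.2, 1.0),
                      padj = c(0.6, 0.01, 0.01, 0.01),
                      base_mean = c(80, 90, 70, 70))
  calls <- call_unique_degs(eo, lo)
  expect_setequal(calls$gene_id, c("gA", "gC"))
  expect_equal(calls$rule_fired[calls$gene_id == "gA"], "locrc_not_significant")
  expect_equal(calls$direction[calls$gene_id == "gA"], "up")
  # gB: significant in both, difference 0.4 <= 1.5 -> not unique
  expect_false("gB" %in% calls$gene_id)
  # gC: opposite significant directions, difference 2.4 -> lfc_difference
  expect_equal(calls$rule_fired[calls$gene_id == "gC"], "lfc_difference")
  # gD: same direction, difference 0.2 -> not unique
  expect_false("gD" %in% calls$gene_id)
})

test_that("genes present in only one table are excluded with a message", {
  eo <- make_de_table(c("g1", "only_eo"), c(2, 2), c(0.01, 0.01), c(100, 100))
  lo <- make_de_table(c("g1", "only_lo"), c(0.1, 0.1), c(0.9, 0.9), c(80, 80))
  expect_message(calls <- call_unique_degs(eo, lo), "one table only")
  expect_equal(calls$gene_id, "g1")
})

test_that("filter cascade recovers exactly the planted unique genes", {
  spec <- small_spec()
  sim <- simulate_paired_counts(spec, seed = 21)
  is_early <- sim$meta$cohort == "early"
  eo <- de_table_from_counts(sim$counts[, sim$meta$sample_id[is_early]],
                             sim$meta[is_early, ])
  lo <- de_table_from_counts(sim$counts[, sim$meta$sample_id[!is_early]],
                             sim$meta[!is_early, ])
  calls <- call_unique_degs(eo, lo)
  expect_setequal(calls$gene_id, sim$truth$unique_genes)
  expect_setequal(calls$gene_id[calls$direction == "up"], sim$truth$unique_up)
  expect_setequal(calls$gene_id[calls$direction == "down"], sim$truth$unique_down)
})

test_that("unique calls are a subset of early-significant calls", {
  spec <- small_spec()
  sim <- simulate_paired_counts(spec, seed = 22)
  is_early <- sim$meta$cohort == "early"
  eo <- de_table_from_counts(sim$counts[, sim$meta$sample_id[is_early]],
                             sim$meta[is_early, ])
  lo <- de_table_from_counts(sim$counts[, sim$meta$sample_id[!is_early]],
                             sim$meta[!is_early, ])
  calls <- call_unique_degs(eo, lo)
  eo_sig <- call_significant(eo)
  expect_true(all(calls$gene_id %in% c(eo_sig$up, eo_sig$down)))
})

test_that("filter predicates are monotone in their thresholds", {
  set.seed(31)
  n <- 200
  eo <- make_de_table(paste0("g", 1:n), stats::rnorm(n, 0, 2),
                      stats::runif(n), exp(stats::runif(n, log(5), log(500))))
  lo <- make_de_table(paste0("g", 1:n), stats::rnorm(n, 0, 2),
                      stats::runif(n), exp(stats::runif(n, log(5), log(500))))
  strict <- pipeline_config()
  loose <- pipeline_config(de_padj = 0.2, de_lfc = 0.5, de_base_mean = 10,
                           ns_padj = 0.1, ns_lfc = 1.2, ns_base_mean = 10,
                           lfc_difference = 0.8)
  s_strict <- call_unique_degs(eo, lo, strict)
  s_loose <- call_unique_degs(eo, lo, loose)
  expect_true(all(s_strict$gene_id %in% s_loose$gene_id))
  sig_strict <- call_significant(eo, strict)
  sig_loose <- call_significant(eo, loose)
  expect_true(all(sig_strict$up %in% sig_loose$up))
  expect_true(all(sig_strict$down %in% sig_loose$down))
})

test_that("refinement rules retain and exclude the documented cases", {
  # build paired expression whose per-patient differences are controlled
  n_pat <- 10
  mk_expr <- function(diffs_by_gene, cohort) {
    genes <- names(diffs_by_gene)
    pat <- paste0(substr(cohort, 1, 1), seq_len(n_pat))
    normal <- matrix(8, length(genes), n_pat, dimnames = list(genes, NULL))
    tumor <- normal + do.call(rbind, diffs_by_gene)
    vals <- cbind(tumor, normal)
    colnames(vals) <- c(paste0(pat, "_t"), paste0(pat, "_n"))
    meta <- data.frame(sample_id = colnames(vals),
                       patient_id = rep(pat, 2),
                       tissue = rep(c("tumor", "normal"), each = n_pat),
                       cohort = cohort)
    paired_expr(vals, meta)
  }
  jitter <- seq(-0.045, 0.045, length.out = n_pat)
  diffs <- list(
    retained_lo_flat = 2 + jitter,      # strong in EO
    retained_opposite = 2 + jitter,
    excluded_same_dir = 2 + jitter
  )
  lo_diffs <- list(
    # alternating signs with increasing magnitudes: signed-rank p ~ 0.77
    retained_lo_flat = c(-1, 1)[rep(1:2, 5)] * (0.02 + 0.01 * (1:10)),
    retained_opposite = -2 + jitter,                  # strong, opposite
    excluded_same_dir = 1.7 + jitter                  # strong, same dir, gap 0.3
  )
  eo_expr <- mk_expr(diffs, "early")
  lo_expr <- mk_expr(lo_diffs, "late")
  out <- refine_signature(names(diffs), eo_expr, lo_expr)
  expect_setequal(out$gene_id, c("retained_lo_flat", "retained_opposite"))
  expect_equal(out$qualifying_rule[out$gene_id == "retained_lo_flat"], "lo_nonsig")
  expect_equal(out$qualifying_rule[out$gene_id == "retained_opposite"],
               "opposite_direction")
})

test_that("refinement recovers exactly the planted signature among planted decoys", {
  spec <- small_spec()
  sim <- simulate_paired_counts(spec, seed = 23)
  is_early <- sim$meta$cohort == "early"
  eo_expr <- normalize_counts(sim$counts[, sim$meta$sample_id[is_early]],
                              sim$meta[is_early, ])
  lo_expr <- normalize_counts(sim$counts[, sim$meta$sample_id[!is_early]],
                              sim$meta[!is_early, ])
  candidates <- c(sim$truth$signature_genes, sim$truth$decoy_genes)
  out <- refine_signature(candidates, eo_expr, lo_expr)
  expect_setequal(out$gene_id, sim$truth$signature_genes)
  # refinement output is always a subset of its candidate input
  expect_true(all(out$gene_id %in% candidates))
})

test_that("refinement refuses cohorts with fewer than 5 pairs", {
  spec <- small_spec(n_early = 3L)
  sim <- simulate_paired_counts(spec, seed = 2)
  is_early <- sim$meta$cohort == "early"
  eo_expr <- normalize_counts(sim$counts[, sim$meta$sample_id[is_early]],
                              sim$meta[is_early, ])
  lo_expr <- normalize_counts(sim$counts[, sim$meta$sample_id[!is_early]],
                              sim$meta[!is_early, ])
  expect_error(refine_signature(sim$truth$signature_genes, eo_expr, lo_expr),
               "fewer than 5")
})

test_that("paired Wilcoxon matches exact enumeration for small tie-free samples", {
  set.seed(17)
  for (n in c(5, 8, 10)) {
    for (rep in 1:10) {
      d <- round(stats::rnorm(n, 0.3), 3)
      while (any(d == 0) || anyDuplicated(abs(d)) > 0) d <- round(stats::rnorm(n, 0.3), 3)
      expect_equal(crconset:::paired_wilcoxon_p(d), enum_signed_rank_p(d),
                   tolerance = 1e-12)
    }
  }
})
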