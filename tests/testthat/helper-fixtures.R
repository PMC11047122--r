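# Shared fixtures: small in-code tables and a reduced simulation spec so
# most tests run in well under a second.

small_spec <- function(...) {
  sim_spec(n_genes = 300L, n_unique_up = 6L, n_unique_down = 6L,
           n_signature = 4L, n_decoy = 4L,
           n_early_events = 12L, n_late_events = 20L, n_shared_events = 5L,
           n_splice_decoys = 6L, n_peptide_events = 6L, ...)
}

# Write a de_table fixture file and return its path.
write_de_fixture <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

make_de_table <- function(gene_id, lfc, padj, base_mean) {
  de_table(data.frame(gene_id = gene_id, base_mean = base_mean, lfc = lfc,
                      padj = padj, stringsAsFactors = FALSE))
}

# Minimal single-row event-level splice event.
one_event <- function(start = 100, end = 200, event_type = "SE", chrom = "chr1",
                      strand = "+", delta_psi = 0.3, fdr = 0.01,
                      ijc = c(20L, 20L), sjc = c(10L, 10L),
                      caller = "event_level", event_id = "ev1") {
  df <- data.frame(event_id = event_id, caller = caller, event_type = event_type,
                   gene_id = "g1", chrom = chrom, strand = strand,
                   start = start, end = end, delta_psi = delta_psi,
                   significance = fdr, stringsAsFactors = FALSE)
  df$ijc_tumor <- I(list(ijc))
  df$sjc_tumor <- I(list(sjc))
  splice_events(df)
}

# Exact two-sided signed-rank p by full enumeration of sign assignments
# (no ties, no zeros, n <= 12).
enum_signed_rank_p <- function(d) {
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  min(1, 2 * min(mean(v_all <= v_obs), mean(v_all >= v_obs)))
}

# Exact two-sided rank-sum p by enumeration of group assignments (no ties).
enum_rank_sum_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combs <- utils::combn(nx + ny, nx)
  w_all <- apply(combs, 2, function(i) sum(r[i])) - nx * (nx + 1) / 2
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}
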