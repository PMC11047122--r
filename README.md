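# crconset

Comparative transcriptomics of early-onset versus later-onset colorectal
cancer (CRC), as an R package.

The incidence of CRC diagnosed before ~50 years of age (early-onset CRC)
has been rising for decades, and early-onset tumors are molecularly
distinct from later-onset ones. A productive way to find what is specific
to the younger patients is to compare patient-matched tumor/normal
transcriptomes *within* each onset cohort and then contrast the cohorts,
so that tumor biology is separated from the biology of aging tissue.
`crconset` implements that comparison as a reusable, tested pipeline:

- **Cohort-specific differential expression.** A gene is *unique to the
  early-onset cohort* when it is significantly deregulated there
  (`padj < 0.05`, `|LFC| > 1`, mean normalized counts > 50) and the
  later-onset cohort shows either no signal (`padj > 0.2`, `|LFC| < 0.7`,
  mean counts > 50) or a robustly weaker/opposite one
  (`|LFC_eo − LFC_lo| > 1.5` with the early-onset magnitude larger, or
  significant calls in opposite directions). A paired Wilcoxon signed-rank
  refinement of per-patient log2 fold changes (tumor − matched normal)
  then yields the final gene signature.
- **Survival risk score.** For a k-gene signature, a Cox proportional
  hazards fit (Breslow ties) gives coefficients `C_1..C_k`; each sample's
  risk score is `Σ C_i E_i` over its expression `E_i`; samples split at
  the median score (ties go high) and the groups are compared with the
  log-rank test. Ages in days classify cohorts at the inclusive 18,250-day
  (~50-year) boundary.
- **Contingency statistics.** Fisher's exact test with the
  conditional-MLE odds ratio and 95% CI by inverting the 0.025 tails of
  the noncentral hypergeometric likelihood; Yates-corrected 2×2
  chi-square; gene-set overlap tests; per-gene Pearson age correlation.
- **Cell-type score aggregation.** 64-type deconvolution scores are
  aggregated into lymphoid/myeloid/other proportions (group sum over
  total), compared by paired/unpaired Wilcoxon tests, ranked for the top
  differential types, and embedded by PCA over the most variable features.
- **Dual-caller splicing reconciliation.** Differential-splicing calls
  from an event-level, junction-count caller (FDR < 0.05, |ΔPSI| > 0.1,
  mean tumor junction coverage > 20) and a node-level caller
  (|ΔPSI| > 0.1, probability > 0.7) are intersected on harmonized
  (chromosome, 1-based coordinate) match keys: one is added to the
  event-level 0-based start, except alternative 3' splice sites, which
  match on the end coordinate. Cohort-unique events are set differences on
  match keys.
- **Splice-junction neoantigen candidates.** Tumor-enriched (ΔPSI > 0)
  events become BED12 records — the variable region plus 27 nt of each
  flanking exon — whose strand-aware spliced sequence is translated in
  three frames; frames containing stop codons are discarded; all 9-mer
  windows are ranked through a pluggable MHC class I binding predictor,
  with percent rank ≤ 0.5 flagged as a strong binder.
- **Synthetic data with planted ground truth** for every input:
  negative-binomial paired counts with planted cohort-specific effects,
  caller-dialect splice tables with planted intersections, a toy genome
  with independently constructed oracle junction peptides, survival times
  with known coefficients, and cell-score tables with planted shifts.

## Worked example

```r
library(crconset)

# the gene-set overlap validation: a 48-gene cohort-unique set against
# 268 age-correlated genes in a 2291-gene universe, 12 genes shared
universe <- sprintf("g%04d", 1:2291)
unique48 <- universe[1:48]
age268   <- c(universe[1:12], universe[101:356])
ov <- overlap_test(unique48, age268, universe)
round(c(or = ov$or_cmle, lo = ov$ci_low, hi = ov$ci_high, p = ov$p_two_sided), 4)
#>     or     lo     hi      p
#> 2.5857 1.2088 5.1650 0.0097
```

The odds ratio 2.59 (95% CI 1.21–5.17, p = 0.0097) says the overlap is
about 2.6-fold enriched over chance — the unique set is validated by the
independent age correlation.

```r
# full synthetic pipeline at the study conditions
res <- run_pipeline(sim_spec(), seed = 1)
nrow(res$de$unique_calls)          # 48 cohort-unique genes (22 up + 26 down)
nrow(res$splice$early_reconciled)  # 82 early reconciled splice events
nrow(res$splice$late_reconciled)   # 191 late
nrow(res$splice$early_unique)      # 33 unique to the early cohort
round(res$survival$model$coefficients, 2)
#> 1.48 -1.06 0.05 0.05 0.08 0.07 0.06 -0.12   (true: 1.5 -1 0 0 0 0 0 0)
```

## Documentation

The methods vignette (`vignettes/crconset-methods.Rmd`) describes the
models, thresholds, numerical choices, what the synthetic generators do
and do not emulate, and known limitations.
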