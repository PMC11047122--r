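---
title: "Methods: cohort-specific expression, splicing and neoantigen analysis in crconset"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cohort-specific expression, splicing and neoantigen analysis in crconset}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crconset)
```

`crconset` compares patient-matched tumor/normal transcriptomes between an
early-onset colorectal cancer cohort (diagnosis at or under 18,250 days,
about 50 years) and a later-onset cohort. This vignette is the package's
account of the methods: the rules and models, the tunable parameters and
why their defaults are what they are, what the synthetic generators
emulate, and the numerical and design choices made where the design was
genuinely open.

## The cohort-specific differential-expression cascade

The cascade consumes one DE results table per cohort (gene, base mean,
log2 fold change, adjusted p) and paired expression matrices. Three rules
are applied in order, all threshold comparisons strict:

1. **Cohort significance** (`call_significant`): `padj < 0.05`,
   `|LFC| > 1`, base mean `> 50`. The base-mean floor suppresses
   low-coverage genes whose fold changes are unstable; a missing `padj`
   (as produced by independent filtering in standard DE engines) is
   treated as non-significant everywhere.
2. **Uniqueness against the other cohort** (`call_unique_degs`): an
   early-significant gene is *unique* when the later-onset table shows no
   signal (`padj > 0.2`, `|LFC| < 0.7`, base mean `> 50`) or a robustly
   weaker or opposite one (`|LFC_eo − LFC_lo| > 1.5` with the early
   magnitude larger, or significant calls in opposite directions). The
   LFC difference is the signed difference of the two cohorts' LFCs; an
   alternative reading (difference of absolute values) was considered and
   rejected because the side-condition "early magnitude larger" already
   encodes the intended asymmetry. When both rules hold, the
   no-signal rule is recorded as the qualifying one.
3. **Paired-Wilcoxon refinement** (`refine_signature`): per-patient LFC is
   tumor minus matched normal log2 expression; within each cohort a
   signed-rank test is run per candidate. A gene is kept when
   `p_eo < 0.05` and either `p_lo > 0.25`, or `p_lo < 0.05` with
   per-patient median LFCs in opposite directions or differing by more
   than 1.5. Cohorts with fewer than 5 pairs are refused — the signed-rank
   test cannot reach `p < 0.05` two-sided below n = 5 with any reliability.

The signed-rank implementation follows the standard behavior of the
statistical environment: zero differences dropped, exact null distribution
for small tie-free samples, normal approximation with continuity
correction otherwise; a vector of all-zero differences reports `p = 1`
(no evidence) rather than an error.

**Normalization stand-in.** Upstream DE engines apply a variance
stabilizing transformation; that transformation is not reproduced here.
The package normalizes counts by median-of-ratios size factors and reports
`log2(normalized count + 1)`. All downstream rules operate on whatever
normalized matrix they are given, so users with engine-produced matrices
can supply them directly. The per-cohort base mean is the mean of
normalized counts within that cohort's analysis — the two cohorts are
analyzed separately, so their base means do not share one normalization.

## Contingency statistics

`fisher_exact_2x2` reports the two-sided exact p (summing hypergeometric
probabilities at or below the observed table's), the conditional
maximum-likelihood odds ratio under the noncentral hypergeometric
likelihood, and a 95% CI by inverting the one-sided 0.025 tails. The
generic root-finder behind the exact test stops around 1e-4, so the
package re-solves each tail to |tail − 0.025| < 1e-6; zero-cell tables
keep their one-sided 0 or infinite bound. The sample odds ratio (ad/bc)
is reported alongside for transparency: for the worked overlap example
(12, 36, 256, 1987) the conditional MLE is 2.586 and the sample ratio
2.587 — close here, but they diverge for unbalanced tables.

`chi_square_2x2` applies the Yates continuity correction by default
(clamping |ad − bc| − n/2 at zero): the published clinical-correlate
p-values reproduce only with the correction, which is how the package
settles the otherwise unstated choice; `correct = FALSE` is available. A
zero margin yields statistic 0 and p 1 with a warning rather than NaN.
Note the corrected approximation tracks the exact test loosely — worst
observed gaps on fuzzed tables with all cells in the hundreds are a few
hundredths — so the test suite asserts bounded disagreement, not
near-equality.

## Survival risk score

`fit_cox` maximizes the Cox partial likelihood with Breslow tie handling
(ties are rare at day resolution, and Breslow is the simplest consistent
choice), requires at least 10 observed events, and converts
non-convergence, singular information and apparent separation (runaway
coefficients) into errors. The risk score is the plain linear combination
`Σ C_i E_i`; `median_split` sends scores at or above the median to the
high-risk group (midpoint median for even n, so ties at the median can
only inflate the high group); `logrank_test` is the standard two-group
chi-square on one degree of freedom. Per-gene survival splits reuse
`median_split` on single-gene expression — no separate operation exists.

The study this design follows did not publish its eight fitted
coefficients, so exact score reproduction is not possible; the package
instead validates by parameter recovery on simulated survival (below).

## Cell-type score aggregation

Deconvolution scores for 64 cell types are aggregated by
`group_proportions`: each of lymphoid/myeloid/other gets its group sum
divided by the sample's total score, so the triple sums to exactly 1.
Composite aggregate scores (immune/stroma/microenvironment summaries)
must be excluded from the input — they are sums of the 64 types and would
double-count. The lymphoid/myeloid/other membership of the 64 types is
not something the upstream publication enumerates; the package ships a
default grouping following the deconvolution tool's published category
annotations (stem, stromal and epithelial categories map to "other") and
treats it as fully user-overridable configuration, isolating the one
unverifiable choice in a replaceable file. PCA (`pca_embed`) selects the
top-variance features (default 5000), centers rows, and reports sample
scores with the variance-explained fractions; PSI matrices reuse it
unchanged with per-event mean imputation of missing values, the imputed
fraction logged. All 64 types enter the cell-type PCA — whether a filtered
subset was ever used upstream is not stated, and using all is the neutral
choice.

## Dual-caller splice reconciliation

The event-level caller reports exon coordinates 0-based (its start is the
last intronic base before the exon); the node-level caller reports 1-based
sites. Internally every interval is 0-based half-open; 1-based views exist
only at format boundaries and in match keys. The match key adds one to the
event-level start — except alternative 3' splice-site events, which the
two callers describe differently and which therefore match on the ending
coordinate (identical under both conventions). Both callers' ΔPSI is
stored as tumor minus normal; because neither dialect records which sample
group was listed first, the readers take an explicit `sample_order`
argument instead of guessing.

Filters: event-level FDR < 0.05, |ΔPSI| > 0.1, mean tumor junction
coverage (inclusion + skipping counts over tumor replicates) > 20;
node-level |ΔPSI| > 0.1, probability > 0.7. Matching is by coordinate key
only — not event-type label or ΔPSI sign — since coordinate comparison is
all the reconciliation requires; a `strict_sign` mode additionally demands
sign agreement. Mutually exclusive exon events key on the first (5'-most)
alternative exon's start; duplicate keys within one caller collapse to the
best-supported record (smallest FDR / largest probability); minus-strand
events use genomic coordinates as stored, mirroring the plus-one rule as
literally defined. Cohort-unique events are a plain set difference on
match keys: an early event is unique unless its key appears among the
later cohort's reconciled events. This set-difference reading (rather
than "failing both callers separately in the later cohort") is adopted
because it is the reading under which the event counts close arithmetically
(82 early − 49 shared = 33 unique).

## Neoantigen candidates

Tumor-enriched events (ΔPSI strictly positive — the variable region more
included in tumors) become BED12 records with three blocks: the last 27 nt
of the upstream exon, the variable region, the first 27 nt of the
downstream exon. Flanks are exon-adjacent, not genomic-adjacent: spliced
(block-split) extraction excludes introns, and 27 nt = 9 codons is exactly
what junction-spanning 9-mers need. Flanks clamp to short exons with a
warning; events without flanking-exon annotation yield single-block
records; mutually exclusive exon pairs emit one record per alternative
exon. Extraction concatenates block sequences in genomic order and
reverse-complements the whole for minus-strand records; non-ACGT bases
pass through.

Translation covers the three forward frames with the standard code,
dropping trailing partial codons; a frame containing any stop codon is
discarded whole (truncating at the stop is a config-level alternative,
not the default). Every 9-mer window of each surviving peptide is scored
through a pluggable predictor — the neural MHC binding predictor itself is
deliberately out of scope; the package ships a predictor-compatible
peptide FASTA writer and a deterministic hash-based mock for testing. A
candidate's per-allele rank is the minimum over its windows, and a strong
binder has minimum rank ≤ 0.5 (the top 0.5% of the predictor's reference
distribution) for any of the four default HLA-A alleles (A\*01:01,
A\*02:01, A\*03:01, A\*24:02).

## The synthetic-data module

Every input the pipeline consumes can be generated with planted ground
truth; all generators are deterministic functions of (spec, seed), and
their defaults are the study conditions: 21 early and 22 late tumor/normal
pairs, 22 planted unique-up and 26 unique-down genes, an 8-gene signature,
and 82/191/49 early/late/shared reconciled splice events.

- **Counts**: negative-binomial with dispersion 0.1 and library sizes
  log-uniform over a 4-fold range (typical bulk RNA-seq scale — these are
  configuration, not claims about any dataset), with a patient random
  effect on library size to make the pairing real. Planted genes carry
  |LFC| 3 in the early cohort. Signature genes additionally carry a
  later-onset effect of 1.5 in the *opposite* direction, and refinement
  decoys a same-direction 2.5: at these effect sizes the refinement rules
  fire deterministically, so the planted signature is recovered exactly
  against the decoys. (A cascade-unique gene that fails refinement with a
  truly null later cohort can only do so through the random position of
  its later-onset p-value, so "exact recovery" is only a meaningful claim
  under the opposite-direction construction.) Planted splice significance
  is written directly into the dialect columns rather than re-derived
  from simulated reads, because the reconciliation logic starts at caller
  outputs.
- **Splice tables**: a common planted event set written into both dialects
  with their native conventions; decoys failing exactly one filter each;
  extra event-level-only significant events planting a cross-caller
  concordance of 0.8; alternative 3' nodes written with a deliberately
  different start so only end-matching reconciles them.
- **Genome and oracle peptides**: random-sequence chromosomes covering the
  planted cassettes; ground-truth peptides built by direct substring
  concatenation and an independent reference translation — a second code
  path that never touches the pipeline's BED12 extractor or codon table.
- **Survival**: exponential event times with hazard
  `1e-3 · exp(score)` per day and independent uniform censoring whose
  upper bound is calibrated so ~30% of a null cohort is censored (the
  uniform-censoring relation `(1 − e^{−x})/x = 0.3` is solved at run
  time). Thirty percent keeps log-rank power simulations stable.
- **Cell scores**: gamma-distributed with shape 4 and per-type scales
  spanning 0.005–0.1 (scores are small positive enrichment values), with
  a 2x multiplicative shift planted in early tumors for one type. Shape 4
  keeps the planted 2x shift reliably at the top of the differential
  ranking at the study's sample sizes.

What the generators do **not** emulate: gene-gene correlation, outlier
samples and batch effects in counts; read-level PSI noise and coverage
coupling in splice tables; realistic codon usage or ORF structure in the
genome (random sequence means most long frames contain stops, which is
itself realistic for junction peptides); informative censoring. Passing
tests therefore demonstrate that the *rules and bookkeeping* are correct
under known truth — not that the thresholds are well-calibrated for any
particular real dataset.

## Numerical choices and degenerate inputs

- All internal genomic intervals are 0-based half-open; readers and
  writers convert at the boundary, and a fuzzed round-trip test holds for
  every dialect.
- Cox convergence: tight tolerance with 100-iteration cap; coefficients
  beyond |50| are treated as separation and refused.
- Constant-expression genes are refused by the Cox fit and excluded (with
  a warning) from age correlation; all-zero samples are errors; all-zero
  genes are flagged but retained by normalization.
- Median split with all-equal scores sends everyone to the high group —
  forced by the ≥-median rule.
- `top_differential_cells` clamps k to 64 with a warning; an all-null
  table still returns a ranking, flagged non-significant.
- Problem sizes in the shipped tests and acceptance script: 1200 genes,
  the study's 21/22 pairs and 82/191/49 events, 100 fuzzed peptide
  events, Cox recovery at n = 500, and 500 log-rank null replicates —
  sizes at which every stochastic check has comfortable margins while the
  whole suite stays quick on a laptop.

## Interfaces

Readers and writers cover DE tables, expression + metadata, survival,
cell scores, both splice dialects, BED12, genome FASTA and peptide FASTA.
The R functions (plus `run_pipeline` and `scripts/acceptance.R`) are the
package's interface; no shell subcommand layer is provided, as every
intended user drives the analysis from R.

## Known limitations

- The vst of the upstream DE engine is not reproduced; the stand-in
  changes absolute expression values (not the cascade's table-level
  rules, which consume the engine's own tables).
- Exact reproduction of the published eight-gene score is impossible
  without the unpublished coefficients; validation is by synthetic
  parameter recovery.
- r×c exact tests (beyond 2×2) and multiple-testing correction across
  clinical-correlate rows are out of scope, matching the upstream
  analysis, which reported unadjusted tests.
- How mutually-exclusive-exon and retained-intron events were keyed
  against the node-level caller is not documented upstream; the
  first-exon-start choice is flagged per event in output.
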