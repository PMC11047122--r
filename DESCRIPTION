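Package: crconset
Title: Comparative Transcriptomics of Early- Versus Later-Onset Colorectal Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing tumor/normal transcriptomes between early-onset
    (diagnosis at or under 50 years) and later-onset colorectal cancer cohorts.
    Implements cohort-specific differential-expression signature calling with a
    paired-Wilcoxon refinement step, an eight-gene Cox risk score with median
    split and log-rank comparison, cell-type deconvolution score aggregation
    into lymphoid/myeloid/other proportions, reconciliation of alternative
    splicing calls between an event-level (junction count) caller and a
    node-level caller with coordinate-convention harmonization, and
    construction of junction-spanning neoantigen candidate peptides ranked
    through a pluggable MHC class I binding predictor. A synthetic-data module
    generates every input the pipeline consumes, with planted ground truth, so
    all stages can be exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    Biostrings
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
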