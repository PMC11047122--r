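# Synthetic-data generators with planted ground truth.
#
# Every generator is a deterministic function of (spec, seed) and emits
# exactly the formats the package's readers consume. Defaults reproduce the
# study conditions: 21 early-onset and 22 later-onset tumor/normal pairs,
# 22 + 26 planted cohort-unique genes containing an 8-gene signature, and
# 82 early / 191 late / 49 shared reconciled splice events.

#' Simulation specification
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A validated list of class \code{sim_spec}.
#' @details Defaults: cohorts of 21 (early) and 22 (late) tumor/normal
#'   pairs; 1200 genes with 22 planted unique-up and 26 unique-down genes
#'   at |LFC| 3, of which 8 form the signature (later-onset effect of 1.5
#'   in the opposite direction); 10 refinement decoys (later-onset effect
#'   2.5 in the same direction); negative-binomial dispersion 0.1 and
#'   library sizes log-uniform over a 4-fold range; 82/191/49
#'   early/late/shared reconciled splice events with cross-caller
#'   concordance 0.8; 150-nt exons, 27-nt flanks; survival baseline hazard
#'   1e-3 per day with true coefficients (1.5, -1, 0, ...) and ~30%
#'   independent uniform censoring; one 2x cell-score shift planted in
#'   early tumors.
#' @export
sim_spec <- function(...) {
  spec <- list(
    n_early = 21L, n_late = 22L,
    n_genes = 1200L,
    n_unique_up = 22L, n_unique_down = 26L,
    n_signature = 8L, n_decoy = 10L,
    effect_lfc = 3, signature_late_lfc = 1.5, decoy_late_lfc = 2.5,
    dispersion = 0.1, libsize_fold = 4,
    n_early_events = 82L, n_late_events = 191L, n_shared_events = 49L,
    concordance = 0.8, n_splice_decoys = 30L,
    event_type_weights = c(SE = 0.70, MXE = 0.12, A5SS = 0.10,
                           A3SS = 0.05, RI = 0.03),
    exon_len = 150L, flank_nt = 27L, n_peptide_events = 12L,
    baseline_hazard = 1e-3, censor_frac = 0.3,
    true_beta = c(1.5, -1, 0, 0, 0, 0, 0, 0), n_survival = 500L,
    cell_shift_types = "aDC", cell_shift_factor = 2, cell_score_shape = 4,
    seed = 1L
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(spec))
  if (length(unknown) > 0L) stop("unknown spec field(s): ", paste(unknown, collapse = ", "))
  spec[names(dots)] <- dots
  with(spec, {
    stopifnot(n_unique_up + n_unique_down + n_decoy <= n_genes,
              n_signature <= n_unique_up + n_unique_down,
              n_shared_events <= min(n_early_events, n_late_events),
              dispersion > 0, libsize_fold >= 1, baseline_hazard > 0,
              concordance > 0, concordance <= 1,
              censor_frac >= 0, censor_frac < 1)
  })
  class(spec) <- "sim_spec"
  spec
}

#' Simulate paired tumor/normal counts with planted cohort-specific effects
#'
#' Negative-binomial counts for both cohorts with a patient random effect
#' on library size. Planted genes carry the specified tumor-vs-normal LFC
#' in the specified cohort only (see \code{\link{sim_spec}}).
#'
#' @param spec A \code{\link{sim_spec}}.
#' @param seed Random seed (defaults to \code{spec$seed}).
#' @return List: \code{counts} (genes by samples), \code{meta}, and
#'   \code{truth} (planted gene classes and per-cohort LFC vectors).
#' @export
simulate_paired_counts <- function(spec = sim_spec(), seed = spec$seed) {
  set.seed(seed)
  n_genes <- spec$n_genes
  genes <- sprintf("gene%04d", seq_len(n_genes))
  n_up <- spec$n_unique_up; n_down <- spec$n_unique_down
  idx_up <- seq_len(n_up)
  idx_down <- n_up + seq_len(n_down)
  n_sig_up <- ceiling(spec$n_signature / 2)
  idx_sig <- c(idx_up[seq_len(min(n_sig_up, n_up))],
               idx_down[seq_len(spec$n_signature - min(n_sig_up, n_up))])
  idx_decoy <- n_up + n_down + seq_len(spec$n_decoy)

  lfc_early <- numeric(n_genes)
  lfc_late <- numeric(n_genes)
  lfc_early[idx_up] <- spec$effect_lfc
  lfc_early[idx_down] <- -spec$effect_lfc
  lfc_late[idx_sig] <- -sign(lfc_early[idx_sig]) * spec$signature_late_lfc
  decoy_sign <- rep_len(c(1, -1), spec$n_decoy)
  lfc_early[idx_decoy] <- decoy_sign * spec$effect_lfc
  lfc_late[idx_decoy] <- decoy_sign * spec$decoy_late_lfc

  q <- exp(stats::runif(n_genes, log(20), log(500)))
  planted <- c(idx_up, idx_down, idx_decoy)
  q[planted] <- stats::runif(length(planted), 150, 400)

  build_cohort <- function(cohort, n_pat, lfc) {
    pat <- sprintf("%s%02d", substr(cohort, 1, 1), seq_len(n_pat))
    pat_sf <- exp(stats::runif(n_pat, 0, log(spec$libsize_fold)))
    cols <- list(); meta <- list()
    for (i in seq_len(n_pat)) {
      for (tissue in c("tumor", "normal")) {
        sf <- pat_sf[i] * exp(stats::runif(1, -0.05, 0.05))
        mu <- sf * q * 2^(if (tissue == "tumor") lfc else 0)
        cols[[paste(pat[i], tissue, sep = "_")]] <-
          stats::rnbinom(n_genes, mu = mu, size = 1 / spec$dispersion)
        meta[[length(meta) + 1L]] <- data.frame(
          sample_id = paste(pat[i], tissue, sep = "_"),
          patient_id = pat[i], tissue = tissue, cohort = cohort,
          stringsAsFactors = FALSE)
      }
    }
    list(counts = do.call(cbind, cols), meta = do.call(rbind, meta))
  }
  early <- build_cohort("early", spec$n_early, lfc_early)
  late <- build_cohort("late", spec$n_late, lfc_late)
  counts <- cbind(early$counts, late$counts)
  rownames(counts) <- genes
  meta <- rbind(early$meta, late$meta)
  truth <- list(
    unique_up = genes[idx_up], unique_down = genes[idx_down],
    unique_genes = genes[c(idx_up, idx_down)],
    signature_genes = genes[idx_sig], decoy_genes = genes[idx_decoy],
    lfc_early = stats::setNames(lfc_early, genes),
    lfc_late = stats::setNames(lfc_late, genes)
  )
  list(counts = counts, meta = meta, truth = truth)
}

# Deterministic grid of event loci: upstream exon, variable exon (plus a
# second alternative exon for MXE), downstream exon, all within a
# 1200-nt segment, alternating between two chromosomes.
event_locus <- function(k, exon_len) {
  seg <- 1200L
  chrom <- paste0("chr", (k - 1L) %% 2L + 1L)
  o <- ((k - 1L) %/% 2L) * seg
  list(chrom = chrom,
       up = c(o + 100, o + 100 + exon_len),
       var = c(o + 400, o + 400 + exon_len),
       var2 = c(o + 600, o + 600 + exon_len),
       dn = c(o + 800, o + 800 + exon_len))
}

make_event_rows <- function(ks, types, spec, ids, dpsi, fdr, counts_mean) {
  rows <- lapply(seq_along(ks), function(i) {
    loc <- event_locus(ks[i], spec$exon_len)
    is_mxe <- types[i] == "MXE"
    data.frame(event_id = ids[i], caller = "event_level", event_type = types[i],
               gene_id = paste0("g", ks[i]), chrom = loc$chrom,
               strand = c("+", "-")[ks[i] %% 2L + 1L],
               start = loc$var[1], end = loc$var[2],
               start2 = if (is_mxe) loc$var2[1] else NA_real_,
               end2 = if (is_mxe) loc$var2[2] else NA_real_,
               upstream_start = loc$up[1], upstream_end = loc$up[2],
               downstream_start = loc$dn[1], downstream_end = loc$dn[2],
               delta_psi = dpsi[i], significance = fdr[i],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  n_rep <- 3L
  df$ijc_tumor <- I(lapply(seq_len(nrow(df)), function(i) {
    stats::rpois(n_rep, counts_mean[i] / 2) }))
  df$sjc_tumor <- I(lapply(seq_len(nrow(df)), function(i) {
    stats::rpois(n_rep, counts_mean[i] / 2) }))
  splice_events(df)
}

#' Simulate dual-caller differential-splicing tables
#'
#' Writes, per cohort, event-level (junction-count dialect, one file per
#' event type) and node-level (diff dialect) tables into \code{dir}. A
#' common planted event set appears in both dialects with their native
#' conventions (0-based starts event-level, 1-based node-level; alternative
#' 3' events get a deliberately different node start so only end-matching
#' reconciles them). Planted significance flags control FDR, delta PSI,
#' probability and coverage. Each cohort also receives filter-failing decoy
#' events and -- to plant a cross-caller concordance below 1 -- significant
#' event-level events with no node-level counterpart.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @param dir Output directory (created if needed).
#' @param seed Random seed (defaults to \code{spec$seed}).
#' @return List: \code{rmats} and \code{whippet} file paths per cohort,
#'   \code{truth} (data.frame of planted events with cohort significance
#'   flags and match keys), \code{truth_path} (sidecar TSV).
#' @export
simulate_splice_tables <- function(spec = sim_spec(), dir = tempfile("splice"),
                                   seed = spec$seed) {
  set.seed(seed + 1L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n_shared <- spec$n_shared_events
  n_eo <- spec$n_early_events - n_shared
  n_lo <- spec$n_late_events - n_shared
  n_extra <- function(n_sig) round(n_sig * (1 - spec$concordance) / spec$concordance)
  n_xe <- n_extra(spec$n_early_events)
  n_xl <- n_extra(spec$n_late_events)
  n_dec <- spec$n_splice_decoys
  total <- n_shared + n_eo + n_lo + n_xe + n_xl + 2L * n_dec
  ks <- seq_len(total)
  types <- sample(names(spec$event_type_weights), total, replace = TRUE,
                  prob = spec$event_type_weights)
  # ids carry the type prefix so the dialect writer/reader round-trips them
  ids <- sprintf("%s_ev%04d", types, ks)
  grp <- rep(c("shared", "early", "late", "extra_early", "extra_late",
               "decoy_early", "decoy_late"),
             c(n_shared, n_eo, n_lo, n_xe, n_xl, n_dec, n_dec))

  dpsi <- stats::runif(total, 0.15, 0.6) *
    sample(c(1, -1), total, replace = TRUE, prob = c(0.7, 0.3))
  fdr <- stats::runif(total, 0, 0.04)
  cov_mean <- stats::runif(total, 60, 120)
  # decoys fail exactly one event-level filter each, round-robin
  decoy_mode <- rep_len(c("fdr", "dpsi", "coverage"), n_dec)
  for (side in c("decoy_early", "decoy_late")) {
    di <- which(grp == side)
    fdr[di][decoy_mode == "fdr"] <- stats::runif(sum(decoy_mode == "fdr"), 0.1, 0.9)
    dpsi[di][decoy_mode == "dpsi"] <- stats::runif(sum(decoy_mode == "dpsi"), 0.01, 0.09)
    cov_mean[di][decoy_mode == "coverage"] <- 4
  }

  in_early <- grp %in% c("shared", "early", "extra_early", "decoy_early")
  in_late <- grp %in% c("shared", "late", "extra_late", "decoy_late")
  in_whippet <- !grp %in% c("extra_early", "extra_late")

  all_events <- make_event_rows(ks, types, spec, ids, dpsi, fdr, cov_mean)

  write_cohort <- function(cohort, sel) {
    ev <- all_events[sel, , drop = FALSE]
    paths <- character(0)
    for (et in unique(ev$event_type)) {
      p <- file.path(dir, sprintf("%s_%s.MATS.JC.txt", cohort, et))
      write_rmats_table(splice_events(ev[ev$event_type == et, , drop = FALSE]), p)
      paths[et] <- p
    }
    wh <- ev[in_whippet[sel], , drop = FALSE]
    wh$caller <- "node_level"
    wh$significance <- stats::runif(nrow(wh), 0.75, 0.99)
    # node dialect: A3SS nodes share only the end coordinate
    a3 <- wh$event_type == "A3SS"
    wh$start[a3] <- wh$start[a3] - 30
    type_map <- c(SE = "CE", MXE = "CE", A5SS = "AD", A3SS = "AA", RI = "RI")
    wh$event_type <- unname(type_map[wh$event_type])
    wp <- file.path(dir, sprintf("%s_whippet.diff.tsv", cohort))
    write_whippet_diff(splice_events(wh), wp)
    list(rmats = paths, whippet = wp)
  }
  early_files <- write_cohort("early", in_early)
  late_files <- write_cohort("late", in_late)

  truth <- data.frame(
    event_id = ids, event_type = types, chrom = all_events$chrom,
    start = all_events$start, end = all_events$end,
    match_key = harmonize_key(all_events),
    category = grp,
    sig_early = grp %in% c("shared", "early"),
    sig_late = grp %in% c("shared", "late"),
    rmats_sig_early = in_early & !grp %in% "decoy_early",
    rmats_sig_late = in_late & !grp %in% "decoy_late",
    in_whippet = in_whippet,
    delta_psi = dpsi,
    stringsAsFactors = FALSE
  )
  truth_path <- file.path(dir, "ground_truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(rmats = list(early = early_files$rmats, late = late_files$rmats),
       whippet = list(early = early_files$whippet, late = late_files$whippet),
       truth = truth, truth_path = truth_path)
}

# Independent reverse complement (plain string ops, used only by the
# generator's peptide oracle).
revcomp_chr <- function(seq) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", seq), "")[[1]]), collapse = "")
}

#' Simulate a genome carrying planted cassette events, with oracle peptides
#'
#' Generates a random-sequence genome covering the given (or default)
#' planted events and computes ground-truth junction peptides by directly
#' concatenating the flanking-exon and variable-exon substrings (reverse
#' complemented on the minus strand) and translating the three forward
#' frames. The oracle path is plain string slicing plus
#' \code{Biostrings::translate} -- independent of the pipeline's BED12
#' extractor and codon table.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @param events Optional \code{splice_events} to cover; by default
#'   \code{spec$n_peptide_events} skipped-exon cassettes on alternating
#'   strands.
#' @param seed Random seed (defaults to \code{spec$seed}).
#' @return List: \code{genome} (named character), \code{events},
#'   \code{peptides} (data.frame \code{name}, \code{frame}, \code{peptide},
#'   \code{contains_stop}, one row per frame per variable exon).
#' @export
simulate_genome_with_events <- function(spec = sim_spec(), events = NULL,
                                        seed = spec$seed) {
  set.seed(seed + 2L)
  if (is.null(events)) {
    n <- spec$n_peptide_events
    events <- make_event_rows(seq_len(n), rep("SE", n), spec,
                              sprintf("pep%03d", seq_len(n)),
                              stats::runif(n, 0.15, 0.5),
                              stats::runif(n, 0, 0.04),
                              stats::runif(n, 60, 120))
  }
  chroms <- unique(events$chrom)
  genome <- vapply(chroms, function(ch) {
    sel <- events$chrom == ch
    len <- max(c(events$end[sel], events$downstream_end[sel],
                 events$end2[sel]), na.rm = TRUE) + 200
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, character(1))
  names(genome) <- chroms

  nm <- if ("match_key" %in% names(events)) events$match_key else events$event_id
  pep_rows <- list()
  for (i in seq_len(nrow(events))) {
    ch <- genome[[events$chrom[i]]]
    fl <- spec$flank_nt
    exons <- list(c(events$start[i], events$end[i]))
    names(exons) <- nm[i]
    if (!is.na(events$start2[i])) {
      exons[[paste0(nm[i], "|exon2")]] <- c(events$start2[i], events$end2[i])
    }
    for (j in seq_along(exons)) {
      v <- exons[[j]]
      pieces <- character(0)
      if (!is.na(events$upstream_start[i])) {
        u <- c(events$upstream_start[i], events$upstream_end[i])
        f <- min(fl, u[2] - u[1])
        pieces <- c(pieces, substr(ch, u[2] - f + 1, u[2]))
      }
      pieces <- c(pieces, substr(ch, v[1] + 1, v[2]))
      if (!is.na(events$downstream_start[i])) {
        d <- c(events$downstream_start[i], events$downstream_end[i])
        f <- min(fl, d[2] - d[1])
        pieces <- c(pieces, substr(ch, d[1] + 1, d[1] + f))
      }
      seq <- paste(pieces, collapse = "")
      if (events$strand[i] == "-") seq <- revcomp_chr(seq)
      for (frame in 1:3) {
        sub <- substr(seq, frame, frame + ((nchar(seq) - frame + 1) %/% 3) * 3 - 1)
        pep <- if (nchar(sub) >= 3) {
          as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                             no.init.codon = TRUE))
        } else ""
        pep_rows[[length(pep_rows) + 1L]] <- data.frame(
          name = names(exons)[j], frame = frame, peptide = pep,
          contains_stop = grepl("*", pep, fixed = TRUE),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(genome = genome, events = events, peptides = do.call(rbind, pep_rows))
}

#' Simulate survival times with hazard tied to a known linear score
#'
#' Exponential event times with hazard \code{baseline_hazard * exp(score)}
#' and independent uniform censoring calibrated to the spec's censoring
#' fraction at a null score.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @param scores Named numeric vector: the true linear predictor per sample.
#' @param seed Random seed (defaults to \code{spec$seed}).
#' @return Data.frame: \code{sample_id}, \code{time} (days), \code{event}.
#' @export
simulate_survival <- function(spec = sim_spec(), scores, seed = spec$seed) {
  stopifnot(all(is.finite(scores)))
  set.seed(seed + 3L)
  n <- length(scores)
  t_event <- stats::rexp(n, rate = spec$baseline_hazard * exp(scores))
  if (spec$censor_frac > 0) {
    # (1 - exp(-x)) / x = censor_frac at the null score gives the upper bound
    f <- function(x) (1 - exp(-x)) / x - spec$censor_frac
    x <- stats::uniroot(f, c(1e-6, 1e3))$root
    t_cens <- stats::runif(n, 0, x / spec$baseline_hazard)
  } else {
    t_cens <- rep(Inf, n)
  }
  data.frame(
    sample_id = if (is.null(names(scores))) sprintf("s%04d", seq_len(n)) else names(scores),
    time = pmin(t_event, t_cens),
    event = t_event <= t_cens,
    stringsAsFactors = FALSE
  )
}

#' Simulate a 64-type cell-score table with planted group shifts
#'
#' Gamma-distributed nonnegative scores per cell type, with a
#' multiplicative shift planted for the chosen types in early-onset tumor
#' samples.
#'
#' @param spec A \code{\link{sim_spec}}.
#' @param meta Sample metadata (default: the paired design implied by the
#'   spec's cohort sizes).
#' @param seed Random seed (defaults to \code{spec$seed}).
#' @return List: \code{scores} (64 x samples), \code{meta}, \code{truth}
#'   (shifted types).
#' @export
simulate_cell_scores <- function(spec = sim_spec(), meta = NULL,
                                 seed = spec$seed) {
  set.seed(seed + 4L)
  if (is.null(meta)) {
    pats <- c(sprintf("e%02d", seq_len(spec$n_early)),
              sprintf("l%02d", seq_len(spec$n_late)))
    coh <- rep(c("early", "late"), c(spec$n_early, spec$n_late))
    meta <- data.frame(
      sample_id = paste(rep(pats, each = 2), c("tumor", "normal"), sep = "_"),
      patient_id = rep(pats, each = 2),
      tissue = rep(c("tumor", "normal"), length(pats)),
      cohort = rep(coh, each = 2), stringsAsFactors = FALSE)
  }
  types <- names(default_cell_grouping())
  type_scale <- exp(stats::runif(length(types), log(0.005), log(0.1)))
  m <- matrix(stats::rgamma(length(types) * nrow(meta),
                            shape = spec$cell_score_shape,
                            scale = rep(type_scale, nrow(meta))),
              nrow = length(types), dimnames = list(types, meta$sample_id))
  shift_cols <- meta$cohort == "early" & meta$tissue == "tumor"
  m[spec$cell_shift_types, shift_cols] <-
    m[spec$cell_shift_types, shift_cols] * spec$cell_shift_factor
  list(scores = m, meta = meta,
       truth = list(shifted_types = spec$cell_shift_types,
                    factor = spec$cell_shift_factor))
}
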