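# Dual-caller reconciliation of differential-splicing events.
#
# Each caller's table is filtered by its own significance rules, coordinate
# conventions are harmonized into a (chrom, 1-based coordinate) match key,
# and events are kept only when both callers report them. Cohort-unique
# sets are then plain set differences on match keys.

#' Filter event-level (junction-count) splice calls
#'
#' Keeps events with FDR < 0.05, |delta PSI| > 0.1 and a mean tumor
#' junction coverage (inclusion + skipping counts, averaged over tumor
#' replicates) above 20 reads. All comparisons strict. Events with missing
#' counts are dropped with a warning.
#'
#' @param events \code{splice_events} with \code{caller = "event_level"}.
#' @param config A \code{\link{pipeline_config}}.
#' @return The significant subset, with a \code{tumor_coverage} column.
#' @export
filter_rmats_events <- function(events, config = pipeline_config()) {
  stopifnot(all(events$caller == "event_level"))
  cov <- vapply(seq_len(nrow(events)), function(i) {
    ijc <- events$ijc_tumor[[i]]; sjc <- events$sjc_tumor[[i]]
    if (is.null(ijc) || is.null(sjc) || length(ijc) == 0L) return(NA_real_)
    mean(ijc + sjc)
  }, numeric(1))
  if (anyNA(cov) && nrow(events) > 0L) {
    warning(sum(is.na(cov)), " event(s) without junction counts dropped")
  }
  keep <- !is.na(cov) &
    events$significance < config$splice_fdr &
    abs(events$delta_psi) > config$splice_dpsi &
    cov > config$splice_coverage
  out <- events[keep, , drop = FALSE]
  out$tumor_coverage <- cov[keep]
  out
}

#' Filter node-level splice calls
#'
#' Keeps nodes with |delta PSI| > 0.1 and posterior probability > 0.7,
#' both strict.
#'
#' @param events \code{splice_events} with \code{caller = "node_level"}.
#' @param config A \code{\link{pipeline_config}}.
#' @return The significant subset.
#' @export
filter_whippet_events <- function(events, config = pipeline_config()) {
  stopifnot(all(events$caller == "node_level"))
  keep <- abs(events$delta_psi) > config$node_dpsi &
    events$significance > config$node_probability
  events[keep, , drop = FALSE]
}

#' Harmonized match keys for splice events
#'
#' The event-level caller reports 0-based starts, the node-level caller
#' 1-based starts, so one is added to the event-level start. Alternative 3'
#' splice-site events are described differently by the two callers and are
#' matched on the ending coordinate instead (which is identical under both
#' conventions). For mutually exclusive exons the first (5'-most)
#' alternative exon's start is used.
#'
#' @param events A \code{splice_events} table.
#' @param use_end Match on the ending coordinate (applied to node-level
#'   events when intersecting with A3SS partners).
#' @return Character vector of \code{"chrom:coordinate"} keys.
#' @export
harmonize_key <- function(events, use_end = FALSE) {
  coord <- ifelse(events$caller == "event_level",
                  ifelse(events$event_type == "A3SS" | use_end,
                         events$end,         # end is shared by both conventions
                         events$start + 1),  # 0-based -> 1-based start
                  if (use_end) events$end else events$start + 1)
  paste0(events$chrom, ":", fmt_coord(coord))
}

# Collapse duplicate keys within one caller, keeping the best-supported
# record (smallest FDR for the event-level caller, largest probability for
# the node-level caller).
collapse_duplicate_keys <- function(events, keys) {
  better <- if (all(events$caller == "node_level")) -events$significance else events$significance
  ord <- order(keys, better)
  events <- events[ord, , drop = FALSE]
  keys <- keys[ord]
  events[!duplicated(keys), , drop = FALSE]
}

#' Intersect significant events across callers
#'
#' One reconciled event per event-level record whose harmonized key is also
#' reported by at least one node-level record (A3SS events match on the end
#' coordinate, everything else on the 1-based start). Multiple node matches
#' collapse onto one reconciled event. Matching is by coordinate key only;
#' \code{strict_sign} additionally requires delta-PSI sign agreement.
#'
#' @param event_level_sig,node_level_sig Pre-filtered \code{splice_events}.
#' @param strict_sign Require the two callers to agree on the delta-PSI
#'   sign (default FALSE).
#' @return Data.frame of class \code{reconciled_events}: \code{match_key},
#'   the event-level statistics, and the matched node-level delta PSI and
#'   probability.
#' @export
match_events <- function(event_level_sig, node_level_sig, strict_sign = FALSE) {
  empty <- data.frame(match_key = character(0), event_id = character(0),
                      event_type = character(0), gene_id = character(0),
                      chrom = character(0), strand = character(0),
                      start = numeric(0), end = numeric(0),
                      delta_psi = numeric(0), fdr = numeric(0),
                      node_delta_psi = numeric(0), node_probability = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(event_level_sig) == 0L || nrow(node_level_sig) == 0L) {
    class(empty) <- c("reconciled_events", "data.frame")
    return(empty)
  }
  ev <- collapse_duplicate_keys(event_level_sig, harmonize_key(event_level_sig))
  ev_keys <- harmonize_key(ev)
  node_start <- harmonize_key(node_level_sig, use_end = FALSE)
  node_end <- harmonize_key(node_level_sig, use_end = TRUE)
  is_a3ss <- ev$event_type == "A3SS"
  hit <- integer(nrow(ev))
  hit[!is_a3ss] <- match(ev_keys[!is_a3ss], node_start)
  hit[is_a3ss] <- match(ev_keys[is_a3ss], node_end)
  ok <- !is.na(hit)
  if (strict_sign) {
    ok <- ok & sign(ev$delta_psi) ==
      sign(node_level_sig$delta_psi[replace(hit, is.na(hit), 1L)])
  }
  out <- data.frame(
    match_key = ev_keys[ok],
    event_id = ev$event_id[ok],
    event_type = ev$event_type[ok],
    gene_id = ev$gene_id[ok],
    chrom = ev$chrom[ok],
    strand = ev$strand[ok],
    start = ev$start[ok],
    end = ev$end[ok],
    delta_psi = ev$delta_psi[ok],
    fdr = ev$significance[ok],
    node_delta_psi = node_level_sig$delta_psi[hit[ok]],
    node_probability = node_level_sig$significance[hit[ok]],
    stringsAsFactors = FALSE
  )
  if ("upstream_start" %in% names(ev)) {
    for (col in c("upstream_start", "upstream_end",
                  "downstream_start", "downstream_end", "start2", "end2")) {
      out[[col]] <- ev[[col]][ok]
    }
  }
  class(out) <- c("reconciled_events", "data.frame")
  out
}

#' Events unique to the early-onset cohort
#'
#' The early cohort's reconciled events minus any whose match key also
#' appears among the later-onset cohort's reconciled events.
#'
#' @param early,late \code{reconciled_events} from \code{\link{match_events}}.
#' @return The early-unique subset of \code{early}.
#' @export
cohort_unique_events <- function(early, late) {
  early[!(early$match_key %in% late$match_key), , drop = FALSE]
}

#' Cross-caller concordance per event type
#'
#' Fraction of significant event-level events whose harmonized key is also
#' reported (at any significance) by the node-level caller, per event type.
#' Types with no events are omitted.
#'
#' @param event_level_sig Filtered event-level \code{splice_events}.
#' @param node_level_all Unfiltered node-level \code{splice_events}.
#' @return Named numeric vector of fractions, one per event type present.
#' @export
caller_concordance_rate <- function(event_level_sig, node_level_all) {
  if (nrow(event_level_sig) == 0L) return(stats::setNames(numeric(0), character(0)))
  ev_keys <- harmonize_key(event_level_sig)
  node_start <- harmonize_key(node_level_all, use_end = FALSE)
  node_end <- harmonize_key(node_level_all, use_end = TRUE)
  matched <- ifelse(event_level_sig$event_type == "A3SS",
                    ev_keys %in% node_end,
                    ev_keys %in% node_start)
  tapply(matched, event_level_sig$event_type, mean)[
    unique(event_level_sig$event_type)]
}
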