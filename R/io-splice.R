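# Splice-event container and the two caller dialects.
#
# Internal convention: every genomic interval is 0-based half-open. The
# event-level (junction-count) dialect stores 0-based starts natively; the
# node-level dialect stores 1-based inclusive coordinates and is converted
# at the boundary. 1-based views reappear only in match keys and on write.

RMATS_COORD_COLS <- list(
  SE   = c("exonStart_0base", "exonEnd",
           "upstreamES", "upstreamEE", "downstreamES", "downstreamEE"),
  MXE  = c("1stExonStart_0base", "1stExonEnd", "2ndExonStart_0base", "2ndExonEnd",
           "upstreamES", "upstreamEE", "downstreamES", "downstreamEE"),
  A5SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  A3SS = c("longExonStart_0base", "longExonEnd", "shortES", "shortEE",
           "flankingES", "flankingEE"),
  RI   = c("riExonStart_0base", "riExonEnd",
           "upstreamES", "upstreamEE", "downstreamES", "downstreamEE")
)

SPLICE_EVENT_TYPES <- names(RMATS_COORD_COLS)

#' Construct and validate a splice-event table
#'
#' @param df Data.frame with one row per alternative-splicing event. Required
#'   columns: \code{event_id}, \code{caller} (\code{"event_level"} or
#'   \code{"node_level"}), \code{event_type}, \code{gene_id}, \code{chrom},
#'   \code{strand}, \code{start}, \code{end} (variable region, 0-based
#'   half-open), \code{delta_psi} (tumor minus normal), \code{significance}
#'   (FDR for the event-level caller, posterior probability for the
#'   node-level caller). Optional: \code{start2}/\code{end2} (second
#'   alternative exon for mutually exclusive exon events), flanking exon
#'   intervals, and list-columns \code{ijc_tumor}/\code{sjc_tumor} of
#'   per-replicate junction counts.
#' @return The data.frame with class \code{splice_events}.
#' @export
splice_events <- function(df) {
  need <- c("event_id", "caller", "event_type", "gene_id", "chrom", "strand",
            "start", "end", "delta_psi", "significance")
  stopifnot(all(need %in% names(df)))
  opt <- c("start2", "end2", "upstream_start", "upstream_end",
           "downstream_start", "downstream_end")
  for (col in opt) if (!col %in% names(df)) df[[col]] <- NA_real_
  if (!"ijc_tumor" %in% names(df)) df$ijc_tumor <- I(rep(list(NULL), nrow(df)))
  if (!"sjc_tumor" %in% names(df)) df$sjc_tumor <- I(rep(list(NULL), nrow(df)))
  if (nrow(df) > 0L) {
    stopifnot(all(df$caller %in% c("event_level", "node_level")))
    if (any(df$start >= df$end)) stop("event with start >= end")
    if (any(abs(df$delta_psi) > 1, na.rm = TRUE)) stop("|delta PSI| > 1")
    if (any(df$significance < 0 | df$significance > 1, na.rm = TRUE)) {
      stop("significance outside [0,1]")
    }
  }
  class(df) <- c("splice_events", "data.frame")
  df
}

parse_count_vector <- function(x) {
  lapply(strsplit(as.character(x), ",", fixed = TRUE),
         function(v) as.integer(v))
}

#' Read an event-level (junction-count dialect) differential-splicing table
#'
#' Parses one event type's results file from the junction-count caller.
#' Exon coordinates in this dialect are 0-based starts with exclusive ends,
#' matching the internal convention, and per-replicate inclusion/skipping
#' junction counts are comma-separated. The inclusion-level difference is
#' PSI(sample 1) - PSI(sample 2); \code{sample_order} states which group is
#' which so that the stored \code{delta_psi} is always tumor minus normal.
#'
#' @param path Results file for one event type.
#' @param event_type One of \code{"SE"}, \code{"A5SS"}, \code{"A3SS"},
#'   \code{"MXE"}, \code{"RI"}.
#' @param sample_order Character vector naming sample 1 and sample 2;
#'   default \code{c("tumor", "normal")}.
#' @return A \code{splice_events} table with \code{caller = "event_level"}.
#' @export
read_rmats_table <- function(path, event_type, sample_order = c("tumor", "normal")) {
  if (!event_type %in% SPLICE_EVENT_TYPES) {
    stop("unknown event type: ", event_type)
  }
  stopifnot(setequal(sample_order, c("tumor", "normal")))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ID", "GeneID", "chr", "strand", RMATS_COORD_COLS[[event_type]],
            "IJC_SAMPLE_1", "SJC_SAMPLE_1", "IJC_SAMPLE_2", "SJC_SAMPLE_2",
            "IncLevelDifference", "FDR")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("junction-count table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  tumor_is_1 <- sample_order[1] == "tumor"
  ijc_t <- parse_count_vector(if (tumor_is_1) raw$IJC_SAMPLE_1 else raw$IJC_SAMPLE_2)
  sjc_t <- parse_count_vector(if (tumor_is_1) raw$SJC_SAMPLE_1 else raw$SJC_SAMPLE_2)
  len_bad <- which(lengths(ijc_t) != lengths(sjc_t))
  if (length(len_bad) > 0L) {
    stop("IJC/SJC replicate count length mismatch at row(s): ",
         paste(len_bad, collapse = ", "))
  }
  cc <- RMATS_COORD_COLS[[event_type]]
  var_start <- raw[[cc[1]]]
  var_end <- raw[[cc[2]]]
  if (event_type == "MXE") {
    start2 <- raw[["2ndExonStart_0base"]]; end2 <- raw[["2ndExonEnd"]]
    up <- cbind(raw$upstreamES, raw$upstreamEE)
    dn <- cbind(raw$downstreamES, raw$downstreamEE)
  } else if (event_type %in% c("A5SS", "A3SS")) {
    start2 <- NA_real_; end2 <- NA_real_
    up <- cbind(raw$flankingES, raw$flankingEE)
    dn <- cbind(NA_real_, NA_real_)[rep(1L, nrow(raw)), , drop = FALSE]
  } else {
    start2 <- NA_real_; end2 <- NA_real_
    up <- cbind(raw$upstreamES, raw$upstreamEE)
    dn <- cbind(raw$downstreamES, raw$downstreamEE)
  }
  dpsi <- raw$IncLevelDifference
  if (!tumor_is_1) dpsi <- -dpsi
  df <- data.frame(
    event_id = paste0(event_type, "_", raw$ID),
    caller = "event_level",
    event_type = event_type,
    gene_id = as.character(raw$GeneID),
    chrom = as.character(raw$chr),
    strand = as.character(raw$strand),
    start = as.numeric(var_start),
    end = as.numeric(var_end),
    start2 = as.numeric(start2),
    end2 = as.numeric(end2),
    upstream_start = as.numeric(up[, 1]),
    upstream_end = as.numeric(up[, 2]),
    downstream_start = as.numeric(dn[, 1]),
    downstream_end = as.numeric(dn[, 2]),
    delta_psi = as.numeric(dpsi),
    significance = as.numeric(raw$FDR),
    stringsAsFactors = FALSE
  )
  df$ijc_tumor <- I(ijc_t)
  df$sjc_tumor <- I(sjc_t)
  splice_events(df)
}

#' Write an event-level splice table in the junction-count dialect
#'
#' Inverse of \code{\link{read_rmats_table}} for a single event type, with
#' tumor as sample 1.
#'
#' @param events A \code{splice_events} table, all rows of one event type.
#' @param path Output path.
#' @export
write_rmats_table <- function(events, path) {
  stopifnot(nrow(events) == 0L || length(unique(events$event_type)) == 1L)
  et <- if (nrow(events) > 0L) events$event_type[1] else "SE"
  cc <- RMATS_COORD_COLS[[et]]
  join <- function(lst) vapply(lst, function(v) paste(v, collapse = ","), character(1))
  out <- data.frame(ID = sub("^[A-Z0-9]+_", "", events$event_id),
                    GeneID = events$gene_id,
                    chr = events$chrom, strand = events$strand,
                    check.names = FALSE, stringsAsFactors = FALSE)
  out[[cc[1]]] <- fmt_coord(events$start)
  out[[cc[2]]] <- fmt_coord(events$end)
  if (et == "MXE") {
    out[["2ndExonStart_0base"]] <- fmt_coord(events$start2)
    out[["2ndExonEnd"]] <- fmt_coord(events$end2)
  }
  if (et %in% c("A5SS", "A3SS")) {
    out$flankingES <- fmt_coord(events$upstream_start)
    out$flankingEE <- fmt_coord(events$upstream_end)
    # dialect keeps the short-form columns; reuse the variable region
    out$shortES <- fmt_coord(events$start)
    out$shortEE <- fmt_coord(events$end)
  } else {
    out$upstreamES <- fmt_coord(events$upstream_start)
    out$upstreamEE <- fmt_coord(events$upstream_end)
    out$downstreamES <- fmt_coord(events$downstream_start)
    out$downstreamEE <- fmt_coord(events$downstream_end)
  }
  out$IJC_SAMPLE_1 <- join(events$ijc_tumor)
  out$SJC_SAMPLE_1 <- join(events$sjc_tumor)
  out$IJC_SAMPLE_2 <- join(events$ijc_tumor)
  out$SJC_SAMPLE_2 <- join(events$sjc_tumor)
  out$IncLevelDifference <- events$delta_psi
  out$FDR <- events$significance
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

fmt_coord <- function(x) ifelse(is.na(x), NA, format(x, scientific = FALSE, trim = TRUE))

#' Read a node-level differential-splicing table
#'
#' Parses the node-level caller's diff dialect: columns \code{Gene},
#' \code{Node}, \code{Coord} (\code{chrom:start-end}, 1-based inclusive),
#' \code{Strand}, \code{Type}, \code{Psi_A}, \code{Psi_B}, \code{DeltaPsi},
#' \code{Probability}. Coordinates are converted to the internal 0-based
#' half-open convention on read; DeltaPsi is Psi_A - Psi_B and
#' \code{sample_order} states which group is A so the stored
#' \code{delta_psi} is tumor minus normal.
#'
#' @param path Diff table path.
#' @param sample_order Character vector naming groups A and B; default
#'   \code{c("tumor", "normal")}.
#' @return A \code{splice_events} table with \code{caller = "node_level"}.
#' @export
read_whippet_diff <- function(path, sample_order = c("tumor", "normal")) {
  stopifnot(setequal(sample_order, c("tumor", "normal")))
  raw <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("Gene", "Node", "Coord", "Strand", "Type", "Psi_A", "Psi_B",
            "DeltaPsi", "Probability")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols) > 0L) {
    stop("node-level table lacks column(s): ", paste(missing_cols, collapse = ", "))
  }
  m <- regmatches(raw$Coord, regexec("^([^:]+):([0-9]+)-([0-9]+)$", raw$Coord))
  bad <- which(lengths(m) != 4L)
  if (length(bad) > 0L) {
    stop("unparseable Coord at row(s): ", paste(bad, collapse = ", "))
  }
  chrom <- vapply(m, `[`, character(1), 2L)
  start1 <- as.numeric(vapply(m, `[`, character(1), 3L))
  end1 <- as.numeric(vapply(m, `[`, character(1), 4L))
  if (any(raw$Probability < 0 | raw$Probability > 1)) {
    stop("Probability outside [0,1]")
  }
  dpsi <- raw$DeltaPsi
  if (sample_order[1] != "tumor") dpsi <- -dpsi
  df <- data.frame(
    event_id = paste0(raw$Gene, ":", raw$Node),
    caller = "node_level",
    event_type = as.character(raw$Type),
    gene_id = as.character(raw$Gene),
    chrom = chrom,
    strand = as.character(raw$Strand),
    start = start1 - 1,   # 1-based inclusive -> 0-based half-open
    end = end1,
    delta_psi = as.numeric(dpsi),
    significance = as.numeric(raw$Probability),
    stringsAsFactors = FALSE
  )
  splice_events(df)
}

#' Write a node-level splice table in its native dialect
#'
#' Inverse of \code{\link{read_whippet_diff}}, with tumor as group A and
#' coordinates rendered 1-based inclusive.
#'
#' @param events A \code{splice_events} table with \code{caller = "node_level"}.
#' @param path Output path.
#' @export
write_whippet_diff <- function(events, path) {
  psi_b <- pmin(pmax(0.5 - events$delta_psi / 2, 0), 1)
  out <- data.frame(
    Gene = events$gene_id,
    Node = sub("^.*:", "", events$event_id),
    Coord = paste0(events$chrom, ":", fmt_coord(events$start + 1), "-",
                   fmt_coord(events$end)),
    Strand = events$strand,
    Type = events$event_type,
    Psi_A = psi_b + events$delta_psi,
    Psi_B = psi_b,
    DeltaPsi = events$delta_psi,
    Probability = events$significance,
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
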