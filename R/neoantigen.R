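# Junction-spanning neoantigen candidate construction.
#
# Tumor-enriched splice events become BED12 records (variable region plus
# 27-nt flanks from the adjacent exons), strand-aware spliced sequences,
# three-frame translations with stop-containing frames discarded whole,
# and 9-mer windows ranked through a pluggable MHC class I predictor.

GENETIC_CODE_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L", CTA = "L",
  CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M", GTT = "V", GTC = "V",
  GTA = "V", GTG = "V", TCT = "S", TCC = "S", TCA = "S", TCG = "S", CCT = "P",
  CCC = "P", CCA = "P", CCG = "P", ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*",
  TAG = "*", CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E", TGT = "C",
  TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R", GGT = "G", GGC = "G", GGA = "G",
  GGG = "G"
)

#' Read a genome FASTA
#'
#' @param path FASTA path.
#' @return Named character vector of uppercase chromosome sequences.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  out <- toupper(as.character(seqs))
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a genome FASTA
#'
#' @param genome Named character vector of sequences.
#' @param path Output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path)
  invisible(path)
}

#' Select tumor-enriched splice events
#'
#' Keeps events whose variable region is more included in tumors than in
#' normals (delta PSI strictly positive).
#'
#' @param events \code{reconciled_events} or \code{splice_events} with a
#'   \code{delta_psi} column.
#' @return The tumor-enriched subset.
#' @export
select_tumor_enriched <- function(events) {
  events[events$delta_psi > 0, , drop = FALSE]
}

#' Build BED12 records for splice events with junction flanks
#'
#' For each event: three blocks — the last \code{flank_nt} bases of the
#' upstream exon, the full variable region, and the first \code{flank_nt}
#' bases of the downstream exon (flanks clamped to the exon length with a
#' warning). 27 nt (9 codons) makes junction-spanning 9-mers possible after
#' translation. Events without flanking exon coordinates yield a
#' single-block record with a warning; mutually exclusive exon events emit
#' one record per alternative exon.
#'
#' @param events \code{splice_events} or \code{reconciled_events} rows with
#'   variable-region and flanking-exon intervals (0-based half-open).
#' @param flank_nt Flank length in nucleotides (default 27).
#' @return A \code{bed12} object, one or two records per event, named by
#'   match key (or event id) with the frame-relevant suffix for second exons.
#' @export
build_bed12_blocks <- function(events, flank_nt = 27L) {
  stopifnot(flank_nt >= 0)
  rows <- list()
  nm <- if ("match_key" %in% names(events)) events$match_key else events$event_id
  for (i in seq_len(nrow(events))) {
    exons <- list(c(events$start[i], events$end[i]))
    names(exons) <- nm[i]
    if (!is.na(events$start2[i])) {
      exons[[paste0(nm[i], "|exon2")]] <- c(events$start2[i], events$end2[i])
    }
    for (j in seq_along(exons)) {
      var <- exons[[j]]
      blocks <- make_flanked_blocks(
        var, flank_nt,
        c(events$upstream_start[i], events$upstream_end[i]),
        c(events$downstream_start[i], events$downstream_end[i])
      )
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = events$chrom[i],
        chromStart = blocks$start, chromEnd = blocks$end,
        name = names(exons)[j], score = 0, strand = events$strand[i],
        thickStart = blocks$start, thickEnd = blocks$end, itemRgb = "0",
        blockCount = length(blocks$sizes),
        blockSizes = paste(fmt_coord(blocks$sizes), collapse = ","),
        blockStarts = paste(fmt_coord(blocks$rel_starts), collapse = ","),
        stringsAsFactors = FALSE
      )
    }
  }
  bed12(do.call(rbind, rows))
}

make_flanked_blocks <- function(var, flank_nt, up, dn) {
  have_up <- !anyNA(up)
  have_dn <- !anyNA(dn)
  if (flank_nt == 0L || (!have_up && !have_dn)) {
    if (flank_nt > 0L) warning("missing flanking exon(s); single-block record")
    return(list(start = var[1], end = var[2], sizes = var[2] - var[1],
                rel_starts = 0))
  }
  starts <- var[1]; ends <- var[2]
  if (have_up) {
    fl <- min(flank_nt, up[2] - up[1])
    if (fl < flank_nt) warning("upstream exon shorter than flank; clamped")
    starts <- c(max(up[2] - fl, up[1]), starts)
    ends <- c(up[2], ends)
  } else {
    warning("missing upstream flanking exon")
  }
  if (have_dn) {
    fl <- min(flank_nt, dn[2] - dn[1])
    if (fl < flank_nt) warning("downstream exon shorter than flank; clamped")
    starts <- c(starts, dn[1])
    ends <- c(ends, min(dn[1] + fl, dn[2]))
  } else {
    warning("missing downstream flanking exon")
  }
  list(start = starts[1], end = ends[length(ends)],
       sizes = ends - starts, rel_starts = starts - starts[1])
}

#' Extract the spliced sequence of a BED12 record
#'
#' Concatenates the block sequences in genomic order (introns excluded by
#' construction) and reverse-complements the concatenation for minus-strand
#' records. Output is uppercase; non-ACGT bases pass through.
#'
#' @param genome Named character vector from \code{\link{read_genome_fasta}}.
#' @param record One \code{bed12} row.
#' @return Nucleotide string.
#' @export
extract_spliced_sequence <- function(genome, record) {
  if (!record$chrom %in% names(genome)) stop("chromosome absent: ", record$chrom)
  chrom_seq <- genome[[record$chrom]]
  sizes <- as.numeric(strsplit(record$blockSizes, ",")[[1]])
  starts <- record$chromStart + as.numeric(strsplit(record$blockStarts, ",")[[1]])
  if (any(starts + sizes > nchar(chrom_seq)) || any(starts < 0)) {
    stop("block outside chromosome bounds for ", record$name)
  }
  seq <- paste(substring(chrom_seq, starts + 1, starts + sizes), collapse = "")
  seq <- toupper(seq)
  if (record$strand == "-") {
    seq <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
  }
  seq
}

#' Translate a nucleotide sequence in the three forward frames
#'
#' Standard genetic code; frame f starts at offset f - 1; trailing partial
#' codons are dropped; stop codons render as \code{"*"}; codons containing
#' non-ACGT bases render as \code{"X"}.
#'
#' @param seq Nucleotide string.
#' @return Character vector of three peptides (empty strings, with a
#'   warning, when the sequence is shorter than 3 nt).
#' @export
translate_three_frames <- function(seq) {
  seq <- toupper(seq)
  if (nchar(seq) < 3L) {
    warning("sequence shorter than one codon")
    return(c(frame1 = "", frame2 = "", frame3 = ""))
  }
  out <- vapply(1:3, function(f) {
    n_codon <- (nchar(seq) - f + 1) %/% 3
    if (n_codon < 1L) return("")
    pos <- f + 3 * (seq_len(n_codon) - 1)
    codons <- substring(seq, pos, pos + 2)
    aa <- GENETIC_CODE_TABLE[codons]
    aa[is.na(aa)] <- "X"
    paste(aa, collapse = "")
  }, character(1))
  names(out) <- paste0("frame", 1:3)
  out
}

#' Build peptide candidates from BED12 records and a genome
#'
#' Extracts each record's spliced sequence and translates it in three
#' frames, producing one candidate row per (record, frame).
#'
#' @param genome Named character vector of chromosome sequences.
#' @param records A \code{bed12} object.
#' @return Data.frame: \code{match_key}, \code{frame}, \code{peptide},
#'   \code{contains_stop}.
#' @export
build_peptide_candidates <- function(genome, records) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    seq <- extract_spliced_sequence(genome, records[i, , drop = FALSE])
    pep <- translate_three_frames(seq)
    data.frame(match_key = records$name[i], frame = 1:3, peptide = unname(pep),
               contains_stop = grepl("*", pep, fixed = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Remove peptides containing stop codons
#'
#' Any frame whose translation contains a stop is discarded whole.
#'
#' @param candidates Data.frame with a \code{peptide} column.
#' @return The stop-free subset, order preserved (a warning if empty).
#' @export
drop_stop_peptides <- function(candidates) {
  out <- candidates[!grepl("*", candidates$peptide, fixed = TRUE), , drop = FALSE]
  if (nrow(out) == 0L && nrow(candidates) > 0L) {
    warning("all peptides contained stop codons")
  }
  out
}

#' Rank 9-mer windows through a binding predictor
#'
#' Enumerates every length-9 window of each candidate peptide, queries the
#' predictor for a percent rank per (window, allele), and summarizes each
#' candidate by its best (minimum) rank per allele. A candidate is a strong
#' binder when its best rank over all alleles is at or below
#' \code{strong_rank} (default 0.5, i.e. the top 0.5% of the predictor's
#' reference distribution). Peptides shorter than 9 residues are dropped
#' with a warning.
#'
#' @param candidates Data.frame with \code{match_key}, \code{frame},
#'   \code{peptide}.
#' @param predictor Function \code{(peptides, allele) -> numeric percent
#'   ranks}; see \code{\link{mock_rank_predictor}}.
#' @param alleles HLA allele names (default the four common HLA-A types).
#' @param strong_rank Strong-binder cutoff (default 0.5).
#' @return \code{candidates} with one \code{rank_<allele>} column per
#'   allele, \code{min_rank} and \code{strong_binder}.
#' @export
rank_9mers <- function(candidates, predictor,
                       alleles = pipeline_config()$hla_alleles,
                       strong_rank = 0.5) {
  short <- nchar(candidates$peptide) < 9L
  if (any(short)) {
    warning(sum(short), " peptide(s) shorter than 9 residues dropped")
    candidates <- candidates[!short, , drop = FALSE]
  }
  if (nrow(candidates) == 0L) {
    candidates$min_rank <- numeric(0)
    candidates$strong_binder <- logical(0)
    return(candidates)
  }
  windows <- lapply(candidates$peptide, function(p) {
    substring(p, seq_len(nchar(p) - 8L), seq_len(nchar(p) - 8L) + 8L)
  })
  for (al in alleles) {
    ranks <- vapply(windows, function(w) min(predictor(w, al)), numeric(1))
    candidates[[paste0("rank_", gsub("[*:]", "", al))]] <- ranks
  }
  rank_cols <- grep("^rank_", names(candidates), value = TRUE)
  candidates$min_rank <- do.call(pmin, candidates[rank_cols])
  candidates$strong_binder <- candidates$min_rank <= strong_rank
  candidates
}

#' Deterministic mock binding predictor
#'
#' Hash-based stand-in for a neural MHC binding predictor, for tests and
#' examples: every (9-mer, allele) pair maps reproducibly to a percent rank
#' in (0.5, 100]; windows listed in \code{strong} instead receive rank 0.1.
#' It models nothing biological.
#'
#' @param strong Character vector of 9-mers to plant as strong binders.
#' @return Function \code{(peptides, allele) -> ranks}.
#' @export
mock_rank_predictor <- function(strong = character(0)) {
  hash01 <- function(s) {
    vapply(s, function(x) {
      h <- 7
      for (code in utf8ToInt(x)) h <- (h * 31 + code) %% 1000003
      h / 1000003
    }, numeric(1), USE.NAMES = FALSE)
  }
  function(peptides, allele) {
    r <- 0.5 + 99.5 * hash01(paste0(allele, "|", peptides))
    r[peptides %in% strong] <- 0.1
    r
  }
}

#' Write peptides as FASTA for an external binding predictor
#'
#' @param candidates Data.frame with \code{match_key}, \code{frame},
#'   \code{peptide}.
#' @param path Output path; headers are \code{match_key|frame<f>}.
#' @export
write_peptide_fasta <- function(candidates, path) {
  lines <- as.vector(rbind(
    paste0(">", candidates$match_key, "|frame", candidates$frame),
    candidates$peptide
  ))
  writeLines(lines, path)
  invisible(path)
}
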