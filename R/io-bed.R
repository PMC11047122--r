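# BED12 records: 0-based half-open, block arithmetic validated on
# construction so malformed records never reach disk.

#' Construct a validated BED12 record set
#'
#' @param df Data.frame with columns \code{chrom}, \code{chromStart},
#'   \code{chromEnd}, \code{name}, \code{score}, \code{strand},
#'   \code{thickStart}, \code{thickEnd}, \code{itemRgb}, \code{blockCount},
#'   \code{blockSizes}, \code{blockStarts} (the last two comma-joined
#'   strings). Blocks must be sorted, non-overlapping, start at relative 0
#'   and end at \code{chromEnd - chromStart}.
#' @return The data.frame with class \code{bed12}.
#' @export
bed12 <- function(df) {
  need <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
            "thickStart", "thickEnd", "itemRgb", "blockCount", "blockSizes",
            "blockStarts")
  stopifnot(all(need %in% names(df)))
  for (i in seq_len(nrow(df))) {
    sizes <- as.numeric(strsplit(df$blockSizes[i], ",")[[1]])
    starts <- as.numeric(strsplit(df$blockStarts[i], ",")[[1]])
    n <- df$blockCount[i]
    span <- df$chromEnd[i] - df$chromStart[i]
    if (length(sizes) != n || length(starts) != n) {
      stop("record ", df$name[i], ": blockCount disagrees with block lists")
    }
    if (starts[1] != 0) stop("record ", df$name[i], ": first blockStart must be 0")
    if (any(sizes <= 0)) stop("record ", df$name[i], ": nonpositive block size")
    if (n > 1 && any(starts[-1] < (starts + sizes)[-n])) {
      stop("record ", df$name[i], ": blocks overlap or are unsorted")
    }
    if (starts[n] + sizes[n] != span) {
      stop("record ", df$name[i], ": last block must end at chromEnd - chromStart")
    }
  }
  class(df) <- c("bed12", "data.frame")
  df
}

#' Write BED12 records
#'
#' @param records A \code{bed12} object (validated block arithmetic).
#' @param path Output path; 12 tab-separated columns, no header.
#' @export
write_bed12 <- function(records, path) {
  records <- bed12(as.data.frame(records))  # re-validate before writing
  cols <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
            "thickStart", "thickEnd", "itemRgb", "blockCount", "blockSizes",
            "blockStarts")
  utils::write.table(records[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED12 file
#'
#' @param path BED12 path (no header).
#' @return A \code{bed12} data.frame.
#' @export
read_bed12 <- function(path) {
  raw <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) != 12L) stop("expected 12 columns, found ", ncol(raw))
  names(raw) <- c("chrom", "chromStart", "chromEnd", "name", "score", "strand",
                  "thickStart", "thickEnd", "itemRgb", "blockCount",
                  "blockSizes", "blockStarts")
  raw$blockSizes <- sub(",$", "", as.character(raw$blockSizes))
  raw$blockStarts <- sub(",$", "", as.character(raw$blockStarts))
  bed12(raw)
}
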