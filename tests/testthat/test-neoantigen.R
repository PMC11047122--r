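test_that("tumor-enriched selection keeps strictly positive delta PSI", {
  ev <- rbind(one_event(event_id = "pos", delta_psi = 0.2),
              one_event(event_id = "neg", delta_psi = -0.2),
              one_event(event_id = "zero", delta_psi = 0))
  kept <- select_tumor_enriched(splice_events(ev))
  expect_equal(kept$event_id, "pos")
})

test_that("BED12 blocks are flank + variable region + flank with exact arithmetic", {
  ev <- one_event(start = 1000, end = 1100)
  ev$upstream_start <- 700; ev$upstream_end <- 900
  ev$downstream_start <- 1200; ev$downstream_end <- 1400
  b <- build_bed12_blocks(splice_events(as.data.frame(ev)), flank_nt = 27)
  expect_equal(b$chromStart, 873)
  expect_equal(b$chromEnd, 1227)
  expect_equal(b$blockSizes, "27,100,27")
  expect_equal(b$blockStarts, "0,127,327")
  sizes <- as.numeric(strsplit(b$blockSizes, ",")[[1]])
  expect_equal(sum(sizes), 154)   # total spliced length
})

test_that("flank length zero and missing or short exons degrade gracefully", {
  ev <- one_event(start = 1000, end = 1100)
  ev$upstream_start <- 700; ev$upstream_end <- 900
  ev$downstream_start <- 1200; ev$downstream_end <- 1400
  b0 <- build_bed12_blocks(splice_events(as.data.frame(ev)), flank_nt = 0)
  expect_equal(b0$blockCount, 1L)
  expect_equal(c(b0$chromStart, b0$chromEnd), c(1000, 1100))
  # upstream exon of length 10: clamped with a warning
  ev$upstream_start <- 890
  expect_warning(
    bc <- build_bed12_blocks(splice_events(as.data.frame(ev)), flank_nt = 27),
    "clamped")
  expect_equal(strsplit(bc$blockSizes, ",")[[1]][1], "10")
  # no flanking exons at all: single-block record
  ev2 <- one_event(start = 1000, end = 1100)
  expect_warning(
    b1 <- build_bed12_blocks(splice_events(as.data.frame(ev2)), flank_nt = 27),
    "missing")
  expect_equal(b1$blockCount, 1L)
})

test_that("mutually-exclusive events emit one record per alternative exon", {
  ev <- one_event(start = 1000, end = 1100, event_type = "MXE")
  ev$start2 <- 1500; ev$end2 <- 1600
  ev$upstream_start <- 700; ev$upstream_end <- 900
  ev$downstream_start <- 1800; ev$downstream_end <- 2000
  b <- build_bed12_blocks(splice_events(as.data.frame(ev)), flank_nt = 27)
  expect_equal(nrow(b), 2L)
  expect_equal(b$name, c("ev1", "ev1|exon2"))
})

test_that("spliced sequence extraction concatenates blocks and honors strand", {
  genome <- c(chr1 = "NNACGTTTNN")
  rec <- bed12(data.frame(chrom = "chr1", chromStart = 2, chromEnd = 8,
                          name = "x", score = 0, strand = "+", thickStart = 2,
                          thickEnd = 8, itemRgb = "0", blockCount = 2L,
                          blockSizes = "3,3", blockStarts = "0,3",
                          stringsAsFactors = FALSE))
  expect_equal(extract_spliced_sequence(genome, rec), "ACGTTT")
  rec$strand <- "-"
  expect_equal(extract_spliced_sequence(genome, rec), "AAACGT")
  # N passthrough and bounds checking
  rec_n <- rec; rec_n$strand <- "+"; rec_n$chromStart <- 0; rec_n$chromEnd <- 6
  expect_equal(extract_spliced_sequence(genome, rec_n), "NNACGT")
  rec_oob <- rec; rec_oob$chromStart <- 6; rec_oob$chromEnd <- 12
  expect_error(extract_spliced_sequence(genome, rec_oob), "bounds")
  expect_error(extract_spliced_sequence(genome,
               transform(rec, chrom = "chr9")), "chr9")
})

test_that("three-frame translation follows the standard code and drops partials", {
  expect_equal(unname(translate_three_frames("ATGGCC")["frame1"]), "MA")
  expect_equal(unname(translate_three_frames("ATGGCCTAA")["frame1"]), "MA*")
  fr <- translate_three_frames("ATGGCCA")
  expect_equal(unname(fr), c("MA", "WP", "G"))  # trailing partials dropped
  expect_warning(out <- translate_three_frames("AT"), "shorter")
  expect_equal(unname(out), c("", "", ""))
})

test_that("translation matches the reference implementation on fuzzed sequences", {
  set.seed(101)
  for (i in 1:50) {
    len <- sample(9:90, 1)
    seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
    mine <- translate_three_frames(seq)
    for (f in 1:3) {
      sub <- substr(seq, f, f + ((len - f + 1) %/% 3) * 3 - 1)
      if (nchar(sub) < 3) next
      ref <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                                no.init.codon = TRUE))
      expect_equal(unname(mine[f]), ref)
    }
  }
})

test_that("stop-containing frames are discarded whole, order preserved", {
  cand <- data.frame(match_key = c("k1", "k2", "k3"), frame = 1:3,
                     peptide = c("MA*", "MAW", "GHK"), stringsAsFactors = FALSE)
  out <- drop_stop_peptides(cand)
  expect_equal(out$peptide, c("MAW", "GHK"))
  expect_warning(drop_stop_peptides(cand[1, ]), "all peptides")
})

test_that("9-mer enumeration counts windows and flags planted strong binders", {
  cand <- data.frame(match_key = c("k1", "k2", "k3"), frame = 1L,
                     peptide = c(strrep("A", 9),
                                 "ACDEFGHIKLMNPQRSTVWY",  # 20-mer -> 12 windows
                                 "SHORT"),
                     stringsAsFactors = FALSE)
  planted <- substr(cand$peptide[2], 5, 13)
  expect_warning(
    ranked <- rank_9mers(cand, mock_rank_predictor(strong = planted)),
    "shorter than 9")
  expect_equal(nrow(ranked), 2L)
  expect_true(ranked$strong_binder[ranked$match_key == "k2"])
  expect_false(ranked$strong_binder[ranked$match_key == "k1"])
  expect_lte(ranked$min_rank[ranked$match_key == "k2"], 0.5)
  # window count arithmetic: len 20 -> 12 windows; len 9 -> 1 window
  expect_equal(nchar(cand$peptide[2]) - 8L, 12L)
  # mock predictor is deterministic
  pred <- mock_rank_predictor()
  expect_identical(pred(c("AAAAAAAAA"), "HLA-A*02:01"),
                   pred(c("AAAAAAAAA"), "HLA-A*02:01"))
})

test_that("pipeline peptides equal the generator's independent oracle on both strands", {
  spec <- small_spec(n_peptide_events = 50L)
  gen <- simulate_genome_with_events(spec, seed = 103)
  bed <- build_bed12_blocks(gen$events, spec$flank_nt)
  cand <- build_peptide_candidates(gen$genome, bed)
  oracle <- gen$peptides
  merged <- merge(cand, oracle, by.x = c("match_key", "frame"),
                  by.y = c("name", "frame"))
  expect_equal(nrow(merged), nrow(oracle))
  expect_identical(merged$peptide.x, merged$peptide.y)
  expect_true(any(gen$events$strand == "-") && any(gen$events$strand == "+"))
})

test_that("strand symmetry: flipping genome and strand reproduces the sequence", {
  set.seed(107)
  len <- 400
  fwd <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  rc <- function(s) paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
                          collapse = "")
  genome <- c(chr1 = fwd)
  genome_rc <- c(chr1 = rc(fwd))
  rec <- bed12(data.frame(chrom = "chr1", chromStart = 50, chromEnd = 200,
                          name = "x", score = 0, strand = "+", thickStart = 50,
                          thickEnd = 200, itemRgb = "0", blockCount = 2L,
                          blockSizes = "60,40", blockStarts = "0,110",
                          stringsAsFactors = FALSE))
  rec_flipped <- rec
  rec_flipped$strand <- "-"
  rec_flipped$chromStart <- len - 200
  rec_flipped$chromEnd <- len - 50
  rec_flipped$blockSizes <- "40,60"
  rec_flipped$blockStarts <- paste(c(0, 150 - 60), collapse = ",")
  expect_equal(extract_spliced_sequence(genome_rc, bed12(rec_flipped)),
               extract_spliced_sequence(genome, rec))
})

test_that("peptide FASTA writer emits one header-sequence pair per candidate", {
  cand <- data.frame(match_key = c("chr1:101", "chr1:500"), frame = c(1L, 2L),
                     peptide = c("MAWMAWMAW", "GHKGHKGHK"), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".fa")
  write_peptide_fasta(cand, path)
  lines <- readLines(path)
  expect_equal(lines[1], ">chr1:101|frame1")
  expect_equal(lines[4], "GHKGHKGHK")
})
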