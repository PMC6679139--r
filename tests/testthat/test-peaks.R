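test_that("TFBS extraction centers the 101-bp window on the peak midpoint", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 200)))
  r <- extract_tfbs(g, list(chrom = "chr1", start = 60L, end = 80L))
  expect_identical(r$seq, strrep("A", 101))
  expect_identical(r$binding_label, "positive")

  # width-1 peak at 0-based position i: window is genome[i-50 .. i+50]
  set.seed(21)
  gseq <- random_dna(1, len = 400L)
  g <- Biostrings::DNAStringSet(c(chrZ = gseq))
  i <- 163L
  r <- extract_tfbs(g, list(chrom = "chrZ", start = i, end = i + 1L))
  expect_identical(r$seq, substr(gseq, i - 50 + 1, i + 50 + 1))
  expect_identical(substr(r$seq, 51, 51), substr(gseq, i + 1, i + 1))
})

test_that("extracted centers match direct string indexing on random peaks", {
  set.seed(33)
  gseq <- random_dna(1, len = 1000L)
  g <- Biostrings::DNAStringSet(c(chr1 = gseq))
  for (k in 1:20) {
    start <- sample(60:900, 1)
    end <- start + sample(1:40, 1)
    mid <- start + (end - start) %/% 2
    r <- extract_tfbs(g, list(chrom = "chr1", start = start, end = end))
    expect_identical(nchar(r$seq), 101L)
    expect_identical(substr(r$seq, 51, 51), substr(gseq, mid + 1, mid + 1))
    expect_identical(r$seq, substr(gseq, mid - 49, mid + 51))
  }
})

test_that("out-of-bounds windows are skipped with a warning, unknown chromosomes are hard errors", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 200)))
  expect_warning(r <- extract_tfbs(g, list(chrom = "chr1", start = 0L, end = 4L)),
                 "outside chromosome bounds")
  expect_null(r)
  expect_error(extract_tfbs(g, list(chrom = "chr9", start = 60L, end = 80L)),
               "chr9")
})

test_that("extract_tfbs_set drops N-containing windows and reports counts", {
  gseq <- paste0(strrep("A", 150), "N", strrep("G", 150))
  g <- Biostrings::DNAStringSet(c(chr1 = gseq))
  peaks <- data.frame(chrom = "chr1",
                      start = c(100L, 240L), end = c(102L, 260L))
  expect_warning(out <- extract_tfbs_set(g, peaks), "contains N")
  expect_identical(nrow(out), 1L)
  expect_false(grepl("N", out$seq))
})

test_that("BED-family peak files parse with track lines, comments and signal columns", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "peaks.narrowPeak")
  writeLines(c(
    "track name=test",
    "# a comment",
    "chr1\t10\t60\tpeak1\t0\t.\t5.5\t-1\t-1\t25",
    "chr2\t100\t200\tpeak2\t0\t.\t7.25\t-1\t-1\t50"
  ), p)
  peaks <- read_peaks(p)
  expect_identical(nrow(peaks), 2L)
  expect_identical(peaks$start, c(10L, 100L))
  expect_equal(peaks$signal, c(5.5, 7.25))

  p3 <- file.path(dir, "plain.bed")
  writeLines("chr1\t5\t15", p3)
  expect_true(is.na(read_peaks(p3)$signal))

  bad <- file.path(dir, "bad.bed")
  writeLines("chr1\t20\t10", bad)
  expect_error(read_peaks(bad), "start >= end")
})

test_that("random negatives avoid peaks (exhaustive interval check)", {
  set.seed(44)
  gseq <- random_dna(1, len = 10000L)
  g <- Biostrings::DNAStringSet(c(chr1 = gseq))

  # one admissible region: only windows in the tail [9400, 10000) fit
  peaks <- data.frame(chrom = "chr1", start = 0L, end = 9400L)
  neg <- sample_random_negatives(g, peaks, n = 5L, seed = 1L)
  for (s in neg$seq) {
    at <- as.integer(regexpr(s, gseq, fixed = TRUE)) - 1L  # 0-based
    expect_gte(at, 9400L)
  }

  # 50 negatives vs 10 random peaks: zero overlaps by brute force
  peaks <- data.frame(chrom = "chr1",
                      start = as.integer(seq(500, 9000, length.out = 10)))
  peaks$end <- peaks$start + 80L
  neg <- sample_random_negatives(g, peaks, n = 50L, seed = 7L)
  expect_identical(nrow(neg), 50L)
  for (s in neg$seq) {
    at <- as.integer(regexpr(s, gseq, fixed = TRUE)) - 1L
    overlaps <- any(at < peaks$end & (at + 101L) > peaks$start)
    expect_false(overlaps)
  }

  expect_identical(nrow(sample_random_negatives(g, peaks, 0L, seed = 1L)), 0L)
  expect_identical(sample_random_negatives(g, peaks, 20L, seed = 9L)$seq,
                   sample_random_negatives(g, peaks, 20L, seed = 9L)$seq)
})

test_that("impossible negative placement errors with the achieved count", {
  g <- Biostrings::DNAStringSet(c(chr1 = strrep("A", 150)))
  peaks <- data.frame(chrom = "chr1", start = 0L, end = 150L)
  expect_error(
    sample_random_negatives(g, peaks, 3L, seed = 1L, max_tries = 200L),
    "0 of 3")
})

test_that("shuffle negatives preserve per-positive dinucleotide counts", {
  pos <- toy_dataset(10, seed = 3)[1:10, ]
  neg <- shuffle_negatives(pos, seed = 5)
  expect_identical(nrow(neg), 10L)
  expect_identical(neg$origin, rep("shuffle", 10))
  for (i in 1:10) {
    expect_identical(dinucleotide_counts(neg$seq[i]),
                     dinucleotide_counts(pos$seq[i]))
  }
})

test_that("dataset TSV and FASTA writers round-trip", {
  d <- toy_dataset(5, seed = 8)
  dir <- withr::local_tempdir()
  tsv <- file.path(dir, "data.tsv")
  write_dataset(d, tsv)
  back <- read_dataset(tsv)
  expect_identical(back$seq, d$seq)
  expect_identical(back$binding_label, d$binding_label)
  expect_identical(back$domain_label, d$domain_label)

  fa <- file.path(dir, "data.fa")
  write_dataset(d, fa, format = "fasta")
  lines <- readLines(fa)
  expect_identical(length(lines), 2L * nrow(d))
  expect_match(lines[1], "^>seq1\\|positive\\|target$")
})
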