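# Genome + ChIP-seq peak handling: 101-bp TFBS window extraction, negative
# sampling, and dataset I/O.
#
# Coordinate convention (fixed, BED-style): peaks are 0-based half-open
# [start, end). The peak midpoint is start + floor((end - start) / 2) in
# 0-based coordinates, and a TFBS is the 101-bp window [mid - 50, mid + 51),
# i.e. the genome base at the midpoint sits at window index 50 (0-based).

#' Read a genome from a FASTA file
#'
#' @param path Path to a (optionally multi-record) FASTA file.
#' @return A [Biostrings::DNAStringSet] keyed by chromosome name (the first
#'   whitespace-separated token of each FASTA header).
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Read ChIP-seq peaks from a BED-family file
#'
#' Accepts BED, narrowPeak and broadPeak (ENCODE style). `track`/`browser`
#' lines and `#` comments are skipped; only the first three columns
#' (chrom, start, end) are interpreted, plus column 7 (signalValue) when
#' present. Coordinates are kept 0-based half-open.
#'
#' @param path Path to the interval file.
#' @return A data.frame with columns `chrom`, `start`, `end` and `signal`
#'   (NA when the file has no signal column).
#' @export
read_peaks <- function(path) {
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("no peak records in ", path)
  df <- utils::read.table(text = lines, sep = "\t", header = FALSE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  if (ncol(df) < 3L) stop("peak file must have at least 3 columns: ", path)
  peaks <- data.frame(
    chrom = as.character(df[[1L]]),
    start = as.integer(df[[2L]]),
    end = as.integer(df[[3L]]),
    signal = if (ncol(df) >= 7L) suppressWarnings(as.numeric(df[[7L]]))
             else NA_real_,
    stringsAsFactors = FALSE
  )
  validate_peaks(peaks)
  peaks
}

validate_peaks <- function(peaks) {
  stopifnot(is.data.frame(peaks),
            all(c("chrom", "start", "end") %in% names(peaks)))
  if (nrow(peaks) > 0L) {
    if (any(!nzchar(peaks$chrom))) stop("peak with empty chromosome name")
    if (any(peaks$start >= peaks$end)) {
      bad <- which(peaks$start >= peaks$end)[1L]
      stop("peak with start >= end at row ", bad,
           " (coordinates are 0-based half-open)")
    }
    if (any(peaks$start < 0L)) stop("peak with negative start")
  }
  invisible(peaks)
}

peak_midpoint <- function(start, end) start + (end - start) %/% 2L

#' Extract the 101-bp TFBS window for one peak
#'
#' The TFBS is the 101-bp forward-strand window centered on the peak
#' midpoint: with 0-based midpoint `mid = start + floor((end-start)/2)`, the
#' window is `[mid-50, mid+51)`, so the genome base at the midpoint is the
#' window's center base (index 50, 0-based).
#'
#' @param genome A [Biostrings::DNAStringSet] as from [read_genome()].
#' @param peak A one-row data.frame (or list) with `chrom`, `start`, `end`
#'   in 0-based half-open coordinates.
#' @param domain_label Domain tag attached to the sequence, `"target"` or
#'   `"source"`.
#' @return A one-row data.frame with columns `seq`, `binding_label`
#'   (`"positive"`), `domain_label`, `origin` (`"peak locus"`); or `NULL`
#'   with a warning when the window runs off the chromosome.
#' @export
extract_tfbs <- function(genome, peak, domain_label = "target") {
  chrom <- as.character(peak$chrom)
  if (!chrom %in% names(genome)) {
    stop("unknown chromosome in peak: '", chrom, "' not present in genome")
  }
  start <- as.integer(peak$start)
  end <- as.integer(peak$end)
  if (start >= end) stop("peak with start >= end: [", start, ", ", end, ")")
  mid <- peak_midpoint(start, end)
  L <- Biostrings::width(genome[chrom])
  lo0 <- mid - 50L
  hi0 <- mid + 50L                     # inclusive 0-based bounds
  if (lo0 < 0L || hi0 > L - 1L) {
    warning("skipping peak at ", chrom, ":[", start, ",", end,
            "): 101-bp window around midpoint ", mid,
            " falls outside chromosome bounds")
    return(NULL)
  }
  seq <- as.character(Biostrings::subseq(genome[[chrom]],
                                         start = lo0 + 1L, end = hi0 + 1L))
  labeled_sequence(seq, binding_label = "positive",
                   domain_label = domain_label, origin = "peak locus")
}

# Canonical labeled-sequence record: one row per 101-bp sequence.
labeled_sequence <- function(seq, binding_label, domain_label, origin) {
  stopifnot(binding_label %in% c("positive", "negative", "unknown"),
            domain_label %in% c("target", "source"))
  if (any(nchar(seq) != TFBS_LEN)) {
    stop("labeled sequences must have length ", TFBS_LEN)
  }
  if (any(grepl("[^ACGTN]", toupper(seq)))) {
    stop("labeled sequences must be over {A,C,G,T,N}")
  }
  if (length(seq) == 0L) {
    return(data.frame(seq = character(0), binding_label = character(0),
                      domain_label = character(0), origin = character(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(seq = toupper(seq), binding_label = binding_label,
             domain_label = domain_label, origin = origin,
             stringsAsFactors = FALSE)
}

#' Extract all TFBS windows for a peak table
#'
#' Applies [extract_tfbs()] to every peak, skipping (with one summary
#' warning each) out-of-bounds windows and windows containing N -- the
#' dinucleotide-shuffle contract used for matched negatives is undefined
#' over N.
#'
#' @inheritParams extract_tfbs
#' @param peaks A data.frame of peaks as from [read_peaks()].
#' @return A data.frame of positive labeled sequences.
#' @export
extract_tfbs_set <- function(genome, peaks, domain_label = "target") {
  validate_peaks(peaks)
  rows <- vector("list", nrow(peaks))
  n_oob <- 0L
  for (i in seq_len(nrow(peaks))) {
    r <- withCallingHandlers(
      extract_tfbs(genome, peaks[i, ], domain_label),
      warning = function(w) invokeRestart("muffleWarning")
    )
    if (is.null(r)) n_oob <- n_oob + 1L
    rows[[i]] <- r
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- labeled_sequence(character(0), character(0),
                                            character(0), character(0))
  has_n <- grepl("N", out$seq, fixed = TRUE)
  if (n_oob > 0L) {
    warning(n_oob, " peak(s) skipped: window outside chromosome bounds")
  }
  if (any(has_n)) {
    warning(sum(has_n), " peak(s) dropped: extracted window contains N")
  }
  out[!has_n, , drop = FALSE]
}

#' Sample random non-peak negative windows
#'
#' Draws 101-bp windows uniformly from the genome, rejecting any window that
#' overlaps an annotated peak interval or contains N, emulating
#' random-genomic-locus negatives.
#'
#' @inheritParams extract_tfbs
#' @param peaks Peak data.frame (may have zero rows).
#' @param n Number of negatives to draw.
#' @param seed Integer seed; draws are deterministic given the seed.
#' @param max_tries Total draw budget before giving up.
#' @return A data.frame of `n` negative labeled sequences with origin
#'   `"random-locus"`.
#' @export
sample_random_negatives <- function(genome, peaks, n, seed,
                                    domain_label = "target",
                                    max_tries = 200L * max(n, 1L) + 1000L) {
  validate_peaks(peaks)
  n <- as.integer(n)
  if (n == 0L) {
    return(labeled_sequence(character(0), character(0), character(0),
                            character(0)))
  }
  widths <- Biostrings::width(genome)
  valid <- widths >= TFBS_LEN
  if (!any(valid)) stop("no chromosome long enough for a 101-bp window")
  chroms <- names(genome)[valid]
  n_starts <- widths[valid] - TFBS_LEN + 1L   # admissible 0-based starts

  peak_ir <- lapply(chroms, function(ch) {
    p <- peaks[peaks$chrom == ch, , drop = FALSE]
    IRanges::IRanges(start = p$start + 1L, end = p$end)  # 1-based closed
  })
  names(peak_ir) <- chroms

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  got <- character(0)
  tries <- 0L
  chunk <- max(2L * n, 64L)
  while (length(got) < n && tries < max_tries) {
    m <- min(chunk, max_tries - tries)
    tries <- tries + m
    ci <- sample.int(length(chroms), m, replace = TRUE, prob = n_starts)
    s0 <- floor(stats::runif(m) * n_starts[ci])      # 0-based start
    keep <- logical(m)
    for (j in seq_len(m)) {
      ir <- IRanges::IRanges(start = s0[j] + 1L, width = TFBS_LEN)
      keep[j] <- !any(IRanges::overlapsAny(ir, peak_ir[[chroms[ci[j]]]]))
    }
    if (!any(keep)) next
    seqs <- vapply(which(keep), function(j) {
      as.character(Biostrings::subseq(genome[[chroms[ci[j]]]],
                                      start = s0[j] + 1L,
                                      width = TFBS_LEN))
    }, character(1L))
    seqs <- seqs[!grepl("N", seqs, fixed = TRUE)]
    got <- c(got, seqs)
  }
  if (length(got) < n) {
    stop("could only place ", length(got), " of ", n,
         " non-overlapping negative windows within the draw budget")
  }
  labeled_sequence(got[seq_len(n)], binding_label = "negative",
                   domain_label = domain_label, origin = "random-locus")
}

#' Build matched shuffle negatives for a positive set
#'
#' One negative per positive, produced by [dinucleotide_shuffle()], so each
#' negative has exactly the dinucleotide counts of its source positive.
#'
#' @param positives A data.frame of positive labeled sequences.
#' @param seed Integer seed; negative i uses sub-seed `seed + i`.
#' @return A data.frame of negatives with origin `"shuffle"`.
#' @export
shuffle_negatives <- function(positives, seed) {
  if (nrow(positives) == 0L) {
    return(labeled_sequence(character(0), character(0), character(0),
                            character(0)))
  }
  seqs <- vapply(seq_len(nrow(positives)), function(i) {
    dinucleotide_shuffle(positives$seq[i], seed = as.integer(seed) + i)
  }, character(1L))
  labeled_sequence(seqs, binding_label = "negative",
                   domain_label = positives$domain_label, origin = "shuffle")
}

#' Write a labeled dataset to disk
#'
#' Emits a 3-column tab-separated table (`seq`, `binding_label`,
#' `domain_label`), or FASTA with the labels encoded in headers as
#' `>id|binding_label|domain_label`.
#'
#' @param data A labeled-sequence data.frame.
#' @param path Output file path.
#' @param format `"tsv"` or `"fasta"`.
#' @export
write_dataset <- function(data, path, format = c("tsv", "fasta")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(data[, c("seq", "binding_label", "domain_label")],
                       path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    hdr <- sprintf(">seq%d|%s|%s", seq_len(nrow(data)),
                   data$binding_label, data$domain_label)
    writeLines(as.vector(rbind(hdr, data$seq)), path)
  }
  invisible(path)
}

#' Read a labeled dataset written by [write_dataset()]
#'
#' @param path Path to a 3-column TSV (with header) of sequence,
#'   binding label and domain label.
#' @return A labeled-sequence data.frame (origin `"file"`).
#' @export
read_dataset <- function(path) {
  if (!file.exists(path)) stop("dataset not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "")
  need <- c("seq", "binding_label", "domain_label")
  if (!all(need %in% names(df))) {
    stop("dataset TSV must have columns: ", paste(need, collapse = ", "))
  }
  labeled_sequence(df$seq, df$binding_label, df$domain_label, origin = "file")
}
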