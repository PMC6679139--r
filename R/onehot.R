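# One-hot encoding of fixed-length DNA windows.
#
# Row order is fixed as (T, G, C, A) from row 1 to row 4, i.e.
# A = (0,0,0,1)', C = (0,0,1,0)', G = (0,1,0,0)', T = (1,0,0,0)'.
# N (and any unknown base) maps to an all-zero column, so an N column sums
# to 0 while A/C/G/T columns sum to 1.

ONEHOT_ROWS <- c("T", "G", "C", "A")
TFBS_LEN <- 101L

#' One-hot encode a DNA sequence window
#'
#' Encodes a 101-bp DNA string as a 4 x 101 indicator matrix with fixed row
#' order (T, G, C, A). `N` encodes as an all-zero column, carrying no base
#' information.
#'
#' @param seq A single character string over the alphabet A, C, G, T, N of
#'   length 101.
#' @return A 4 x 101 numeric matrix of 0/1 with rownames `c("T","G","C","A")`.
#' @examples
#' m <- one_hot_encode(strrep("A", 101))
#' all(m["A", ] == 1)
#' @export
one_hot_encode <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  n <- nchar(seq)
  if (n != TFBS_LEN) {
    stop("one_hot_encode() expects a sequence of length ", TFBS_LEN,
         ", got length ", n)
  }
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(chars), c(ONEHOT_ROWS, "N"))
  if (length(bad) > 0L) {
    stop("sequence contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "))
  }
  m <- matrix(0, nrow = 4L, ncol = n, dimnames = list(ONEHOT_ROWS, NULL))
  code <- match(chars, ONEHOT_ROWS)
  keep <- !is.na(code)
  m[cbind(code[keep], which(keep))] <- 1
  m
}

#' Decode a one-hot matrix back to a DNA string
#'
#' Inverse of [one_hot_encode()]: each column is decoded to the base whose
#' indicator row is 1; all-zero columns decode to `N`.
#'
#' @param mat A 4 x L one-hot matrix with row order (T, G, C, A).
#' @return A DNA string of length `ncol(mat)`.
#' @export
one_hot_decode <- function(mat) {
  stopifnot(is.matrix(mat), nrow(mat) == 4L)
  out <- character(ncol(mat))
  hit <- max.col(t(mat), ties.method = "first")
  is_n <- colSums(mat) == 0
  out <- ONEHOT_ROWS[hit]
  out[is_n] <- "N"
  paste(out, collapse = "")
}

# Encode many equal-length sequences into a (4*L) x N matrix, column-major
# within each item (4 channels fastest, then position). This is the layout
# the network consumes; unknown bases become zero columns.
encode_seq_matrix <- function(seqs, len = TFBS_LEN) {
  n <- length(seqs)
  if (n == 0L) return(matrix(0, nrow = 4L * len, ncol = 0L))
  nc <- nchar(seqs)
  if (any(nc != len)) {
    stop("all sequences must have length ", len, "; offending lengths: ",
         paste(utils::head(unique(nc[nc != len])), collapse = ", "))
  }
  chars <- matrix(unlist(strsplit(toupper(seqs), "", fixed = TRUE),
                         use.names = FALSE), nrow = len)
  code <- match(chars, ONEHOT_ROWS)          # len x n, NA for N
  x <- matrix(0, nrow = 4L * len, ncol = n)
  pos <- rep(seq_len(len), times = n)
  item <- rep(seq_len(n), each = len)
  keep <- !is.na(code)
  x[cbind((pos[keep] - 1L) * 4L + code[keep], item[keep])] <- 1
  x
}
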