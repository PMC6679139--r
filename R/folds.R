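# Stratified k-fold construction with rotating train/validation/test roles
# (for k = 10: 8 folds train, 1 validation, 1 test, each fold tested once).

#' Build stratified cross-validation folds with rotating roles
#'
#' Partitions the data indices into `k` folds of near-equal size, stratified
#' by binding label so each fold carries a proportional share of positives
#' and negatives. Rotation `r` uses fold `r` as test, the next fold
#' (cyclically) as validation, and the remaining `k - 2` folds as training,
#' so each fold serves as test exactly once across the `k` rotations.
#'
#' @param data A labeled-sequence data.frame (needs a `binding_label`
#'   column), or an integer giving the number of items (no stratification).
#' @param k Number of folds, at least 3.
#' @param seed Integer seed for the stratified shuffle.
#' @return An object of class `danntf_folds`: a list with `fold` (integer
#'   fold id per item) and `rotations` (list of `k` lists with `train`,
#'   `val`, `test` index vectors).
#' @export
make_folds <- function(data, k, seed) {
  n <- if (is.data.frame(data)) nrow(data) else as.integer(data)
  k <- as.integer(k)
  if (k < 3L) stop("k must be >= 3 (train/validation/test roles)")
  if (k > n) stop("k = ", k, " exceeds data size ", n)
  labels <- if (is.data.frame(data) && "binding_label" %in% names(data)) {
    data$binding_label
  } else {
    rep("all", n)
  }

  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))

  fold <- integer(n)
  offset <- 0L  # continue the fold cycle across strata so totals stay even
  for (lab in unique(labels)) {
    idx <- which(labels == lab)
    idx <- idx[sample.int(length(idx))]
    f <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    fold[idx] <- f
    offset <- (offset + length(idx)) %% k
  }

  rotations <- lapply(seq_len(k), function(r) {
    test_f <- r
    val_f <- (r %% k) + 1L
    list(train = which(!fold %in% c(test_f, val_f)),
         val = which(fold == val_f),
         test = which(fold == test_f))
  })
  structure(list(fold = fold, k = k, rotations = rotations),
            class = "danntf_folds")
}

#' @export
print.danntf_folds <- function(x, ...) {
  cat("Stratified ", x$k, "-fold partition over ", length(x$fold),
      " items (fold sizes: ",
      paste(tabulate(x$fold, x$k), collapse = ", "), ")\n", sep = "")
  invisible(x)
}
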