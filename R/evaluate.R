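# Evaluation: AUC (Mann-Whitney rank form), F1 at a score threshold,
# stratified 10-fold rotation, and paired Wilcoxon signed-rank comparison.

#' Area under the ROC curve
#'
#' Computed in the Mann-Whitney rank form: the probability that a randomly
#' chosen positive is scored above a randomly chosen negative, with ties
#' counted half. Equals exhaustive pair counting exactly.
#'
#' @param scores Numeric scores (higher = more TFBS-like).
#' @param labels Binary labels: 1/TRUE/"positive" for positives.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(scores, labels) {
  y <- as_binary_label(labels)
  stopifnot(length(scores) == length(y), !anyNA(scores), !anyNA(y))
  n_pos <- sum(y == 1L)
  n_neg <- sum(y == 0L)
  if (n_pos == 0L || n_neg == 0L) {
    stop("AUC needs at least one positive and one negative")
  }
  r <- rank(scores)          # average ranks give half credit to ties
  (sum(r[y == 1L]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' F1 score at a threshold
#'
#' `F1 = 2 P R / (P + R)` with `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, where a
#' window is called positive when its score is at least `threshold`.
#' Defined as 0 when `P + R = 0` (no true positives).
#'
#' @inheritParams compute_auc
#' @param threshold Score cutoff for a positive call (default 0.5 on the
#'   softmax TFBS probability).
#' @return F1 in `[0, 1]`.
#' @export
compute_f1 <- function(scores, labels, threshold = 0.5) {
  y <- as_binary_label(labels)
  stopifnot(length(scores) == length(y), length(y) > 0L)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & y == 1L)
  fp <- sum(pred == 1L & y == 0L)
  fn <- sum(pred == 0L & y == 1L)
  if (tp == 0L) return(0)
  p <- tp / (tp + fp)
  r <- tp / (tp + fn)
  2 * p * r / (p + r)
}

as_binary_label <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.numeric(labels)) {
    stopifnot(all(labels %in% c(0, 1)))
    return(as.integer(labels))
  }
  y <- ifelse(as.character(labels) == "positive", 1L,
              ifelse(as.character(labels) == "negative", 0L, NA_integer_))
  if (anyNA(y)) stop("labels must be binary (positive/negative, 0/1, logical)")
  y
}

#' Paired Wilcoxon signed-rank comparison of two methods
#'
#' Two-sided signed-rank test on paired metric vectors (e.g. per-fold AUCs of
#' two methods). Zero differences are dropped; the exact distribution is used
#' for up to 25 informative pairs (falling back to the normal approximation
#' when tied absolute differences make the exact distribution unavailable),
#' the normal approximation above.
#'
#' @param metrics_a,metrics_b Equal-length numeric vectors, paired.
#' @return A list with `statistic` (signed-rank V of `a - b`), `p_value`,
#'   `n_informative` (pairs with nonzero difference) and
#'   `median_difference`. Identical vectors give `p_value = 1` with
#'   `n_informative = 0`.
#' @export
paired_wilcoxon <- function(metrics_a, metrics_b) {
  if (length(metrics_a) != length(metrics_b)) {
    stop("paired comparison needs equal-length metric vectors (",
         length(metrics_a), " vs ", length(metrics_b), ")")
  }
  d <- metrics_a - metrics_b
  nz <- d[d != 0]
  n <- length(nz)
  if (n == 0L) {
    return(list(statistic = NA_real_, p_value = 1, n_informative = 0L,
                median_difference = 0))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(nz, mu = 0, alternative = "two.sided",
                       exact = n <= 25, correct = TRUE)
  )
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       n_informative = n, median_difference = stats::median(d))
}

#' Cross-validated evaluation of a training regime
#'
#' Builds a stratified k-fold partition of the target data, and for each of
#' the k rotations trains a model on the k-2 training folds (validating on
#' the validation fold, with any source data pooled in per the regime) and
#' scores the held-out test fold. Test items never intersect training items.
#'
#' @param target_data Labeled-sequence data.frame of the target cell type.
#' @param regime A [training_regime()].
#' @param config A [dann_config()].
#' @param k Number of folds (default 10: 8 train / 1 validation / 1 test).
#' @param source_data Pooled source-cell-type data (required by adversarial
#'   regimes).
#' @param f1_threshold Score cutoff passed to [compute_f1()].
#' @return An `eval_report`: list with `per_fold` (fold, auc, f1, n_pos,
#'   n_neg), `mean_auc`, `mean_f1`, and the fold object used.
#' @export
cross_validate <- function(target_data, regime, config, k = 10L,
                           source_data = NULL, f1_threshold = 0.5) {
  folds <- make_folds(target_data, k, config$seed)
  rows <- vector("list", k)
  for (r in seq_len(k)) {
    rot <- folds$rotations[[r]]
    model <- train_dann(
      target_data = target_data[rot$train, , drop = FALSE],
      source_data = source_data,
      regime = regime,
      config = config,
      val_data = target_data[rot$val, , drop = FALSE]
    )
    test <- target_data[rot$test, , drop = FALSE]
    s <- score(test$seq, model)
    y <- as_binary_label(test$binding_label)
    rows[[r]] <- data.frame(fold = r,
                            auc = compute_auc(s, y),
                            f1 = compute_f1(s, y, f1_threshold),
                            n_pos = sum(y == 1L), n_neg = sum(y == 0L))
  }
  per_fold <- do.call(rbind, rows)
  structure(list(per_fold = per_fold,
                 mean_auc = mean(per_fold$auc),
                 mean_f1 = mean(per_fold$f1),
                 k = k, regime = regime$mode),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("eval_report (", x$regime, ", ", x$k, "-fold): mean AUC ",
      round(x$mean_auc, 4), ", mean F1 ", round(x$mean_f1, 4), "\n", sep = "")
  print(x$per_fold, row.names = FALSE)
  invisible(x)
}
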