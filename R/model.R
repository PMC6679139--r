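# The three-part adversarial network: feature extractor Gf (conv/ReLU/maxpool
# x2), label predictor Gl (dropout -> FC -> ReLU -> FC -> ReLU -> softmax) and
# domain classifier Gd (gradient reversal -> FC -> ReLU -> softmax).
#
# There is no autodiff framework here: forward passes cache what the manual
# backward passes need, convolutions are im2col matrix products (BLAS), and
# all gradients are verified against central finite differences in the tests.
#
# Batch layout: a batch of B windows is a (4 * seq_len) x B matrix, each
# column one window with the 4 one-hot channels fastest, then position.
# Intermediate conv/pool maps are K x (positions * B) matrices, item-major
# (all positions of item 1 first).

.idx_cache <- new.env(parent = emptyenv())

# Gather indices turning a (C*L) x B input into an (M*C) x (outL*B) im2col
# matrix for a convolution with window M and the given stride.
im2col_idx <- function(C, L, M, stride) {
  key <- paste("c", C, L, M, stride, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  out_l <- (L - M) %/% stride + 1L
  starts <- (seq_len(out_l) - 1L) * stride          # 0-based window starts
  idx <- as.vector(vapply(starts, function(s) C * s + seq_len(M * C),
                          integer(M * C)))
  .idx_cache[[key]] <- list(idx = idx, out_l = out_l)
  .idx_cache[[key]]
}

# Column indices of the m-th in-window offset for max pooling over an
# item-major K x (inL*B) map; one vector per offset, each of length outP*B.
pool_idx <- function(in_l, pool, stride, B) {
  key <- paste("p", in_l, pool, stride, B, sep = "_")
  if (!is.null(.idx_cache[[key]])) return(.idx_cache[[key]])
  out_p <- (in_l - pool) %/% stride + 1L
  base <- rep((0:(B - 1L)) * in_l, each = out_p) +
    rep((seq_len(out_p) - 1L) * stride + 1L, times = B)
  .idx_cache[[key]] <- list(cols = lapply(0:(pool - 1L), function(m) base + m),
                            out_p = out_p)
  .idx_cache[[key]]
}

conv_forward <- function(x, W, b, C, L, M, stride) {
  ii <- im2col_idx(C, L, M, stride)
  xcol <- matrix(x[ii$idx, , drop = FALSE], nrow = M * C)
  a <- crossprod(W, xcol) + b            # K x (outL*B), pre-activation
  y <- a
  y[y < 0] <- 0                          # ReLU
  list(xcol = xcol, pre = a, out = y, out_l = ii$out_l, idx = ii$idx)
}

# dpre: gradient at the pre-activation (ReLU already applied by caller).
conv_backward <- function(cache, W, dpre, C, L, need_dx) {
  dW <- cache$xcol %*% t(dpre)
  db <- rowSums(dpre)
  dx <- NULL
  if (need_dx) {
    dxcol <- W %*% dpre                  # (M*C) x (outL*B)
    B <- ncol(dxcol) / cache$out_l
    dmat <- matrix(dxcol, nrow = length(cache$idx), ncol = B)
    dx <- rowsum(dmat, group = cache$idx, reorder = TRUE)  # (C*L) x B
  }
  list(dW = dW, db = db, dx = dx)
}

maxpool_forward <- function(y, in_l, pool, stride, B) {
  pi <- pool_idx(in_l, pool, stride, B)
  z <- y[, pi$cols[[1L]], drop = FALSE]
  winner <- matrix(0L, nrow(z), ncol(z))
  for (m in 2:pool) {
    cand <- y[, pi$cols[[m]], drop = FALSE]
    upd <- cand > z
    z[upd] <- cand[upd]
    winner[upd] <- m - 1L
  }
  list(out = z, winner = winner, cols = pi$cols, out_p = pi$out_p,
       in_cols = in_l * B)
}

maxpool_backward <- function(cache, dz) {
  K <- nrow(dz)
  dy <- matrix(0, K, cache$in_cols)
  for (m in seq_along(cache$cols)) {
    sel <- which(cache$winner == (m - 1L))
    if (length(sel) == 0L) next
    col_out <- (sel - 1L) %/% K + 1L
    row <- (sel - 1L) %% K + 1L
    lin_in <- (cache$cols[[m]][col_out] - 1L) * K + row
    dy[lin_in] <- dy[lin_in] + dz[sel]
  }
  dy
}

softmax_cols <- function(l) {
  mx <- if (nrow(l) == 2L) pmax(l[1L, ], l[2L, ]) else apply(l, 2L, max)
  e <- exp(sweep(l, 2L, mx))
  sweep(e, 2L, colSums(e), "/")
}

# ---------------------------------------------------------------------------
# Full forward passes (with caches for the training loop)

feature_forward <- function(theta_f, x, cfg) {
  dims <- dann_dims(cfg)
  B <- ncol(x)
  c1 <- conv_forward(x, theta_f$W1, theta_f$b1, C = 4L, L = cfg$seq_len,
                     M = cfg$kernel_size, stride = cfg$conv_stride)
  p1 <- maxpool_forward(c1$out, dims$conv1, cfg$pool_size, cfg$pool_stride, B)
  # re-block pooled map to (K1 * pool1) x B for the second im2col
  z1 <- matrix(p1$out, nrow = cfg$n_kernels_1 * dims$pool1, ncol = B)
  c2 <- conv_forward(z1, theta_f$W2, theta_f$b2, C = cfg$n_kernels_1,
                     L = dims$pool1, M = cfg$kernel_size,
                     stride = cfg$conv_stride)
  p2 <- maxpool_forward(c2$out, dims$conv2, cfg$pool_size, cfg$pool_stride, B)
  feat <- matrix(p2$out, nrow = dims$feat, ncol = B)
  list(feat = feat, c1 = c1, p1 = p1, c2 = c2, p2 = p2, B = B, dims = dims)
}

feature_backward <- function(theta_f, fwd, dfeat, cfg) {
  dz2 <- matrix(dfeat, nrow = cfg$n_kernels_2)        # K2 x (pool2*B)
  dy2 <- maxpool_backward(fwd$p2, dz2)                # K2 x (conv2*B)
  dy2[fwd$c2$pre <= 0] <- 0
  g2 <- conv_backward(fwd$c2, theta_f$W2, dy2, C = cfg$n_kernels_1,
                      L = fwd$dims$pool1, need_dx = TRUE)
  dz1 <- matrix(g2$dx, nrow = cfg$n_kernels_1)        # K1 x (pool1*B)
  dy1 <- maxpool_backward(fwd$p1, dz1)
  dy1[fwd$c1$pre <= 0] <- 0
  g1 <- conv_backward(fwd$c1, theta_f$W1, dy1, C = 4L, L = cfg$seq_len,
                      need_dx = FALSE)
  list(W1 = g1$dW, b1 = g1$db, W2 = g2$dW, b2 = g2$db)
}

label_forward <- function(theta_l, feat, training, dropout_rate) {
  mask <- NULL
  zin <- feat
  if (training && dropout_rate > 0) {
    # inverted dropout: kept units scaled by 1/(1-rate), inference untouched
    mask <- matrix((stats::runif(length(feat)) >= dropout_rate) /
                     (1 - dropout_rate), nrow(feat), ncol(feat))
    zin <- feat * mask
  }
  a1 <- crossprod(theta_l$W1, zin) + theta_l$b1
  h1 <- a1; h1[h1 < 0] <- 0
  a2 <- crossprod(theta_l$W2, h1) + theta_l$b2
  h2 <- a2; h2[h2 < 0] <- 0
  logits <- crossprod(theta_l$W3, h2) + theta_l$b3
  list(probs = softmax_cols(logits), logits = logits, zin = zin, mask = mask,
       a1 = a1, h1 = h1, a2 = a2, h2 = h2)
}

# dlogits: gradient at the label logits. Returns parameter grads and the
# gradient at the (pre-dropout) feature input.
label_backward <- function(theta_l, fwd, dlogits) {
  dW3 <- fwd$h2 %*% t(dlogits)
  db3 <- rowSums(dlogits)
  dh2 <- theta_l$W3 %*% dlogits
  dh2[fwd$a2 <= 0] <- 0
  dW2 <- fwd$h1 %*% t(dh2)
  db2 <- rowSums(dh2)
  dh1 <- theta_l$W2 %*% dh2
  dh1[fwd$a1 <= 0] <- 0
  dW1 <- fwd$zin %*% t(dh1)
  db1 <- rowSums(dh1)
  dfeat <- theta_l$W1 %*% dh1
  if (!is.null(fwd$mask)) dfeat <- dfeat * fwd$mask
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2,
                    W3 = dW3, b3 = db3),
       dfeat = dfeat)
}

domain_forward <- function(theta_d, feat) {
  a1 <- crossprod(theta_d$W1, feat) + theta_d$b1
  h1 <- a1; h1[h1 < 0] <- 0
  logits <- crossprod(theta_d$W2, h1) + theta_d$b2
  list(probs = softmax_cols(logits), logits = logits, a1 = a1, h1 = h1,
       feat = feat)
}

domain_backward <- function(theta_d, fwd, dlogits) {
  dW2 <- fwd$h1 %*% t(dlogits)
  db2 <- rowSums(dlogits)
  dh1 <- theta_d$W2 %*% dlogits
  dh1[fwd$a1 <= 0] <- 0
  dW1 <- fwd$feat %*% t(dh1)
  db1 <- rowSums(dh1)
  dfeat <- theta_d$W1 %*% dh1
  list(grads = list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2), dfeat = dfeat)
}

# ---------------------------------------------------------------------------
# Public operations

# Coerce a batch argument (character vector of 101-mers, one 4x101 one-hot
# matrix, list of such matrices, or a (4*L) x B layout matrix) to the
# internal layout.
as_input_batch <- function(x, cfg) {
  if (is.character(x)) return(encode_seq_matrix(x, cfg$seq_len))
  if (is.data.frame(x) && "seq" %in% names(x)) {
    return(encode_seq_matrix(x$seq, cfg$seq_len))
  }
  if (is.list(x) && !is.data.frame(x)) {
    x <- vapply(x, function(m) as.vector(m), numeric(4L * cfg$seq_len))
    return(matrix(x, nrow = 4L * cfg$seq_len))
  }
  if (is.matrix(x)) {
    if (nrow(x) == 4L && ncol(x) == cfg$seq_len) {
      return(matrix(as.vector(x), ncol = 1L))
    }
    if (nrow(x) == 4L * cfg$seq_len) return(x)
  }
  stop("cannot interpret input batch: expected sequences, a 4x", cfg$seq_len,
       " one-hot matrix, a list of such matrices, or a ", 4L * cfg$seq_len,
       " x B matrix")
}

#' Run the convolutional feature extractor
#'
#' Applies conv -> ReLU -> maxpool -> conv -> ReLU -> maxpool (valid padding)
#' and flattens each item to a fixed-width feature vector. Deterministic:
#' the extractor has no stochastic layers.
#'
#' @param x Input batch: character vector of 101-mers, a single 4 x 101
#'   one-hot matrix, a list of them, or a `(4*101) x B` matrix.
#' @param theta_f Feature-extractor parameters (see [init_dann_params()]).
#' @param config A [dann_config()].
#' @param training Unused by the extractor (kept for interface symmetry).
#' @return A `feature_width x B` matrix, one column per item.
#' @export
feature_extractor <- function(x, theta_f, config, training = FALSE) {
  x <- as_input_batch(x, config)
  check_theta_shapes(theta_f, config, "theta_f")
  feature_forward(theta_f, x, config)$feat
}

#' Run the label predictor head
#'
#' Dropout (training only) -> FC -> ReLU -> FC -> ReLU -> softmax over the
#' two binding classes.
#'
#' @param z Feature matrix (`feature_width x B`), as from
#'   [feature_extractor()].
#' @param theta_l Label-predictor parameters.
#' @param config A [dann_config()].
#' @param training If `TRUE`, dropout is active (stochastic).
#' @return A `2 x B` matrix of class probabilities; row 1 is the TFBS
#'   probability, row 2 the non-TFBS probability; columns sum to 1.
#' @export
label_predictor <- function(z, theta_l, config, training = FALSE) {
  check_theta_shapes(theta_l, config, "theta_l")
  if (nrow(z) != nrow(theta_l$W1)) {
    stop("feature width mismatch: predictor expects ", nrow(theta_l$W1),
         ", got ", nrow(z))
  }
  p <- label_forward(theta_l, z, training, config$dropout_rate)$probs
  rownames(p) <- c("TFBS", "non-TFBS")
  p
}

#' Gradient reversal layer (forward)
#'
#' The identity map in the forward pass. In the backward pass the gradient
#' flowing to the input is the downstream gradient multiplied by `-lambda`
#' (see [grad_reverse_backward()]), which makes the feature extractor ascend
#' the domain-classification loss that the domain classifier descends.
#'
#' @param z Feature matrix.
#' @param lambda Nonnegative reversal strength.
#' @return `z`, unchanged.
#' @export
grad_reverse <- function(z, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  z
}

#' Gradient reversal layer (backward rule)
#'
#' @param grad Gradient of the downstream loss with respect to the layer
#'   output.
#' @param lambda Nonnegative reversal strength.
#' @return `-lambda * grad`, the gradient with respect to the layer input.
#' @export
grad_reverse_backward <- function(grad, lambda) {
  if (lambda < 0) stop("lambda must be >= 0")
  -lambda * grad
}

#' Adversarial strength schedule
#'
#' The logistic ramp `lambda(p) = 2 / (1 + exp(-gamma * p)) - 1` annealing
#' the gradient-reversal strength from 0 at the start of training upward,
#' which keeps the domain classifier from dominating while features are
#' still noisy. `p` is the fraction of optimizer steps completed.
#'
#' @param p Training progress in `[0, 1]` (vectorized).
#' @param gamma Ramp steepness (default 10).
#' @return `lambda` values in `[0, 2/(1+exp(-gamma)) - 1)`.
#' @export
lambda_schedule <- function(p, gamma = 10) {
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("training progress p must lie in [0, 1]")
  }
  2 / (1 + exp(-gamma * p)) - 1
}

#' Run the domain classifier head
#'
#' Routes features through the gradient reversal layer (identity forward),
#' then FC -> ReLU -> softmax over the two domains.
#'
#' @param z Feature matrix (`feature_width x B`).
#' @param theta_d Domain-classifier parameters.
#' @param config A [dann_config()].
#' @param lambda Reversal strength used by the backward pass.
#' @return A `2 x B` matrix of domain probabilities; row 1 is the target
#'   cell type, row 2 the source cell types.
#' @export
domain_classifier <- function(z, theta_d, config, lambda = 1) {
  check_theta_shapes(theta_d, config, "theta_d")
  if (nrow(z) != nrow(theta_d$W1)) {
    stop("feature width mismatch: domain classifier expects ",
         nrow(theta_d$W1), ", got ", nrow(z))
  }
  z <- grad_reverse(z, lambda)
  p <- domain_forward(theta_d, z)$probs
  rownames(p) <- c("target", "source")
  p
}

#' Score sequences with a trained model
#'
#' The binding score of a window is its softmax TFBS probability from the
#' label predictor applied to the extracted features, with dropout off:
#' deterministic for fixed parameters.
#'
#' @param x Input batch (see [feature_extractor()] for accepted forms).
#' @param model A `dann_model`, e.g. from [train_dann()].
#' @return A numeric vector of scores in `[0, 1]`, one per item.
#' @export
score <- function(x, model) {
  stopifnot(inherits(model, "dann_model"))
  cfg <- model$config
  x <- as_input_batch(x, cfg)
  feat <- feature_forward(model$theta_f, x, cfg)$feat
  probs <- label_forward(model$theta_l, feat, training = FALSE,
                         dropout_rate = 0)$probs
  as.numeric(probs[1L, ])
}

# ---------------------------------------------------------------------------
# Parameters, shapes, checkpoints

param_shapes <- function(cfg) {
  dims <- dann_dims(cfg)
  list(
    theta_f = list(W1 = c(cfg$kernel_size * 4L, cfg$n_kernels_1),
                   b1 = cfg$n_kernels_1,
                   W2 = c(cfg$kernel_size * cfg$n_kernels_1, cfg$n_kernels_2),
                   b2 = cfg$n_kernels_2),
    theta_l = list(W1 = c(dims$feat, cfg$fc_width), b1 = cfg$fc_width,
                   W2 = c(cfg$fc_width, cfg$fc_width), b2 = cfg$fc_width,
                   W3 = c(cfg$fc_width, 2L), b3 = 2L),
    theta_d = list(W1 = c(dims$feat, cfg$fc_width), b1 = cfg$fc_width,
                   W2 = c(cfg$fc_width, 2L), b2 = 2L)
  )
}

check_theta_shapes <- function(theta, cfg, which_group) {
  want <- param_shapes(cfg)[[which_group]]
  for (nm in names(want)) {
    got <- if (is.matrix(theta[[nm]])) dim(theta[[nm]]) else length(theta[[nm]])
    if (!identical(as.integer(got), as.integer(want[[nm]]))) {
      stop(which_group, "$", nm, " shape mismatch: expected (",
           paste(want[[nm]], collapse = " x "), "), observed (",
           paste(got, collapse = " x "), ")")
    }
  }
  invisible(TRUE)
}

#' Initialize network parameters
#'
#' He-style fan-in scaled normal initialization for weights, zero biases,
#' drawn from the current RNG stream (seed discipline is owned by the
#' training loop). With `zero = TRUE` all parameters are zero, which makes
#' every softmax output exactly (0.5, 0.5).
#'
#' @param config A [dann_config()].
#' @param zero If `TRUE`, return all-zero parameters.
#' @return A list with elements `theta_f`, `theta_l`, `theta_d`.
#' @export
init_dann_params <- function(config, zero = FALSE) {
  shapes <- param_shapes(config)
  he <- function(shape) {
    if (length(shape) == 1L) return(numeric(shape))
    if (zero) return(matrix(0, shape[1L], shape[2L]))
    matrix(stats::rnorm(prod(shape), sd = sqrt(2 / shape[1L])),
           shape[1L], shape[2L])
  }
  lapply(shapes, function(group) lapply(group, he))
}

new_dann_model <- function(params, config, regime = NULL,
                           training_log = NULL, best_epoch = NA_integer_,
                           val_auc = NA_real_) {
  structure(list(theta_f = params$theta_f, theta_l = params$theta_l,
                 theta_d = params$theta_d, config = config, regime = regime,
                 training_log = training_log, best_epoch = best_epoch,
                 val_auc = val_auc),
            class = "dann_model")
}

#' @export
print.dann_model <- function(x, ...) {
  cat("dann_model (", if (is.null(x$regime)) "untrained" else x$regime$mode,
      "): feature width ", dann_dims(x$config)$feat, sep = "")
  if (!is.na(x$val_auc)) {
    cat(", best validation AUC ", round(x$val_auc, 4),
        " at epoch ", x$best_epoch, sep = "")
  }
  cat("\n")
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint is a single archive holding all parameter tensors keyed by
#' component, the config that produced them, and the training log. Loading
#' re-validates every parameter shape against the stored config and fails
#' loudly on mismatch.
#'
#' @param model A `dann_model`.
#' @param path Checkpoint file path.
#' @return `save_checkpoint()` returns `path` invisibly; `load_checkpoint()`
#'   returns the `dann_model`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "dann_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  model <- readRDS(path)
  if (!inherits(model, "dann_model")) stop("not a dann_model checkpoint: ", path)
  cfg <- model$config
  check_theta_shapes(model$theta_f, cfg, "theta_f")
  check_theta_shapes(model$theta_l, cfg, "theta_l")
  check_theta_shapes(model$theta_d, cfg, "theta_d")
  model
}
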