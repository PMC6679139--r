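# Validated hyperparameter record for the adversarial TFBS network.

#' Architecture and optimization hyperparameters
#'
#' Collects every tunable of the network and its training loop in one
#' validated record. Defaults follow the published configuration: two
#' convolution layers with 32 and 48 kernels of size 5 (stride 1), each
#' followed by max pooling of size 5 (stride 2); dropout with drop
#' probability 0.7 before the label predictor's first fully connected layer;
#' fully connected width 100; domain-adaptation weight `alpha = 1`; momentum
#' SGD with momentum 0.9, learning rate 0.001 and batch size 128; and the
#' logistic gradient-reversal ramp constant `grl_gamma = 10`.
#'
#' @param n_kernels_1,n_kernels_2 Kernel counts of the two convolution layers.
#' @param kernel_size Convolution window size (bases).
#' @param pool_size Max-pooling window size.
#' @param conv_stride,pool_stride Strides of convolution and pooling.
#' @param dropout_rate Probability of zeroing a feature during training,
#'   in `[0, 1)`.
#' @param fc_width Width of the fully connected layers.
#' @param alpha Weight of the domain loss in the total loss (`>= 0`);
#'   `alpha = 0` reduces training exactly to the no-adversary baseline
#'   objective.
#' @param grl_gamma Steepness constant of the adversarial ramp
#'   `lambda(p) = 2 / (1 + exp(-grl_gamma * p)) - 1`.
#' @param batch_size Training batch size.
#' @param momentum,learning_rate Momentum-SGD parameters.
#' @param max_epochs Upper bound on training epochs.
#' @param patience Early-stopping patience (epochs without validation AUC
#'   improvement).
#' @param seq_len Input window length (101 bp).
#' @param seed Integer seed controlling initialization, batching and dropout.
#' @param lambda_p Reversal-strength progress parameter. `NULL` (default)
#'   anneals `p` with training progress, the fraction of optimizer steps
#'   completed; a fixed value in `[0, 1]` holds `p` (hence `lambda`)
#'   constant throughout training. Both readings of the schedule are in
#'   circulation; the annealed form is the default.
#' @return A validated list of class `dann_config`.
#' @export
dann_config <- function(n_kernels_1 = 32L, n_kernels_2 = 48L,
                        kernel_size = 5L, pool_size = 5L,
                        conv_stride = 1L, pool_stride = 2L,
                        dropout_rate = 0.7, fc_width = 100L,
                        alpha = 1.0, grl_gamma = 10,
                        batch_size = 128L, momentum = 0.9,
                        learning_rate = 0.001, max_epochs = 60L,
                        patience = 5L, seq_len = 101L, seed = 1L,
                        lambda_p = NULL) {
  cfg <- list(
    n_kernels_1 = as.integer(n_kernels_1),
    n_kernels_2 = as.integer(n_kernels_2),
    kernel_size = as.integer(kernel_size),
    pool_size = as.integer(pool_size),
    conv_stride = as.integer(conv_stride),
    pool_stride = as.integer(pool_stride),
    dropout_rate = as.numeric(dropout_rate),
    fc_width = as.integer(fc_width),
    alpha = as.numeric(alpha),
    grl_gamma = as.numeric(grl_gamma),
    batch_size = as.integer(batch_size),
    momentum = as.numeric(momentum),
    learning_rate = as.numeric(learning_rate),
    max_epochs = as.integer(max_epochs),
    patience = as.integer(patience),
    seq_len = as.integer(seq_len),
    seed = as.integer(seed),
    lambda_p = if (!is.null(lambda_p)) as.numeric(lambda_p)
  )
  counts <- c("n_kernels_1", "n_kernels_2", "kernel_size", "pool_size",
              "conv_stride", "pool_stride", "fc_width", "batch_size",
              "max_epochs", "patience", "seq_len")
  for (f in counts) {
    if (is.na(cfg[[f]]) || cfg[[f]] < 1L) stop(f, " must be a positive count")
  }
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    stop("dropout_rate must be in [0, 1)")
  }
  if (cfg$alpha < 0) stop("alpha must be >= 0")
  if (cfg$learning_rate <= 0) stop("learning_rate must be positive")
  if (cfg$momentum < 0 || cfg$momentum >= 1) stop("momentum must be in [0, 1)")
  if (!is.null(cfg$lambda_p) && (cfg$lambda_p < 0 || cfg$lambda_p > 1)) {
    stop("lambda_p must lie in [0, 1] (or NULL for annealing)")
  }
  structure(cfg, class = "dann_config")
}

#' @export
print.dann_config <- function(x, ...) {
  dims <- dann_dims(x)
  cat("dann_config: conv ", x$n_kernels_1, "+", x$n_kernels_2,
      " kernels (size ", x$kernel_size, "), pool ", x$pool_size,
      " (stride ", x$pool_stride, "), fc ", x$fc_width,
      ", dropout ", x$dropout_rate, ", alpha ", x$alpha, "\n",
      "position chain ", x$seq_len, " -> ", dims$conv1, " -> ", dims$pool1,
      " -> ", dims$conv2, " -> ", dims$pool2,
      " (feature width ", dims$feat, ")\n", sep = "")
  invisible(x)
}

# Valid-padding dimension chain of the feature extractor; the feature width
# is a pure function of the config.
dann_dims <- function(cfg) {
  conv_out <- function(l) (l - cfg$kernel_size) %/% cfg$conv_stride + 1L
  pool_out <- function(l) (l - cfg$pool_size) %/% cfg$pool_stride + 1L
  c1 <- conv_out(cfg$seq_len)
  p1 <- pool_out(c1)
  c2 <- conv_out(p1)
  p2 <- pool_out(c2)
  if (min(c1, p1, c2, p2) < 1L) {
    stop("config yields an empty feature map (sequence too short for the ",
         "kernel/pool sizes)")
  }
  list(conv1 = c1, pool1 = p1, conv2 = c2, pool2 = p2,
       feat = p2 * cfg$n_kernels_2)
}
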