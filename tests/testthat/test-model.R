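test_that("feature width follows the valid-padding dimension chain", {
  cfg <- dann_config()   # published sizes
  dims <- danntf:::dann_dims(cfg)
  expect_identical(
    unlist(dims),
    c(conv1 = 97L, pool1 = 47L, conv2 = 43L, pool2 = 20L, feat = 960L))

  cfg_small <- dann_config(n_kernels_1 = 8L, n_kernels_2 = 12L)
  expect_identical(danntf:::dann_dims(cfg_small)$feat, 240L)

  set.seed(1)
  params <- init_dann_params(cfg_small)
  z <- feature_extractor(random_dna(3), params$theta_f, cfg_small)
  expect_identical(dim(z), c(240L, 3L))
})

test_that("all-zero input with zero parameters yields all-zero features", {
  cfg <- tiny_config()
  params <- init_dann_params(cfg, zero = TRUE)
  z <- feature_extractor(strrep("N", 101), params$theta_f, cfg)
  expect_true(all(z == 0))
})

test_that("first conv layer matches a sliding-window correlation oracle", {
  cfg <- tiny_config()
  set.seed(4)
  seq <- random_dna(1)
  x <- danntf:::encode_seq_matrix(seq)
  W <- matrix(rnorm(20 * 3), 20, 3)
  b <- rnorm(3)
  out <- danntf:::conv_forward(x, W, b, C = 4L, L = 101L, M = 5L, stride = 1L)

  onehot <- one_hot_encode(seq)
  for (k in 1:3) {
    kern <- matrix(W[, k], nrow = 4)       # 4 x 5, channel-fastest layout
    for (i in c(1, 37, 97)) {
      ref <- max(0, sum(kern * onehot[, i:(i + 4)]) + b[k])
      expect_equal(out$out[k, i], ref, tolerance = 1e-12)
    }
  }

  # a kernel that exactly matches a planted 5-mer peaks at the plant site
  probe <- paste0(strrep("A", 40), "TGCGT", strrep("A", 56))
  xp <- danntf:::encode_seq_matrix(probe)
  kern <- as.vector(one_hot_encode(paste0("TGCGT", strrep("N", 96)))[, 1:5])
  Wp <- cbind(kern - 0.2)   # penalize mismatches so the match dominates
  op <- danntf:::conv_forward(xp, Wp, 0, C = 4L, L = 101L, M = 5L, stride = 1L)
  expect_identical(which.max(op$out[1L, ]), 41L)
})

test_that("label predictor emits a valid two-class simplex", {
  cfg <- tiny_config()
  params <- init_dann_params(cfg, zero = TRUE)
  feat_w <- danntf:::dann_dims(cfg)$feat
  z <- matrix(rnorm(feat_w * 10), feat_w, 10)
  p <- label_predictor(z, params$theta_l, cfg)
  expect_true(all(p == 0.5))   # zero logits -> exactly uniform

  set.seed(2)
  params <- init_dann_params(cfg)
  for (rep in 1:5) {
    z <- matrix(rnorm(feat_w * 200, sd = 2), feat_w, 200)
    p <- label_predictor(z, params$theta_l, cfg)
    expect_true(all(p > 0 & p < 1))
    expect_true(all(abs(colSums(p) - 1) < 1e-6))
  }

  # raising the TFBS logit (bias) strictly raises the TFBS probability
  p0 <- label_predictor(z, params$theta_l, cfg)
  params$theta_l$b3[1] <- params$theta_l$b3[1] + 0.5
  p1 <- label_predictor(z, params$theta_l, cfg)
  expect_true(all(p1["TFBS", ] > p0["TFBS", ]))

  expect_error(label_predictor(z[-1, ], params$theta_l, cfg), "mismatch")
})

test_that("gradient reversal is the identity forward and -lambda x gradient backward", {
  set.seed(3)
  z <- matrix(rnorm(40), 8, 5)
  expect_identical(grad_reverse(z, 1), z)          # bit-exact identity
  expect_identical(grad_reverse(z, 0.37), z)

  # downstream loss = sum(z): gradient at the input is all -lambda
  expect_equal(grad_reverse_backward(matrix(1, 8, 5), 1),
               matrix(-1, 8, 5))

  # random quadratic downstream loss, central finite differences
  A <- matrix(rnorm(64), 8, 8)
  Q <- crossprod(A) / 8
  loss <- function(z) sum(diag(t(z) %*% Q %*% z)) / 2
  g_ana <- Q %*% z                                 # d loss / d (grl output)
  eps <- 1e-5
  for (lambda in c(0, 0.37, 1)) {
    g_in <- grad_reverse_backward(g_ana, lambda)
    for (i in sample(length(z), 10)) {
      zp <- z; zp[i] <- zp[i] + eps
      zm <- z; zm[i] <- zm[i] - eps
      fd <- (loss(zp) - loss(zm)) / (2 * eps)
      expect_equal(g_in[i], -lambda * fd, tolerance = 1e-4)
    }
  }
  expect_error(grad_reverse(z, -0.1), ">= 0")
})

test_that("the adversarial ramp is the documented logistic in p", {
  expect_identical(lambda_schedule(0), 0)          # 2/(1+1) - 1, exactly
  # independent closed form: 2/(1+exp(-10p)) - 1 == tanh(5p)
  expect_equal(lambda_schedule(1), tanh(5), tolerance = 1e-12)
  expect_equal(lambda_schedule(0.3), tanh(1.5), tolerance = 1e-12)
  grid <- lambda_schedule(seq(0, 1, length.out = 100))
  expect_true(all(diff(grid) > 0))
  expect_error(lambda_schedule(1.01), "\\[0, 1\\]")
  expect_error(lambda_schedule(-0.01), "\\[0, 1\\]")
})

test_that("domain classifier outputs a simplex and routes through the GRL", {
  cfg <- tiny_config()
  feat_w <- danntf:::dann_dims(cfg)$feat
  params <- init_dann_params(cfg, zero = TRUE)
  z <- matrix(rnorm(feat_w * 7), feat_w, 7)
  p <- domain_classifier(z, params$theta_d, cfg, lambda = 1)
  expect_true(all(p == 0.5))

  set.seed(5)
  params <- init_dann_params(cfg)
  p <- domain_classifier(z, params$theta_d, cfg, lambda = 0.5)
  expect_true(all(abs(colSums(p) - 1) < 1e-6))
  expect_identical(rownames(p), c("target", "source"))
})

test_that("feature-extractor domain gradient is the -lambda multiple of the unreversed one", {
  cfg <- tiny_config(dropout_rate = 0)
  set.seed(6)
  params <- init_dann_params(cfg)
  X <- danntf:::encode_seq_matrix(random_dna(8))
  y <- rep(NA_integer_, 8)                  # isolate the domain path
  d <- rep(c(1L, 2L), 4)

  g1 <- suppressWarnings(danntf:::dann_step_grads(
    params, X, y, d, lambda = 1, cfg, training = FALSE))
  g037 <- suppressWarnings(danntf:::dann_step_grads(
    params, X, y, d, lambda = 0.37, cfg, training = FALSE))
  for (nm in names(g1$grads$theta_f)) {
    expect_equal(g037$grads$theta_f[[nm]], 0.37 * g1$grads$theta_f[[nm]],
                 tolerance = 1e-10)
  }
  # theta_d gradients do not carry lambda (the reversal sits below them)
  for (nm in names(g1$grads$theta_d)) {
    expect_equal(g037$grads$theta_d[[nm]], g1$grads$theta_d[[nm]],
                 tolerance = 1e-12)
  }

  # against central finite differences of the plain domain cross entropy
  dom_loss_at <- function(pp) {
    ff <- danntf:::feature_forward(pp$theta_f, X, cfg)
    df <- danntf:::domain_forward(pp$theta_d, ff$feat)
    -mean(log(df$probs[cbind(d, seq_along(d))]))
  }
  eps <- 1e-5
  for (nm in c("W1", "W2")) {
    idx <- sample(length(params$theta_f[[nm]]), 6)
    for (i in idx) {
      pp <- params; pp$theta_f[[nm]][i] <- pp$theta_f[[nm]][i] + eps
      pm <- params; pm$theta_f[[nm]][i] <- pm$theta_f[[nm]][i] - eps
      fd <- (dom_loss_at(pp) - dom_loss_at(pm)) / (2 * eps)
      expect_equal(g1$grads$theta_f[[nm]][i], -fd, tolerance = 1e-4)
    }
  }
})

test_that("scoring is deterministic, batch-consistent and 0.5 for a zero model", {
  cfg <- tiny_config()
  model <- danntf:::new_dann_model(init_dann_params(cfg, zero = TRUE), cfg)
  seqs <- random_dna(6, seed = 12)
  expect_identical(score(seqs, model), rep(0.5, 6))

  set.seed(13)
  model <- danntf:::new_dann_model(init_dann_params(cfg), cfg)
  s1 <- score(seqs, model)
  s2 <- score(seqs, model)
  expect_identical(s1, s2)                       # bit-identical replays
  per_item <- vapply(seqs, function(s) score(s, model), numeric(1))
  expect_equal(unname(per_item), s1, tolerance = 1e-12)
})

test_that("checkpoints round-trip and shape corruption fails loudly", {
  cfg <- tiny_config()
  set.seed(14)
  model <- danntf:::new_dann_model(init_dann_params(cfg), cfg)
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  back <- load_checkpoint(path)
  expect_identical(back$theta_f, model$theta_f)
  expect_identical(score(random_dna(3, seed = 2), back),
                   score(random_dna(3, seed = 2), model))

  broken <- model
  broken$theta_l$W1 <- broken$theta_l$W1[-1, ]
  save_checkpoint(broken, path)
  expect_error(load_checkpoint(path), "shape mismatch")
})
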