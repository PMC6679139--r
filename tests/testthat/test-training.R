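test_that("prediction loss matches hand-computed cross entropy", {
  perfect <- matrix(c(1, 0, 0, 1), 2, 2)   # saturated at the true labels
  expect_equal(prediction_loss(perfect, c("positive", "negative")), 0)

  uniform <- matrix(0.5, 2, 4)
  expect_equal(prediction_loss(uniform, rep(c("positive", "negative"), 2)),
               log(2))

  # raising a correct-class probability lowers the loss
  p1 <- matrix(c(0.6, 0.4), 2, 1)
  p2 <- matrix(c(0.8, 0.2), 2, 1)
  expect_lt(prediction_loss(p2, "positive"), prediction_loss(p1, "positive"))

  # unlabeled items are excluded; all-unlabeled batches contribute 0
  mix <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2)
  expect_equal(prediction_loss(mix, c("positive", NA)), -log(0.9))
  expect_warning(z <- prediction_loss(uniform, rep(NA, 4)), "no labeled")
  expect_equal(z, 0)
})

test_that("domain loss is the plain mean cross entropy over all items", {
  perfect <- matrix(c(1, 0, 0, 1), 2, 2)
  expect_equal(domain_loss(perfect, c("target", "source")), 0)
  uniform <- matrix(0.5, 2, 6)
  expect_equal(domain_loss(uniform, rep(c("target", "source"), 3)), log(2))
  expect_error(domain_loss(uniform, c("target", NA, rep("source", 4)))
               , "domain label")
})

test_that("total loss is pred + alpha * dom, reducing to the baseline at alpha 0", {
  expect_equal(total_loss(0.7, 0.3, 1), 1.0)
  expect_identical(total_loss(0.123456, 99, 0), 0.123456)
  expect_error(total_loss(1, 1, -0.5), ">= 0")
})

test_that("label-predictor gradients are independent of the domain loss", {
  cfg <- tiny_config(dropout_rate = 0)
  set.seed(31)
  params <- init_dann_params(cfg)
  X <- danntf:::encode_seq_matrix(random_dna(8))
  y <- rep(c(1L, 2L), 4)
  d <- rep(c(1L, 2L), each = 4)
  with_adv <- danntf:::dann_step_grads(params, X, y, d, lambda = 0.8, cfg,
                                       training = FALSE, use_adversary = TRUE)
  without <- danntf:::dann_step_grads(params, X, y, d, lambda = 0.8, cfg,
                                      training = FALSE, use_adversary = FALSE)
  expect_identical(with_adv$grads$theta_l, without$grads$theta_l)
})

test_that("masked items contribute zero gradient to the label predictor", {
  cfg <- tiny_config(dropout_rate = 0)
  set.seed(32)
  params <- init_dann_params(cfg)
  seqs <- random_dna(8)
  X <- danntf:::encode_seq_matrix(seqs)
  y_masked <- c(1L, 2L, NA, NA, 1L, 2L, NA, NA)
  d <- rep(1L, 8)
  full <- suppressWarnings(danntf:::dann_step_grads(
    params, X, y_masked, d, 0, cfg, training = FALSE, use_adversary = FALSE))
  lab <- which(!is.na(y_masked))
  sub <- danntf:::dann_step_grads(
    params, X[, lab], y_masked[lab], d[lab], 0, cfg,
    training = FALSE, use_adversary = FALSE)
  for (nm in names(full$grads$theta_l)) {
    expect_equal(full$grads$theta_l[[nm]], sub$grads$theta_l[[nm]],
                 tolerance = 1e-12)
  }
})

test_that("batch plans respect regime label masking and domain composition", {
  cfg <- dann_config(batch_size = 128L, seed = 5L)
  t_labels <- rep(c("positive", "negative"), 500)
  s_labels <- rep(c("positive", "negative"), 600)

  plans <- make_batches(t_labels, s_labels, training_regime("cross_cell_type"),
                        cfg, epoch = 1L, total_epochs = 3L)
  for (pl in plans) {
    expect_length(pl$target_idx, 64L)
    expect_length(pl$source_idx, 64L)
    expect_identical(pl$d, c(rep(1L, 64), rep(2L, 64)))
    expect_true(all(is.na(pl$y[1:64])))          # target labels masked
    expect_false(anyNA(pl$y[65:128]))            # source always labeled
  }
  # p is the fraction of total steps completed, starting at 0
  expect_identical(plans[[1]]$p, 0)
  expect_true(all(diff(vapply(plans, `[[`, numeric(1), "p")) > 0))

  # semi-supervised: exactly the seeded fixed subset ever appears labeled
  ids <- semi_labeled_ids(1000L, 0.2, seed = 7L)
  expect_length(ids, 200L)
  seen <- integer(0)
  for (epoch in 1:3) {
    plans <- make_batches(t_labels, s_labels,
                          training_regime("semi_supervised",
                                          labeled_fraction = 0.2),
                          cfg, epoch, 3L, labeled_ids = ids)
    for (pl in plans) {
      seen <- union(seen, pl$target_idx[!is.na(pl$y[1:64])])
    }
  }
  expect_setequal(seen, ids)

  # baseline: source-only full batches
  plans <- make_batches(character(0), s_labels,
                        training_regime("supervised_baseline"), cfg, 1L, 1L)
  expect_true(all(vapply(plans, function(p) length(p$target_idx), 1L) == 0L))
  expect_true(all(vapply(plans, function(p) all(p$d == 2L), TRUE)))

  expect_error(make_batches(t_labels, character(0),
                            training_regime("cross_cell_type"), cfg, 1L, 1L),
               "source")
})

test_that("alpha = 0 adversarial training equals baseline training bit for bit", {
  d_target <- toy_dataset(60, seed = 41)
  d_source <- toy_dataset(60, seed = 42, domain_label = "source")
  val <- toy_dataset(20, seed = 43)
  cfg <- tiny_config(alpha = 0, max_epochs = 2L, patience = 2L, seed = 9L)

  m_adv <- train_dann(d_target, d_source,
                      training_regime("data_augmentation"), cfg,
                      val_data = val)
  m_base <- train_dann(d_target, d_source,
                       training_regime("data_augmentation",
                                       use_adversary = FALSE), cfg,
                       val_data = val)
  expect_identical(m_adv$theta_f, m_base$theta_f)
  expect_identical(m_adv$theta_l, m_base$theta_l)
  expect_identical(m_adv$training_log$pred_loss, m_base$training_log$pred_loss)
  expect_identical(m_adv$training_log$val_auc, m_base$training_log$val_auc)
})

test_that("seeded training runs are exactly reproducible", {
  d_target <- toy_dataset(50, seed = 51)
  d_source <- toy_dataset(50, seed = 52, domain_label = "source")
  cfg <- tiny_config(max_epochs = 2L, patience = 2L, seed = 77L)
  r <- training_regime("data_augmentation")
  m1 <- train_dann(d_target, d_source, r, cfg)
  m2 <- train_dann(d_target, d_source, r, cfg)
  expect_identical(m1$training_log, m2$training_log)
  expect_identical(m1$theta_f, m2$theta_f)
  expect_identical(m1$theta_d, m2$theta_d)
})

test_that("a plain supervised run on separable data reduces the training loss", {
  d <- toy_dataset(150, seed = 61)
  cfg <- dann_config(n_kernels_1 = 6L, n_kernels_2 = 8L, fc_width = 32L,
                     alpha = 0, batch_size = 64L, max_epochs = 8L,
                     patience = 8L, seed = 3L)
  m <- train_dann(d, NULL,
                  training_regime("data_augmentation", use_adversary = FALSE),
                  cfg)
  lg <- m$training_log
  expect_lt(mean(tail(lg$pred_loss, 2)), mean(head(lg$pred_loss, 2)))
})

test_that("training rejects configurations it cannot run", {
  d <- toy_dataset(30, seed = 71)
  cfg <- tiny_config(seed = 1L)
  expect_error(train_dann(d, NULL, training_regime("cross_cell_type"), cfg,
                          val_data = toy_dataset(10, seed = 72)),
               "source data")
  one_class <- d[d$binding_label == "positive", ]
  expect_error(train_dann(d, NULL,
                          training_regime("data_augmentation",
                                          use_adversary = FALSE),
                          cfg, val_data = one_class),
               "both binding classes")
})

test_that("regime records enforce their invariants", {
  expect_identical(training_regime("cross_cell_type")$labeled_fraction, 0)
  expect_identical(training_regime("data_augmentation")$labeled_fraction, 1)
  expect_false(training_regime("supervised_baseline")$use_adversary)
  expect_error(training_regime("semi_supervised"), "labeled_fraction")
  expect_error(training_regime("semi_supervised", labeled_fraction = 1.2),
               "\\[0, 1\\]")
})
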