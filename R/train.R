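# Adversarial training: composite loss, target/source batch mixing, the
# training regimes (data augmentation, semi-supervised, cross-cell-type) and
# the no-adversary baseline.
#
# Sign bookkeeping: the domain classifier parameters DESCEND the plain domain
# cross entropy (weighted by alpha), while the feature extractor receives
# that gradient through the reversal layer, i.e. multiplied by -lambda, so it
# ASCENDS the domain loss. The reported total loss is
# prediction_loss + alpha * domain_loss with the plain (unreversed) domain
# term; the adversarial sign lives entirely in the backward pass.

#' Describe a training regime
#'
#' @param mode One of `"data_augmentation"` (target fully labeled),
#'   `"semi_supervised"` (a seeded `labeled_fraction` of target items keep
#'   their labels), `"cross_cell_type"` (no target binding labels) or
#'   `"supervised_baseline"` (no adversary; trained on labeled source data
#'   only, mirroring a method that cannot use unlabeled data).
#' @param labeled_fraction Fraction of target training items carrying
#'   binding labels (used by `semi_supervised`; forced to 1 for
#'   `data_augmentation` and 0 for `cross_cell_type`).
#' @param use_adversary If `FALSE`, the domain classifier is neither trained
#'   nor allowed to influence the feature extractor. Forced off for
#'   `supervised_baseline`.
#' @return A validated list of class `training_regime`.
#' @export
training_regime <- function(mode = c("data_augmentation", "semi_supervised",
                                     "cross_cell_type",
                                     "supervised_baseline"),
                            labeled_fraction = NULL, use_adversary = TRUE) {
  mode <- match.arg(mode)
  labeled_fraction <- switch(mode,
    data_augmentation = 1.0,
    cross_cell_type = 0.0,
    supervised_baseline = 1.0,
    semi_supervised = {
      if (is.null(labeled_fraction)) {
        stop("semi_supervised requires labeled_fraction (e.g. 0.5, 0.2, 0.1)")
      }
      labeled_fraction
    })
  if (labeled_fraction < 0 || labeled_fraction > 1) {
    stop("labeled_fraction must be in [0, 1]")
  }
  if (mode == "supervised_baseline") use_adversary <- FALSE
  structure(list(mode = mode, labeled_fraction = as.numeric(labeled_fraction),
                 use_adversary = isTRUE(use_adversary)),
            class = "training_regime")
}

#' Prediction (binding) cross-entropy loss
#'
#' Mean cross entropy of the label predictor over the labeled items of a
#' batch. Items with `NA`/unknown labels are excluded; a batch with no
#' labeled items (routine for cross-cell-type target batches) contributes a
#' loss of 0 with a warning.
#'
#' @param probs `2 x B` probability matrix, row 1 = TFBS.
#' @param labels Character vector of `"positive"`/`"negative"` (or integer
#'   1/2); `NA` or `"unknown"` marks unlabeled items.
#' @return Nonnegative scalar; 0 iff predictions saturate at the true labels.
#' @export
prediction_loss <- function(probs, labels) {
  y <- as_label_int(labels)
  labeled <- !is.na(y)
  if (!any(labeled)) {
    warning("batch has no labeled items; prediction loss defined as 0")
    return(0)
  }
  -mean(log(pmax(probs[cbind(y[labeled], which(labeled))], 1e-300)))
}

#' Domain cross-entropy loss
#'
#' Plain mean cross entropy of the domain classifier over all items. The
#' adversarial `-lambda` factor is applied in the gradient reversal layer's
#' backward rule, not here, so the domain parameters descend this loss while
#' the feature extractor ascends it.
#'
#' @param probs `2 x B` probability matrix, row 1 = target.
#' @param domains Character vector of `"target"`/`"source"` (or integer 1/2).
#' @return Nonnegative scalar.
#' @export
domain_loss <- function(probs, domains) {
  d <- as_domain_int(domains)
  if (anyNA(d)) stop("every item must carry a domain label")
  -mean(log(pmax(probs[cbind(d, seq_along(d))], 1e-300)))
}

#' Composite training loss
#'
#' @param pred_loss Prediction loss value.
#' @param dom_loss Domain loss value.
#' @param alpha Nonnegative domain-adaptation weight; `alpha = 0` reduces
#'   exactly to the baseline objective.
#' @return `pred_loss + alpha * dom_loss`.
#' @export
total_loss <- function(pred_loss, dom_loss, alpha) {
  if (alpha < 0) stop("alpha must be >= 0")
  pred_loss + alpha * dom_loss
}

as_label_int <- function(labels) {
  if (is.numeric(labels)) return(ifelse(labels %in% c(1, 2), as.integer(labels),
                                        NA_integer_))
  y <- match(as.character(labels), c("positive", "negative"))
  y
}

as_domain_int <- function(domains) {
  if (is.numeric(domains)) return(as.integer(domains))
  match(as.character(domains), c("target", "source"))
}

#' Pick the fixed labeled subset for semi-supervised training
#'
#' Item-level and fixed once per run: the same seeded subset of target items
#' keeps its binding labels in every epoch.
#'
#' @param n_target Number of target training items.
#' @param fraction Labeled fraction in `[0, 1]`.
#' @param seed Integer seed.
#' @return Sorted integer vector of labeled target indices.
#' @export
semi_labeled_ids <- function(n_target, fraction, seed) {
  n_lab <- round(n_target * fraction)
  if (n_lab == 0L) return(integer(0))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  sort(sample.int(n_target, n_lab))
}

#' Plan the batches of one training epoch
#'
#' Adversarial modes mix every batch half-and-half: `batch_size/2` target
#' items and `batch_size/2` source items, reshuffled each epoch under a seed
#' derived from the config seed and the epoch number. Binding labels are
#' attached per regime: all target labels kept (data augmentation), only the
#' fixed `labeled_ids` subset kept (semi-supervised), or all target labels
#' masked (cross-cell-type); source items are always labeled. The
#' supervised baseline draws full batches from source data only. Each plan
#' carries `p`, the fraction of total optimizer steps completed before the
#' batch, from which the reversal strength is scheduled.
#'
#' @param target_labels,source_labels Binding labels of the target and source
#'   training items (`"positive"`/`"negative"`).
#' @param regime A [training_regime()].
#' @param config A [dann_config()].
#' @param epoch 1-based epoch number.
#' @param total_epochs Planned total number of epochs (fixes the step count
#'   that normalizes `p`).
#' @param labeled_ids Target indices keeping labels (semi-supervised).
#' @return A list of batch plans; each has `target_idx`, `source_idx`, `y`
#'   (integer binding labels, `NA` = masked, ordered target then source),
#'   `d` (integer domains, 1 target / 2 source) and `p`.
#' @export
make_batches <- function(target_labels, source_labels, regime, config,
                         epoch, total_epochs,
                         labeled_ids = integer(0)) {
  n_t <- length(target_labels)
  n_s <- length(source_labels)
  if (regime$mode != "supervised_baseline" && regime$use_adversary &&
      n_s == 0L) {
    stop("adversarial training needs nonempty source data")
  }
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer((as.numeric(config$seed) * 1009 + epoch * 7919) %%
                        2147483647))

  if (regime$mode == "supervised_baseline") {
    n_b <- max(1L, n_s %/% config$batch_size)
    ord <- sample.int(n_s)
    plans <- lapply(seq_len(n_b), function(i) {
      idx <- ord[((i - 1L) * config$batch_size + 1L):
                   min(i * config$batch_size, n_s)]
      list(target_idx = integer(0), source_idx = idx,
           y = as_label_int(source_labels[idx]),
           d = rep(2L, length(idx)), p = NA_real_)
    })
  } else if (n_s == 0L) {
    # degenerate target-only configuration (plain supervised CNN)
    y_t <- as_label_int(target_labels)
    if (regime$mode == "semi_supervised") {
      y_t[setdiff(seq_len(n_t), labeled_ids)] <- NA_integer_
    }
    n_b <- max(1L, n_t %/% config$batch_size)
    ord <- sample.int(n_t)
    plans <- lapply(seq_len(n_b), function(i) {
      ti <- ord[((i - 1L) * config$batch_size + 1L):
                  min(i * config$batch_size, n_t)]
      list(target_idx = ti, source_idx = integer(0),
           y = y_t[ti], d = rep(1L, length(ti)), p = NA_real_)
    })
  } else {
    half <- config$batch_size %/% 2L
    # an epoch covers the larger stream once; the smaller side is recycled,
    # so labeled-data exposure per epoch matches source-only training
    n_b <- max(1L, max(n_t, n_s) %/% half)
    ord_t <- sample.int(n_t)
    ord_s <- sample.int(n_s)
    need <- n_b * half
    ord_t <- rep_len(ord_t, need)
    ord_s <- rep_len(ord_s, need)
    y_t <- as_label_int(target_labels)
    if (regime$mode == "cross_cell_type") {
      y_t[] <- NA_integer_
    } else if (regime$mode == "semi_supervised") {
      y_t[setdiff(seq_len(n_t), labeled_ids)] <- NA_integer_
    }
    plans <- lapply(seq_len(n_b), function(i) {
      ti <- ord_t[((i - 1L) * half + 1L):(i * half)]
      si <- ord_s[((i - 1L) * half + 1L):(i * half)]
      list(target_idx = ti, source_idx = si,
           y = c(y_t[ti], as_label_int(source_labels[si])),
           d = c(rep(1L, half), rep(2L, half)), p = NA_real_)
    })
  }
  total_steps <- n_b * total_epochs
  offset <- (epoch - 1L) * n_b
  for (i in seq_along(plans)) {
    plans[[i]]$p <- (offset + i - 1L) / total_steps
  }
  plans
}

# One optimizer step's losses and gradients (no parameter update).
# X: (4*L) x B batch; y: integer binding labels with NA = unlabeled;
# d: integer domains. Exposed internally for gradient-check tests.
dann_step_grads <- function(params, X, y, d, lambda, cfg,
                            training = TRUE, use_adversary = TRUE) {
  ff <- feature_forward(params$theta_f, X, cfg)
  lf <- label_forward(params$theta_l, ff$feat, training, cfg$dropout_rate)

  labeled <- which(!is.na(y))
  n_lab <- length(labeled)
  if (n_lab > 0L) {
    pred_loss <- -mean(log(pmax(lf$probs[cbind(y[labeled], labeled)], 1e-300)))
    dlogits <- matrix(0, 2L, ncol(X))
    dlogits[, labeled] <- lf$probs[, labeled, drop = FALSE]
    dlogits[cbind(y[labeled], labeled)] <-
      dlogits[cbind(y[labeled], labeled)] - 1
    dlogits <- dlogits / n_lab
  } else {
    pred_loss <- 0
    dlogits <- matrix(0, 2L, ncol(X))
  }
  lb <- label_backward(params$theta_l, lf, dlogits)
  dfeat <- lb$dfeat

  dom_loss <- NA_real_
  dgrads <- NULL
  if (use_adversary) {
    df <- domain_forward(params$theta_d, ff$feat)
    dom_loss <- -mean(log(pmax(df$probs[cbind(d, seq_along(d))], 1e-300)))
    ddlogits <- df$probs
    ddlogits[cbind(d, seq_along(d))] <- ddlogits[cbind(d, seq_along(d))] - 1
    ddlogits <- cfg$alpha * ddlogits / ncol(X)
    db <- domain_backward(params$theta_d, df, ddlogits)
    dgrads <- db$grads
    # gradient reversal: the extractor ascends the domain loss
    dfeat <- dfeat + grad_reverse_backward(db$dfeat, lambda)
  }
  fgrads <- feature_backward(params$theta_f, ff, dfeat, cfg)

  list(pred_loss = pred_loss, dom_loss = dom_loss,
       grads = list(theta_f = fgrads, theta_l = lb$grads, theta_d = dgrads),
       n_labeled = n_lab)
}

sgd_momentum_update <- function(params, velocity, grads, lr, mom) {
  for (g in names(grads)) {
    if (is.null(grads[[g]])) next
    for (nm in names(grads[[g]])) {
      velocity[[g]][[nm]] <- mom * velocity[[g]][[nm]] - lr * grads[[g]][[nm]]
      params[[g]][[nm]] <- params[[g]][[nm]] + velocity[[g]][[nm]]
    }
  }
  list(params = params, velocity = velocity)
}

#' Train the adversarial TFBS network
#'
#' Runs momentum SGD over the composite loss for the requested regime and
#' returns the checkpoint with the best validation AUC. The run is fully
#' reproducible given `config$seed`: initialization, the per-epoch batch
#' shuffles, the semi-supervised label subset and every dropout mask all
#' derive from it.
#'
#' @param target_data Labeled-sequence data.frame of the target cell type
#'   (training portion). May be `NULL` for `supervised_baseline`.
#' @param source_data Labeled-sequence data.frame pooling all source cell
#'   types; `NULL` only for non-adversarial target-only training.
#' @param regime A [training_regime()].
#' @param config A [dann_config()].
#' @param val_data Labeled validation data from the target cell type; when
#'   `NULL`, a stratified `val_fraction` of `target_data` is held out.
#' @param val_fraction Fraction of target data carved out for validation
#'   when `val_data` is `NULL`.
#' @return A `dann_model` with the best-validation parameters, the config,
#'   the regime and a per-epoch `training_log` data.frame (prediction loss,
#'   domain loss, reversal strength, validation AUC).
#' @export
train_dann <- function(target_data, source_data = NULL, regime, config,
                       val_data = NULL, val_fraction = 0.1) {
  stopifnot(inherits(regime, "training_regime"),
            inherits(config, "dann_config"))
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)

  if (is.null(val_data)) {
    if (is.null(target_data) || nrow(target_data) < 10L) {
      stop("no validation data: supply val_data or enough target_data")
    }
    hold <- validation_holdout(target_data, val_fraction, config$seed)
    val_data <- target_data[hold, , drop = FALSE]
    target_data <- target_data[-hold, , drop = FALSE]
  }
  if (length(unique(as_label_int(val_data$binding_label))) < 2L) {
    stop("validation data must contain both binding classes")
  }

  adversarial <- regime$mode != "supervised_baseline"
  if (adversarial && regime$use_adversary &&
      (is.null(source_data) || nrow(source_data) == 0L)) {
    stop("adversarial training needs nonempty source data")
  }

  set.seed(config$seed)
  params <- init_dann_params(config)
  velocity <- rapply(params, function(x) x * 0, how = "replace")

  n_t <- if (is.null(target_data)) 0L else nrow(target_data)
  labeled_ids <- if (regime$mode == "semi_supervised") {
    semi_labeled_ids(n_t, regime$labeled_fraction, config$seed + 777L)
  } else integer(0)

  Xt <- if (n_t > 0L) encode_seq_matrix(target_data$seq, config$seq_len)
  Xs <- if (!is.null(source_data) && nrow(source_data) > 0L) {
    encode_seq_matrix(source_data$seq, config$seq_len)
  }
  t_labels <- if (n_t > 0L) target_data$binding_label else character(0)
  s_labels <- if (is.null(source_data)) character(0) else
    source_data$binding_label
  Xval <- encode_seq_matrix(val_data$seq, config$seq_len)
  yval <- as_label_int(val_data$binding_label)

  best <- list(params = params, val_auc = -Inf, epoch = 0L)
  log_rows <- vector("list", config$max_epochs)
  stall <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    plans <- make_batches(t_labels, s_labels, regime, config,
                          epoch, config$max_epochs, labeled_ids)
    pl_sum <- 0; dl_sum <- 0; dl_n <- 0L; lam <- 0
    for (plan in plans) {
      X <- cbind(
        if (length(plan$target_idx)) Xt[, plan$target_idx, drop = FALSE],
        if (length(plan$source_idx)) Xs[, plan$source_idx, drop = FALSE]
      )
      lam <- if (regime$use_adversary) {
        lambda_schedule(config$lambda_p %||% plan$p, config$grl_gamma)
      } else 0
      step <- dann_step_grads(params, X, plan$y, plan$d, lam, config,
                              training = TRUE,
                              use_adversary = regime$use_adversary)
      if (!is.finite(step$pred_loss) ||
          (regime$use_adversary && !is.finite(step$dom_loss))) {
        stop("training diverged at epoch ", epoch,
             " (non-finite loss); lower the learning rate")
      }
      upd <- sgd_momentum_update(params, velocity, step$grads,
                                 config$learning_rate, config$momentum)
      params <- upd$params
      velocity <- upd$velocity
      pl_sum <- pl_sum + step$pred_loss
      if (regime$use_adversary) {
        dl_sum <- dl_sum + step$dom_loss
        dl_n <- dl_n + 1L
      }
    }
    val_feat <- feature_forward(params$theta_f, Xval, config)$feat
    val_probs <- label_forward(params$theta_l, val_feat, FALSE, 0)$probs
    val_auc <- compute_auc(as.numeric(val_probs[1L, ]),
                           as.integer(yval == 1L))
    log_rows[[epoch]] <- data.frame(
      epoch = epoch,
      pred_loss = pl_sum / length(plans),
      dom_loss = if (dl_n > 0L) dl_sum / dl_n else NA_real_,
      lambda = lam,
      val_auc = val_auc
    )
    if (val_auc > best$val_auc) {
      best <- list(params = params, val_auc = val_auc, epoch = epoch)
      stall <- 0L
    } else {
      stall <- stall + 1L
      if (stall >= config$patience) break
    }
  }

  new_dann_model(best$params, config, regime,
                 training_log = do.call(rbind, log_rows),
                 best_epoch = best$epoch, val_auc = best$val_auc)
}

# Stratified seeded holdout indices for validation.
validation_holdout <- function(data, fraction, seed) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed) + 31L)
  labs <- data$binding_label
  unlist(lapply(unique(labs), function(l) {
    idx <- which(labs == l)
    take <- max(1L, round(length(idx) * fraction))
    sample(idx, take)
  }), use.names = FALSE)
}
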