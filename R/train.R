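## Cohort splitting, the Adam training loop with early stopping, and the
## restart-and-select-best protocol.

#' Training protocol configuration
#'
#' Defaults follow the reference protocol: Adam with learning rate 0.001 and
#' weight decay 0.001, batches of 100 bags, at most 1000 epochs with early
#' stopping after 40 consecutive epochs without validation-loss improvement,
#' and checkpoint selection by best validation AUC.
#'
#' @param learning_rate Adam step size.
#' @param weight_decay L2 coefficient added to the gradient.
#' @param batch_size TCR sequences (instances) per minibatch; bags are
#'   grouped so each optimiser step sees about this many sequences, so with
#'   the default bag size of 100 each step processes one bag.
#' @param max_epochs epoch budget.
#' @param patience consecutive non-improving validation epochs tolerated
#'   before stopping (0 = stop at the first non-improving epoch).
#' @param split_ratios train/validation/test proportions (default 6:2:2).
#' @param n_restarts independent restarts; the restart with the best
#'   validation selection metric wins (the reference protocol used 50).
#' @param seed base RNG seed; initialisation, shuffling and dropout derive
#'   from it deterministically.
#' @param selection_metric `"val_auc"` (default) or `"val_loss"`.
#' @param head_prior precision of the ridge prior shrinking each bag head's
#'   slot weights toward that head's own mean weight (i.e. toward a uniform,
#'   mean-pooling-like aggregation); rank-slot effects must be supported by
#'   the data to survive it, while each head's overall scale and intercept
#'   stay unpenalised. `weight_decay` applies to the remaining parameters.
#' @param aux_weight weight of the auxiliary per-sequence cross-entropy
#'   (each instance scored against its bag's label) added to the bag-level
#'   objective; stabilises credit assignment through the 1-max pooling at
#'   small cohort sizes. Set 0 for pure bag-level training.
#' @return an object of class `"train_config"`.
#' @export
train_config <- function(learning_rate = 0.001, weight_decay = 0.001,
                         batch_size = 100L, max_epochs = 1000L,
                         patience = min(40L, max_epochs),
                         split_ratios = c(6, 2, 2), n_restarts = 1L, seed = 1L,
                         selection_metric = c("val_auc", "val_loss"),
                         aux_weight = 1, head_prior = 0.1) {
  selection_metric <- match.arg(selection_metric)
  stopifnot(aux_weight >= 0, head_prior >= 0)
  stopifnot(learning_rate >= 0, weight_decay >= 0,
            is_count(batch_size), batch_size >= 1,
            is_count(max_epochs), max_epochs >= 1,
            is_count(patience), patience <= max_epochs,
            all(split_ratios >= 0), sum(split_ratios) > 0,
            is_count(n_restarts), n_restarts >= 1)
  structure(list(learning_rate = learning_rate, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 split_ratios = split_ratios / sum(split_ratios),
                 n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 selection_metric = selection_metric,
                 aux_weight = aux_weight, head_prior = head_prior),
            class = "train_config")
}

## Largest-remainder allocation of n items to the split ratios.
split_sizes <- function(n, ratios) {
  exact <- ratios * n
  base <- floor(exact)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(-(exact - base), seq_along(ratios))[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Split a cohort into train / validation / test sets
#'
#' Random, disjoint and exhaustive partition, reproducible given the seed.
#' With `stratified = TRUE` (default) the split is performed within each
#' class so class proportions are preserved up to rounding.
#'
#' @param cohort a `"tcr_cohort"`, `"embedded_cohort"` or plain list of bags.
#' @param ratios three non-negative proportions (default 6:2:2).
#' @param seed RNG seed.
#' @param stratified preserve class proportions within each split.
#' @return a list with `train`, `val`, `test` (same container type as the
#'   input) and `indices` (the integer indices of each split).
#' @export
split_cohort <- function(cohort, ratios = c(6, 2, 2), seed = 1L, stratified = TRUE) {
  bags <- cohort_bags(cohort)
  n <- length(bags)
  if (sum(ratios) <= 0) stopf("split ratios must sum to a positive value")
  ratios <- ratios / sum(ratios)
  labels <- vapply(bags, function(b) as.integer(b$label), integer(1))
  idx <- vector("list", 3L)
  strata <- if (stratified) split(seq_len(n), labels) else list(seq_len(n))
  with_seed(seed, {
    for (str in strata) {
      perm <- str[sample.int(length(str))]
      sz <- split_sizes(length(str), ratios)
      off <- cumsum(c(0L, sz))
      for (j in 1:3) {
        idx[[j]] <- c(idx[[j]], perm[seq_len(sz[j]) + off[j]])
      }
    }
  })
  idx <- lapply(idx, sort)
  out <- lapply(idx, function(i) subset_cohort(cohort, i))
  names(out) <- c("train", "val", "test")
  out$indices <- stats::setNames(idx, c("train", "val", "test"))
  out
}

cohort_bags <- function(cohort) {
  if (inherits(cohort, c("tcr_cohort", "embedded_cohort"))) cohort$bags else cohort
}

subset_cohort <- function(cohort, i) {
  if (inherits(cohort, "tcr_cohort")) {
    out <- cohort
    out$bags <- cohort$bags[i]
    out
  } else if (inherits(cohort, "embedded_cohort")) {
    structure(list(bags = cohort$bags[i], labels = cohort$labels[i],
                   sample_ids = cohort$sample_ids[i],
                   fingerprint = cohort$fingerprint),
              class = "embedded_cohort")
  } else {
    cohort[i]
  }
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, state, lr, decay_grad,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  grad <- grad + decay_grad
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = state)
}

#' Train a CME model
#'
#' Minibatch Adam on the bag-level cross-entropy (plus the weighted
#' auxiliary per-sequence loss), with per-epoch reshuffling, early stopping
#' on the validation objective, and checkpoint selection by the best
#' validation metric seen before the stop (ties to the epoch with the lower
#' validation objective). Fully reproducible given the seed.
#'
#' @param train,val `"embedded_cohort"` objects (or lists of embedded bags)
#'   with labels.
#' @param config a [cme_config()].
#' @param training a [train_config()].
#' @param init_params optional `"cme_params"` starting point; defaults to
#'   [cme_params_init()] seeded from `training$seed`.
#' @return list with `params` (the selected `"cme_params"`), `history`
#'   (class `"training_history"`: per-epoch train/validation loss and
#'   validation AUC, best epoch, stop reason) and `val_metric` (the
#'   selection metric value of the returned checkpoint).
#' @export
cme_train <- function(train, val, config, training = train_config(),
                      init_params = NULL) {
  tr_bags <- cohort_bags(train)
  cmp_bags <- lapply(tr_bags, function(b) cme_compile(list(b), config))
  cmp_val <- cme_compile(val, config)
  if (length(cmp_bags) == 0L || cmp_val$nb == 0L) stopf("train and validation sets must be non-empty")
  params0 <- init_params %||% cme_params_init(config, seed = training$seed)
  theta <- params_flatten(params0)
  decay <- make_decay(params0, config, training)
  state <- adam_init(length(theta))
  sel_auc <- training$selection_metric == "val_auc"
  hist_epoch <- integer(0); hist_train <- numeric(0)
  hist_val <- numeric(0); hist_auc <- numeric(0)
  best_sel <- -Inf; best_sel_obj <- Inf; best_theta <- theta; best_epoch <- 0L
  best_val_loss <- Inf; since <- 0L
  stop_reason <- "max_epochs"
  nb <- length(cmp_bags)
  use_dropout <- config$dropout_rate > 0
  ## batch_size counts sequences: group bags so one step sees ~batch_size TCRs
  bags_per_batch <- max(1L, training$batch_size %/% config$bag_size)
  for (epoch in seq_len(training$max_epochs)) {
    ep_loss <- 0
    with_seed(derive_seed(training$seed, epoch), {
      ord <- sample.int(nb)
      batches <- split(ord, ceiling(seq_along(ord) / bags_per_batch))
      for (batch in batches) {
        params <- params_unflatten(theta, params0)
        grad <- NULL
        for (b in batch) {
          cmp <- cmp_bags[[b]]
          drop_mask <- NULL; score_drop <- NULL
          if (use_dropout && config$dropout_where %in% c("pooled", "both")) {
            drop_mask <- matrix(stats::rbinom(cmp$n_inst * config$n_filters, 1L,
                                              1 - config$dropout_rate),
                                cmp$n_inst, config$n_filters)
          }
          if (use_dropout && config$dropout_where %in% c("scores", "both")) {
            score_drop <- stats::rbinom(cmp$n_inst, 1L, 1 - config$dropout_rate)
          }
          fw <- cme_forward_all(cmp, params, config, training = use_dropout,
                                drop_mask = drop_mask, score_drop = score_drop)
          bl <- if (config$task == "binary") {
            bag_loss(fw$Ybag, cmp$labels)
          } else {
            multiclass_loss(fw$scores[1, ], cmp$labels)
          }
          if (!is.finite(bl)) {
            stopf("training diverged: non-finite loss at epoch %d", epoch)
          }
          ep_loss <- ep_loss + bl / nb
          gb <- params_flatten(cme_backward_all(cmp, params, config, fw,
                                                wb = 1 / length(batch),
                                                drop_mask,
                                                aux_weight = training$aux_weight,
                                                score_drop = score_drop))
          grad <- if (is.null(grad)) gb else grad + gb
        }
        upd <- adam_step(theta, grad, state, training$learning_rate,
                         decay(theta))
        theta <- upd$theta
        state <- upd$state
      }
    })
    ev <- cme_eval(cmp_val, params_unflatten(theta, params0), config,
                   aux_weight = training$aux_weight)
    if (!is.finite(ev$objective)) {
      stopf("training diverged: non-finite validation loss at epoch %d", epoch)
    }
    hist_epoch <- c(hist_epoch, epoch)
    hist_train <- c(hist_train, ep_loss)
    hist_val <- c(hist_val, ev$loss)
    hist_auc <- c(hist_auc, ev$auc)
    ## multiclass has no single AUC; accuracy plays the selection role there
    sel_val <- if (!sel_auc) {
      -ev$loss
    } else if (config$task == "multiclass") {
      ev$accuracy
    } else if (!is.na(ev$auc)) {
      ev$auc
    } else {
      -ev$loss
    }
    ## ties on the selection metric go to the epoch with the better
    ## validation objective (calibration keeps improving after the AUC
    ## saturates)
    if (sel_val > best_sel ||
        (sel_val == best_sel && ev$objective < best_sel_obj)) {
      best_sel <- sel_val
      best_sel_obj <- ev$objective
      best_theta <- theta
      best_epoch <- epoch
    }
    if (ev$objective < best_val_loss) {
      best_val_loss <- ev$objective
      since <- 0L
    } else {
      since <- since + 1L
    }
    if (since >= max(training$patience, 1L)) {
      stop_reason <- "early_stopping"
      break
    }
  }
  history <- structure(
    list(epochs = data.frame(epoch = hist_epoch, train_loss = hist_train,
                             val_loss = hist_val, val_auc = hist_auc),
         best_epoch = best_epoch, stop_reason = stop_reason,
         selection_metric = training$selection_metric,
         best_value = best_sel),
    class = "training_history")
  list(params = params_unflatten(best_theta, params0), history = history,
       val_metric = best_sel)
}

#' @export
print.training_history <- function(x, ...) {
  n <- nrow(x$epochs)
  cat(sprintf("training history: %d epochs (%s), best epoch %d (%s = %.4f)\n",
              n, x$stop_reason, x$best_epoch, x$selection_metric, x$best_value))
  if (n > 0) {
    last <- x$epochs[n, ]
    cat(sprintf("  final: train loss %.4f, val loss %.4f, val AUC %s\n",
                last$train_loss, last$val_loss,
                ifelse(is.na(last$val_auc), "NA", sprintf("%.4f", last$val_auc))))
  }
  invisible(x)
}

#' Train with independent restarts and keep the best model
#'
#' Repeats [cme_train()] from `n_restarts` independently seeded
#' initialisations and returns the restart with the highest validation
#' selection metric (ties go to the lowest seed).
#'
#' @inheritParams cme_train
#' @param n_restarts number of restarts (defaults to `training$n_restarts`).
#' @param seeds optional explicit seed per restart; defaults to seeds derived
#'   from `training$seed`.
#' @return as [cme_train()], plus `restart_seeds`, `restart_metrics` and
#'   `best_seed`.
#' @export
cme_train_restarts <- function(train, val, config, training = train_config(),
                               n_restarts = training$n_restarts, seeds = NULL) {
  stopifnot(is_count(n_restarts), n_restarts >= 1)
  seeds <- seeds %||% vapply(seq_len(n_restarts) - 1L,
                             function(i) derive_seed(training$seed, i),
                             integer(1))
  stopifnot(length(seeds) == n_restarts)
  ord <- order(seeds)
  best <- NULL
  metrics <- numeric(n_restarts)
  fits <- vector("list", n_restarts)
  for (i in ord) {
    tc <- training
    tc$seed <- as.integer(seeds[i])
    fit <- cme_train(train, val, config, tc)
    fits[[i]] <- fit
    metrics[i] <- fit$val_metric
    if (is.null(best) || fit$val_metric > best$val_metric) {
      best <- fit
      best$best_seed <- seeds[i]
    }
  }
  best$restart_seeds <- seeds
  best$restart_metrics <- metrics
  best
}

## Regularisation gradient factory. Ordinary L2 (`weight_decay`) applies to
## the convolution and sequence-head parameters; the bag-head slot weights
## instead carry a ridge penalty on their deviation from the head's own mean
## weight (`head_prior`), i.e. a shrink-toward-uniform-aggregation prior that
## leaves the head's overall scale and intercept free to calibrate.
make_decay <- function(template, config, training) {
  strengths <- template
  for (si in seq_along(strengths$conv)) {
    strengths$conv[[si]]$W[] <- training$weight_decay
    strengths$conv[[si]]$b[] <- training$weight_decay
  }
  strengths$w_seq[] <- training$weight_decay
  strengths$b_seq[] <- training$weight_decay
  strengths$w_bag[] <- 0   # handled by the centred term below
  strengths$b_bag[] <- training$weight_decay
  svec <- params_flatten(strengths)
  ## locate the bag-head slot weights inside the flattened vector
  probe <- template
  for (si in seq_along(probe$conv)) {
    probe$conv[[si]]$W[] <- 0
    probe$conv[[si]]$b[] <- 0
  }
  probe$w_seq[] <- 0; probe$b_seq[] <- 0
  probe$b_bag[] <- 0
  probe$w_bag[] <- 1
  wb_idx <- which(params_flatten(probe) == 1)
  k <- config$bag_size
  n_heads_total <- length(wb_idx) %/% k
  hp <- training$head_prior
  function(theta) {
    g <- svec * theta
    w <- matrix(theta[wb_idx], k, n_heads_total)
    g[wb_idx] <- hp * as.numeric(w - rep(colMeans(w), each = k))
    g
  }
}
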