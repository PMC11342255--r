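## The user-facing fitted-model interface.

#' Fit a TCR-repertoire multiple-instance classifier
#'
#' Trains the convolutional multiple-instance ensemble (CME) classifier on a
#' labelled cohort of repertoire bags. Each bag's CDR3 sequences are
#' embedded per residue, scored by multi-scale convolutional filters with
#' 1-max pooling and a linear sequence head, and the bag's ordered score
#' vector is aggregated by an averaged ensemble of linear classifiers into a
#' cancer probability.
#'
#' @param x a labelled cohort: a `"tcr_cohort"`, a list of
#'   `"repertoire_bag"` objects, or an `"embedded_cohort"` (in which case
#'   `backend` is only recorded, not applied).
#' @param val optional validation cohort of the same type; when omitted, a
#'   stratified fraction `val_fraction` of `x` is held out for early
#'   stopping and model selection.
#' @param config a [cme_config()]; `embed_dim` defaults to the backend width.
#' @param training a [train_config()].
#' @param backend embedding backend used for non-embedded inputs and for
#'   embedding prediction data later (default [mini_encoder()]).
#' @param val_fraction held-out fraction when `val` is missing (default 0.25).
#' @return an object of class `"tcrmil"` with components `params`, `config`,
#'   `training`, `history`, `backend`, `fingerprint`, `val_metric`, plus
#'   fitted training-set scores. Supports `print`, `summary`, `coef`,
#'   `predict`, `fitted`, `residuals` and `plot`.
#' @examples
#' cfg <- sim_config(n_per_class = 6, clones_per_sample = 12, k = 10, seed = 1)
#' cohort <- generate_cohort(cfg)
#' backend <- mini_encoder(d_model = 8, n_layers = 1, n_heads = 2)
#' fit <- tcrmil(cohort, backend = backend,
#'               config = cme_config(bag_size = 10, embed_dim = 8, n_heads = 2),
#'               training = train_config(max_epochs = 3, batch_size = 4))
#' predict(fit, cohort)[1:2, ]
#' @export
tcrmil <- function(x, val = NULL, config = NULL, training = train_config(),
                   backend = NULL, val_fraction = 0.25) {
  cl <- match.call()
  backend <- backend %||% mini_encoder()
  if (is.null(config)) {
    config <- cme_config(embed_dim = backend$d_model)
  }
  emb <- function(obj) {
    if (inherits(obj, "embedded_cohort")) obj
    else embed_cohort(obj, backend, Lmax = config$Lmax)
  }
  if (is.null(val)) {
    parts <- split_cohort(x, ratios = c(1 - val_fraction, val_fraction, 0),
                          seed = derive_seed(training$seed, 7919L))
    train_set <- emb(parts$train)
    val_set <- emb(parts$val)
  } else {
    train_set <- emb(x)
    val_set <- emb(val)
  }
  fit <- cme_train_restarts(train_set, val_set, config, training)
  cmp <- cme_compile(train_set, config)
  ev <- cme_eval(cmp, fit$params, config)
  structure(list(params = fit$params, config = config, training = training,
                 history = fit$history, val_metric = fit$val_metric,
                 restart_seeds = fit$restart_seeds,
                 restart_metrics = fit$restart_metrics,
                 backend = backend, fingerprint = backend_fingerprint(backend),
                 fitted_scores = ev$scores,
                 train_labels = cmp$labels,
                 n_train = cmp$nb, n_val = length(cohort_bags(val_set)),
                 call = cl),
            class = "tcrmil")
}

#' @export
print.tcrmil <- function(x, ...) {
  cat("CME repertoire classifier\n")
  cat(sprintf("  %s task, %d train / %d validation bags, backend %s (D=%d)\n",
              x$config$task, x$n_train, x$n_val, x$fingerprint$name,
              x$config$embed_dim))
  cat(sprintf("  kernels (%s) x filters (%s), %d-head %s aggregation\n",
              paste(x$config$kernel_sizes, collapse = ","),
              paste(x$config$filters_per_size, collapse = ","),
              x$config$n_heads, x$config$aggregation))
  cat(sprintf("  best %s %.4f at epoch %d of %d (%s)\n",
              x$history$selection_metric, x$val_metric, x$history$best_epoch,
              nrow(x$history$epochs), x$history$stop_reason))
  invisible(x)
}

#' @export
summary.tcrmil <- function(object, ...) {
  structure(list(model = object,
                 n_params = length(params_flatten(object$params)),
                 history = object$history,
                 train_accuracy = mean(
                   (object$fitted_scores > object$config$decision_threshold) ==
                     (object$train_labels == 1L))),
            class = "summary.tcrmil")
}

#' @export
print.summary.tcrmil <- function(x, ...) {
  print(x$model)
  cat(sprintf("  %d trainable parameters, training-set accuracy %.3f\n",
              x$n_params, x$train_accuracy))
  print(x$history)
  invisible(x)
}

#' @export
coef.tcrmil <- function(object, ...) object$params

#' @export
fitted.tcrmil <- function(object, ...) object$fitted_scores

#' @export
residuals.tcrmil <- function(object, ...) {
  if (object$config$task != "binary") {
    stopf("residuals are defined for the binary task")
  }
  object$train_labels - object$fitted_scores
}

#' Predict cancer and health scores for new repertoires
#'
#' @param object a fitted `"tcrmil"` model.
#' @param newdata a cohort (`"tcr_cohort"`, list of bags, or
#'   `"embedded_cohort"`); non-embedded input is embedded with the model's
#'   backend.
#' @param type `"response"` (default) returns a data frame with per-sample
#'   cancer score, health score and decision; `"score"` returns the numeric
#'   cancer scores; `"class"` the 0/1 (or multiclass) decisions; `"health"`
#'   the health scores.
#' @param ... unused.
#' @return see `type`.
#' @export
predict.tcrmil <- function(object, newdata,
                           type = c("response", "score", "class", "health"), ...) {
  type <- match.arg(type)
  eco <- if (inherits(newdata, "embedded_cohort")) {
    newdata
  } else {
    if (is.null(object$backend)) {
      stopf("this model stores no embedding backend; supply an embedded cohort")
    }
    embed_cohort(newdata, object$backend, Lmax = object$config$Lmax)
  }
  cmp <- cme_compile(eco, object$config)
  fw <- cme_forward_all(cmp, object$params, object$config, training = FALSE)
  if (object$config$task == "binary") {
    scores <- fw$Ybag
    decision <- as.integer(scores > object$config$decision_threshold)
    res <- data.frame(sample_id = eco$sample_ids, cancer_score = scores,
                      health_score = health_score(scores), decision = decision,
                      stringsAsFactors = FALSE)
  } else {
    scores <- fw$scores
    decision <- fw$class
    res <- data.frame(sample_id = eco$sample_ids, decision = decision,
                      stringsAsFactors = FALSE)
    res <- cbind(res, as.data.frame(scores))
    names(res)[-(1:2)] <- paste0("score_class", seq_len(ncol(scores)) - 1L)
  }
  switch(type,
         response = res,
         score = scores,
         class = decision,
         health = health_score(fw$Ybag))
}

#' @export
plot.tcrmil <- function(x, ...) {
  h <- x$history$epochs
  if (nrow(h) == 0L) return(invisible(x))
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$val_loss), type = "l",
                    lty = 1, col = c("black", "firebrick"),
                    xlab = "epoch", ylab = "loss", main = "bag cross-entropy")
  graphics::legend("topright", c("train", "validation"), lty = 1,
                   col = c("black", "firebrick"), bty = "n")
  graphics::plot(h$epoch, h$val_auc, type = "l", xlab = "epoch",
                 ylab = "validation AUC", main = "model selection")
  graphics::abline(v = x$history$best_epoch, lty = 2)
  invisible(x)
}

#' Save / load a model checkpoint
#'
#' The checkpoint stores the architecture configuration, learned weights,
#' embedding-backend fingerprint and training seed, and is sufficient for
#' inference without the training data.
#'
#' @param object a `"tcrmil"` model.
#' @param path checkpoint file path.
#' @return `write_checkpoint` returns the path invisibly; `read_checkpoint`
#'   the `"tcrmil"` object.
#' @export
write_checkpoint <- function(object, path) {
  stopifnot(inherits(object, "tcrmil"))
  saveRDS(list(format = "tcrmil-checkpoint", version = 1L, model = object), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "tcrmil-checkpoint")) stopf("not a model checkpoint: %s", path)
  x$model
}
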