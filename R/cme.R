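## The convolutional multiple-instance ensemble (CME) predictor: multi-scale
## convolution over per-residue embeddings, 1-max pooling, per-sequence
## scoring, and bag aggregation through an averaged linear ensemble.

#' CME architecture configuration
#'
#' @param kernel_sizes convolution kernel heights in residues (default 2, 3, 4).
#' @param filters_per_size number of filters at each kernel size (default
#'   3, 2, 1, giving 6 pooled features per sequence).
#' @param dropout_rate dropout on the pooled feature vector during training
#'   (default 0.40).
#' @param n_heads number of linear classifiers in the bag-level ensemble
#'   (default 5); their outputs are averaged.
#' @param bag_size instances per bag, `k` (default 100).
#' @param Lmax padded sequence length (default 24).
#' @param embed_dim embedding width `D` per residue.
#' @param task `"binary"` or `"multiclass"`.
#' @param n_classes number of classes for the multiclass head.
#' @param decision_threshold bag-probability threshold for calling cancer
#'   (default 0.5).
#' @param aggregation `"ensemble"` (default) averages the `n_heads` linear
#'   classifiers inside a sigmoid; `"single"` forces one head; `"mean"` is
#'   the unweighted mean of the per-sequence scores (the mean-pooling
#'   baseline arm, no learned bag weights).
#' @param dropout_where where the dropout mask is applied during training:
#'   `"pooled"` (default) on the pooled feature vector before the sequence
#'   head, `"scores"` on the instance-score vector entering the bag heads,
#'   or `"both"`.
#' @return an object of class `"cme_config"`.
#' @export
cme_config <- function(kernel_sizes = c(2L, 3L, 4L),
                       filters_per_size = c(3L, 2L, 1L),
                       dropout_rate = 0.40, n_heads = 5L, bag_size = 100L,
                       Lmax = 24L, embed_dim = 32L,
                       task = c("binary", "multiclass"), n_classes = 2L,
                       decision_threshold = 0.5,
                       aggregation = c("ensemble", "single", "mean"),
                       dropout_where = c("pooled", "scores", "both")) {
  task <- match.arg(task)
  aggregation <- match.arg(aggregation)
  dropout_where <- match.arg(dropout_where)
  if (length(kernel_sizes) != length(filters_per_size)) {
    stopf("kernel_sizes and filters_per_size must have equal length")
  }
  stopifnot(all(kernel_sizes >= 1), all(filters_per_size >= 1),
            dropout_rate >= 0, dropout_rate < 1,
            is_count(n_heads), n_heads >= 1, is_count(bag_size),
            is_count(Lmax), is_count(embed_dim), is_count(n_classes),
            n_classes >= 2)
  if (aggregation == "single") n_heads <- 1L
  structure(list(kernel_sizes = as.integer(kernel_sizes),
                 filters_per_size = as.integer(filters_per_size),
                 n_filters = sum(as.integer(filters_per_size)),
                 dropout_rate = dropout_rate, n_heads = as.integer(n_heads),
                 bag_size = as.integer(bag_size), Lmax = as.integer(Lmax),
                 embed_dim = as.integer(embed_dim), task = task,
                 n_classes = if (task == "binary") 2L else as.integer(n_classes),
                 n_out = if (task == "binary") 1L else as.integer(n_classes),
                 decision_threshold = decision_threshold,
                 aggregation = aggregation, dropout_where = dropout_where),
            class = "cme_config")
}

#' @export
print.cme_config <- function(x, ...) {
  cat(sprintf("CME config: kernels (%s) x filters (%s) -> %d pooled features\n",
              paste(x$kernel_sizes, collapse = ","),
              paste(x$filters_per_size, collapse = ","), x$n_filters))
  cat(sprintf("  bag size %d, Lmax %d, embed dim %d, dropout %.2f\n",
              x$bag_size, x$Lmax, x$embed_dim, x$dropout_rate))
  cat(sprintf("  task %s, aggregation %s (%d head%s), threshold %.2f\n",
              x$task, x$aggregation, x$n_heads,
              if (x$n_heads > 1) "s" else "", x$decision_threshold))
  invisible(x)
}

#' Initialise CME parameters
#'
#' Random normal initialisation scaled by fan-in, except the ensemble heads,
#' which start at `1/k` per slot plus small noise so the initial bag score
#' is the unweighted mean of the sequence scores. Parameter shapes:
#' one `s x D` kernel plus bias per filter; a per-sequence linear head
#' mapping the pooled feature vector to an output (per class for the
#' multiclass task); and `n_heads` bag-level linear classifiers, each a
#' `k`-vector plus bias (per class for the multiclass task).
#'
#' @param config a [cme_config()].
#' @param seed RNG seed.
#' @return an object of class `"cme_params"`.
#' @export
cme_params_init <- function(config, seed = 1L) {
  D <- config$embed_dim
  nF <- config$n_filters
  k <- config$bag_size
  m <- config$n_heads
  C <- config$n_out
  with_seed(seed, {
    conv <- lapply(seq_along(config$kernel_sizes), function(si) {
      s <- config$kernel_sizes[si]
      f <- config$filters_per_size[si]
      list(W = array(stats::rnorm(s * D * f, sd = 1 / sqrt(s * D)), dim = c(s, D, f)),
           b = stats::rnorm(f, sd = 0.1))
    })
    ## ensemble heads start near the unweighted mean (1/k per slot) so the
    ## bag score begins at the mean-aggregation baseline and training learns
    ## rank-slot deviations from there
    structure(list(conv = conv,
                   w_seq = matrix(stats::rnorm(nF * C, sd = 1 / sqrt(nF)), nF, C),
                   b_seq = stats::rnorm(C, sd = 0.1),
                   w_bag = array(1 / k + stats::rnorm(k * m * C, sd = 0.2 / k),
                                 dim = c(k, m, C)),
                   b_bag = matrix(stats::rnorm(m * C, sd = 0.01), m, C)),
              class = "cme_params")
  })
}

#' Logistic sigmoid
#'
#' \eqn{\sigma(x) = 1 / (1 + e^{-x})}; the activation of the binary CME
#' model. Saturates gracefully for large `|x|`.
#'
#' @param x numeric vector or matrix.
#' @return values in `(0, 1)` with the shape of `x`.
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

relu <- function(x) pmax(x, 0)

#' Multi-scale convolutional feature maps for one sequence
#'
#' Applies every convolutional filter (valid convolution, stride 1) to the
#' embedded sequence and passes each position through the activation
#' (sigmoid for the binary task, ReLU for the multiclass task). Filters
#' slide over the instance's true length only, so a filter of size `s`
#' yields exactly `L - s + 1` positions; a filter longer than the sequence
#' yields an empty map.
#'
#' @param E embedding matrix, either `L x D` (true length) or `Lmax x D`
#'   padded, in which case `true_len` must be given.
#' @param config a [cme_config()].
#' @param params a `"cme_params"` object.
#' @param true_len number of real residue rows (defaults to `nrow(E)`).
#' @return a list of numeric vectors, one per filter, in kernel-size order.
#' @export
conv_feature_maps <- function(E, config, params, true_len = nrow(E)) {
  E <- as.matrix(E)
  if (ncol(E) != config$embed_dim) {
    stopf("embedding width %d does not match config embed_dim %d", ncol(E), config$embed_dim)
  }
  if (true_len > nrow(E)) stopf("true_len exceeds matrix rows")
  if (max(config$kernel_sizes) > config$Lmax) stopf("kernel larger than Lmax")
  act <- if (config$task == "binary") sigmoid else relu
  maps <- list()
  for (si in seq_along(config$kernel_sizes)) {
    s <- config$kernel_sizes[si]
    W <- params$conv[[si]]$W
    b <- params$conv[[si]]$b
    n_pos <- true_len - s + 1L
    for (f in seq_len(config$filters_per_size[si])) {
      if (n_pos < 1L) {
        maps[[length(maps) + 1L]] <- numeric(0)
        next
      }
      out <- vapply(seq_len(n_pos), function(p) {
        sum(E[p:(p + s - 1L), , drop = FALSE] * W[, , f]) + b[f]
      }, numeric(1))
      maps[[length(maps) + 1L]] <- act(out)
    }
  }
  maps
}

#' 1-max pooling
#'
#' The maximum activation of one feature map: the strongest match of one
#' filter anywhere along the sequence.
#'
#' @param feature_map non-empty numeric vector.
#' @return the maximum, a scalar.
#' @export
one_max_pool <- function(feature_map) {
  if (length(feature_map) == 0L) stopf("cannot pool an empty feature map")
  max(feature_map)
}

## Pool every feature map into the concatenated F-vector; filters whose map
## is empty (sequence shorter than the kernel) contribute 0.
pooled_features <- function(feature_maps) {
  vapply(feature_maps, function(v) if (length(v)) max(v) else 0, numeric(1))
}

#' Per-sequence cancer score
#'
#' Linear read-out of the pooled feature vector through the sequence head:
#' \eqn{\hat y = \sigma(w^T p + b)}. A score above 0.5 marks the sequence
#' as cancer-associated. During training, dropout is applied to `pooled`
#' before this head; in evaluation mode (the default) the map is
#' deterministic.
#'
#' @param pooled pooled feature `F`-vector.
#' @param params `"cme_params"`.
#' @param dropout_mask optional 0/1 vector (training only); retained
#'   features are rescaled by `1/(1 - dropout_rate)`.
#' @param dropout_rate rate used to build `dropout_mask`.
#' @return the score in `(0, 1)`.
#' @export
sequence_score <- function(pooled, params, dropout_mask = NULL, dropout_rate = 0) {
  p <- as.numeric(pooled)
  if (!is.null(dropout_mask)) p <- p * dropout_mask / (1 - dropout_rate)
  as.numeric(sigmoid(sum(params$w_seq[, 1L] * p) + params$b_seq[1L]))
}

#' Binary cross-entropy loss
#'
#' \eqn{-[y \ln \hat y + (1-y)\ln(1-\hat y)]}, the per-sequence and
#' per-bag training criterion. Probabilities are clamped to
#' `[eps, 1 - eps]` so exact 0/1 predictions stay finite.
#'
#' @param y_hat predicted probabilities in `(0, 1)`.
#' @param y true labels in `{0, 1}`.
#' @param eps clamping constant (default `1e-7`).
#' @return non-negative loss values.
#' @export
sequence_loss <- function(y_hat, y, eps = 1e-7) {
  p <- pmin(pmax(y_hat, eps), 1 - eps)
  -(y * log(p) + (1 - y) * log(1 - p))
}

#' @rdname sequence_loss
#' @export
bag_loss <- sequence_loss

#' Bag-level cancer score
#'
#' Aggregates the `k` ordered per-sequence scores of a bag. Under the
#' ensemble aggregation, each of the `m` linear classifiers maps the score
#' vector to a scalar \eqn{z_j = w_j'^T \hat y + b_j'} and the bag
#' probability is \eqn{\hat Y = \sigma(\frac{1}{m}\sum_j z_j)}. Under the
#' `"mean"` aggregation the bag score is the unweighted mean of the real
#' instances' scores. Masked (padded) instances contribute score 0 to the
#' learned aggregations and are excluded from the mean.
#'
#' @param y_hats `k`-vector of per-sequence scores.
#' @param mask logical `k`-vector marking real instances.
#' @param params `"cme_params"`.
#' @param config `"cme_config"`.
#' @return the bag probability in `(0, 1)`.
#' @export
bag_score <- function(y_hats, mask, params, config) {
  if (!any(mask)) stopf("bag has no real instances")
  y <- as.numeric(y_hats)
  y[!mask] <- 0
  if (config$aggregation == "mean") {
    return(mean(y[mask]))
  }
  m <- config$n_heads
  z <- vapply(seq_len(m), function(j) {
    sum(params$w_bag[, j, 1L] * y) + params$b_bag[j, 1L]
  }, numeric(1))
  as.numeric(sigmoid(mean(z)))
}

#' Full binary forward pass for one embedded bag
#'
#' Composes convolution, 1-max pooling, the per-sequence head and the bag
#' aggregation. Deterministic in evaluation mode; masked instances carry
#' score 0 into the aggregation.
#'
#' @param ebag an `"embedded_bag"`.
#' @param params `"cme_params"`.
#' @param config `"cme_config"` with `task = "binary"`.
#' @return list with `bag_score` (scalar probability), `sequence_scores`
#'   (`k`-vector, `NA` for masked slots) and `decision`
#'   (1 if above the decision threshold).
#' @export
forward_binary <- function(ebag, params, config) {
  stopifnot(config$task == "binary")
  k <- config$bag_size
  yhat <- rep(NA_real_, k)
  for (i in which(ebag$mask)) {
    E <- matrix(ebag$tensor[i, , ], nrow = ebag$Lmax, ncol = ebag$d)
    fm <- conv_feature_maps(E, config, params, true_len = ebag$lengths[i])
    yhat[i] <- sequence_score(pooled_features(fm), params)
  }
  Y <- bag_score(ifelse(is.na(yhat), 0, yhat), ebag$mask, params, config)
  list(bag_score = Y, sequence_scores = yhat,
       decision = as.integer(Y > config$decision_threshold))
}

#' Multiclass forward pass for one embedded bag
#'
#' The multiclass variant shares the architecture of the binary model but
#' uses ReLU activations, leaves the per-class scores un-normalised, and
#' predicts the argmax class (ties broken towards the lowest class index).
#'
#' @param ebag an `"embedded_bag"`.
#' @param params `"cme_params"` with multiclass shapes.
#' @param config `"cme_config"` with `task = "multiclass"`.
#' @param n_classes expected class count (consistency check).
#' @return list with `class` (0-based predicted index), `scores`
#'   (raw per-class scores) and `sequence_scores` (`k x n_classes`).
#' @export
forward_multiclass <- function(ebag, params, config, n_classes = config$n_classes) {
  stopifnot(config$task == "multiclass")
  if (n_classes != config$n_classes || dim(params$w_bag)[3] != n_classes) {
    stopf("n_classes mismatch between arguments, config and parameters")
  }
  k <- config$bag_size
  C <- n_classes
  seq_scores <- matrix(0, k, C)
  for (i in which(ebag$mask)) {
    E <- matrix(ebag$tensor[i, , ], nrow = ebag$Lmax, ncol = ebag$d)
    fm <- conv_feature_maps(E, config, params, true_len = ebag$lengths[i])
    p <- pooled_features(fm)
    seq_scores[i, ] <- as.numeric(crossprod(params$w_seq, p)) + params$b_seq
  }
  scores <- vapply(seq_len(C), function(c) {
    z <- vapply(seq_len(config$n_heads), function(j) {
      sum(params$w_bag[, j, c] * seq_scores[, c]) + params$b_bag[j, c]
    }, numeric(1))
    mean(z)
  }, numeric(1))
  list(class = which.max(scores) - 1L, scores = scores,
       sequence_scores = seq_scores)
}

#' Multiclass cross-entropy loss on softmax-normalised scores
#'
#' @param scores raw per-class score vector.
#' @param y true 0-based class index.
#' @param eps probability clamp.
#' @return non-negative loss.
#' @export
multiclass_loss <- function(scores, y, eps = 1e-7) {
  p <- exp(scores - max(scores))
  p <- p / sum(p)
  -log(min(max(p[y + 1L], eps), 1 - eps))
}
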