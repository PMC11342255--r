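## Confusion-based metrics, ROC/PRC curves, the health score, and the two
## statistical tests used for downstream analyses.

#' Confusion counts at a decision threshold
#'
#' A sample is predicted positive when its score exceeds the threshold.
#' TP/TN count correct positive/negative calls; FP/FN the incorrect ones.
#'
#' @param labels 0/1 vector of true classes (1 = cancer).
#' @param scores predicted probabilities.
#' @param threshold decision threshold (default 0.5).
#' @return an object of class `"confusion_counts"` with `TP`, `TN`, `FP`, `FN`.
#' @export
confusion <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0L) stopf("cannot build a confusion matrix from no samples")
  if (length(labels) != length(scores)) stopf("labels and scores differ in length")
  labels <- as.integer(labels)
  pred <- as.integer(scores > threshold)
  structure(list(TP = sum(pred == 1L & labels == 1L),
                 TN = sum(pred == 0L & labels == 0L),
                 FP = sum(pred == 1L & labels == 0L),
                 FN = sum(pred == 0L & labels == 1L)),
            class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  m <- matrix(c(x$TP, x$FN, x$FP, x$TN), 2, 2,
              dimnames = list(truth = c("cancer", "healthy"),
                              predicted = c("cancer", "healthy")))
  print(m)
  invisible(x)
}

#' Classification metrics from confusion counts
#'
#' Accuracy, sensitivity (recall), specificity, precision and F1 score.
#' A metric whose denominator is zero is reported as `NaN` with a warning
#' rather than silently substituted.
#'
#' @param counts a [confusion()] result.
#' @return named numeric vector with elements `accuracy`, `sensitivity`,
#'   `specificity`, `precision`, `f1`.
#' @export
classification_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  safe_div <- function(num, den, what) {
    if (den == 0) {
      warnf("%s undefined (zero denominator); reported as NaN", what)
      return(NaN)
    }
    num / den
  }
  acc <- safe_div(TP + TN, TP + TN + FP + FN, "accuracy")
  sens <- safe_div(TP, TP + FN, "sensitivity")
  spec <- safe_div(TN, TN + FP, "specificity")
  prec <- safe_div(TP, TP + FP, "precision")
  f1 <- if (is.nan(prec) || is.nan(sens) || prec + sens == 0) {
    warnf("F1 undefined; reported as NaN")
    NaN
  } else {
    2 * prec * sens / (prec + sens)
  }
  c(accuracy = acc, sensitivity = sens, specificity = spec,
    precision = prec, f1 = f1)
}

#' ROC and precision-recall curves with areas
#'
#' Threshold sweep over the unique scores (ties grouped), ROC area by the
#' trapezoid rule and precision-recall area by the standard step
#' interpolation. With grouped ties the ROC area equals the pairwise
#' concordance probability `P(score_pos > score_neg) + 0.5 P(tie)`.
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores predicted probabilities or arbitrary real scores.
#' @return list with `roc` (`data.frame`: threshold, fpr, tpr), `auc`,
#'   `prc` (`data.frame`: threshold, recall, precision) and `auprc`.
#' @export
roc_prc <- function(labels, scores) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) stopf("ROC requires both classes to be present")
  thr <- sort(unique(scores), decreasing = TRUE)
  ## cumulative counts walking the thresholds downward, ties grouped
  o <- order(scores, decreasing = TRUE)
  ls <- labels[o]; ss <- scores[o]
  grp <- match(ss, thr)
  last <- cumsum(rle(grp)$lengths)
  tp <- cumsum(ls == 1L)[last]
  fp <- cumsum(ls == 0L)[last]
  tpr <- c(0, tp / n1); fpr <- c(0, fp / n0)
  roc <- data.frame(threshold = c(Inf, thr), fpr = fpr, tpr = tpr)
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  recall <- tp / n1
  precision <- tp / (tp + fp)
  prc <- data.frame(threshold = thr, recall = recall, precision = precision)
  ## step interpolation: area accumulated at each recall increment
  auprc <- sum(diff(c(0, recall)) * precision)
  list(roc = roc, auc = as.numeric(auc), prc = prc, auprc = as.numeric(auprc))
}

#' Health score
#'
#' The complement of the predicted cancer probability:
#' `health = 1 - cancer score`. Higher values indicate a healthier immune
#' status; values below 0.5 flag an immune status that warrants attention.
#'
#' @param cancer_score probabilities in `[0, 1]`.
#' @return numeric health scores in `[0, 1]`.
#' @export
health_score <- function(cancer_score) {
  if (any(cancer_score < 0 | cancer_score > 1, na.rm = TRUE)) {
    stopf("cancer scores must lie in [0, 1]")
  }
  1 - cancer_score
}

#' @rdname health_score
#' @param health_scores health scores in `[0, 1]`.
#' @return `health_status` returns `"attention"` for scores strictly below
#'   0.5 and `"healthy"` otherwise.
#' @export
health_status <- function(health_scores) {
  ifelse(health_scores < 0.5, "attention", "healthy")
}

#' Spearman rank correlation test
#'
#' Rank correlation with average ranks for ties and a two-sided p-value
#' (asymptotic t approximation), as used for e.g. the age-versus-health-score
#' association.
#'
#' @param x,y numeric vectors of equal length, `n >= 3`.
#' @return list with `rho` and `p_value`.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stopf("x and y differ in length")
  if (length(x) < 3L) stopf("Spearman test requires at least 3 observations")
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Significance stars
#'
#' `ns` for p > 0.05, `*` for p <= 0.05, `**` for p <= 0.01,
#' `***` for p <= 0.001.
#'
#' @param p p-values.
#' @return character vector of star codes.
#' @export
significance_stars <- function(p) {
  ifelse(p <= 0.001, "***", ifelse(p <= 0.01, "**", ifelse(p <= 0.05, "*", "ns")))
}

#' Mann-Whitney U test
#'
#' Two-sample rank-sum test with tie correction and normal approximation,
#' reporting the U statistic for the first sample, the two-sided p-value and
#' the significance stars.
#'
#' @param a,b numeric vectors, both non-empty.
#' @return list with `U`, `p_value` and `stars`.
#' @export
mann_whitney <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stopf("both groups must be non-empty")
  wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE, correct = TRUE))
  list(U = unname(wt$statistic), p_value = wt$p.value,
       stars = significance_stars(wt$p.value))
}

#' Evaluate binary predictions
#'
#' Bundles confusion counts, the five threshold metrics, ROC/PRC curves with
#' areas, and per-sample cancer/health scores into one report.
#'
#' @param labels 0/1 truth vector.
#' @param scores predicted cancer probabilities.
#' @param threshold decision threshold (default 0.5).
#' @param sample_ids optional sample identifiers.
#' @return an object of class `"evaluation_report"`.
#' @export
evaluate_predictions <- function(labels, scores, threshold = 0.5, sample_ids = NULL) {
  cc <- confusion(labels, scores, threshold)
  curves <- roc_prc(labels, scores)
  structure(list(confusion = cc, metrics = classification_metrics(cc),
                 roc = curves$roc, auc = curves$auc,
                 prc = curves$prc, auprc = curves$auprc,
                 threshold = threshold,
                 samples = data.frame(
                   sample_id = sample_ids %||% paste0("sample", seq_along(labels)),
                   label = as.integer(labels), cancer_score = scores,
                   health_score = health_score(pmin(pmax(scores, 0), 1)),
                   stringsAsFactors = FALSE)),
            class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("evaluation of %d samples at threshold %.2f\n",
              nrow(x$samples), x$threshold))
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("accuracy %.3f | sensitivity %.3f | specificity %.3f | precision %.3f | F1 %.3f\n",
              m["accuracy"], m["sensitivity"], m["specificity"],
              m["precision"], m["f1"]))
  cat(sprintf("ROC AUC %.3f | PRC AUC %.3f\n", x$auc, x$auprc))
  invisible(x)
}

#' Multiclass evaluation
#'
#' Full confusion matrix plus one-vs-rest metrics per class; macro averages
#' are returned alongside but the per-class table is the primary view.
#'
#' @param labels 0-based true class indices.
#' @param predicted 0-based predicted class indices.
#' @param n_classes number of classes.
#' @return list with `confusion_matrix`, `per_class` (one row of
#'   one-vs-rest metrics per class) and `macro` averages.
#' @export
evaluate_multiclass <- function(labels, predicted, n_classes = max(labels, predicted) + 1L) {
  labels <- as.integer(labels); predicted <- as.integer(predicted)
  lv <- seq_len(n_classes) - 1L
  cm <- table(factor(labels, levels = lv), factor(predicted, levels = lv),
              dnn = c("truth", "predicted"))
  per <- do.call(rbind, lapply(lv, function(c) {
    cc <- structure(list(TP = sum(labels == c & predicted == c),
                         TN = sum(labels != c & predicted != c),
                         FP = sum(labels != c & predicted == c),
                         FN = sum(labels == c & predicted != c)),
                    class = "confusion_counts")
    suppressWarnings(classification_metrics(cc))
  }))
  rownames(per) <- paste0("class", lv)
  list(confusion_matrix = cm, per_class = per,
       macro = colMeans(per, na.rm = TRUE))
}

#' Write an evaluation report to disk
#'
#' Metrics as JSON, curves and the per-sample table as CSV.
#'
#' @param report an `"evaluation_report"`.
#' @param dir output directory (created if needed).
#' @param prefix file-name prefix.
#' @return the directory, invisibly.
#' @export
write_evaluation_report <- function(report, dir, prefix = "evaluation") {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(
    list(threshold = report$threshold,
         confusion = report$confusion[c("TP", "TN", "FP", "FN")],
         metrics = as.list(report$metrics),
         auc = report$auc, auprc = report$auprc),
    file.path(dir, paste0(prefix, "_metrics.json")),
    auto_unbox = TRUE, pretty = TRUE, digits = NA)
  utils::write.csv(report$roc, file.path(dir, paste0(prefix, "_roc.csv")),
                   row.names = FALSE)
  utils::write.csv(report$prc, file.path(dir, paste0(prefix, "_prc.csv")),
                   row.names = FALSE)
  utils::write.csv(report$samples, file.path(dir, paste0(prefix, "_samples.csv")),
                   row.names = FALSE)
  invisible(dir)
}
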