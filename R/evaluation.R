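#' Confusion matrix for binary glaucoma classification
#'
#' GL is the positive class.
#'
#' @param labels True labels (0/1 or `"GL"`/`"non-GL"`).
#' @param predictions Predicted labels, same coding.
#' @return A `vf_confusion` object: list with `tp`, `fp`, `fn`, `tn`, `n`.
#' @export
vf_confusion <- function(labels, predictions) {
  if (length(labels) != length(predictions)) {
    stop_vf("labels and predictions differ in length")
  }
  y <- as_binary_label(labels)
  p <- as_binary_label(predictions)
  out <- list(tp = sum(y == 1 & p == 1), fp = sum(y == 0 & p == 1),
              fn = sum(y == 1 & p == 0), tn = sum(y == 0 & p == 0))
  out$n <- out$tp + out$fp + out$fn + out$tn
  structure(out, class = "vf_confusion")
}

#' @rdname vf_confusion
#' @param tp,fp,fn,tn Counts, for building a confusion matrix directly
#'   (e.g. from published error counts).
#' @export
vf_confusion_counts <- function(tp, fp, fn, tn) {
  stopifnot(tp >= 0, fp >= 0, fn >= 0, tn >= 0)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = tp + fp + fn + tn),
            class = "vf_confusion")
}

#' @export
print.vf_confusion <- function(x, ...) {
  cat(sprintf("confusion (n=%d): TP %d  FP %d  FN %d  TN %d\n",
              x$n, x$tp, x$fp, x$fn, x$tn))
  invisible(x)
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy, precision, sensitivity (recall) and F-score; ratios with a
#' zero denominator are reported as `NA` (undefined), never as 0.
#'
#' @param cm A [vf_confusion()] object.
#' @return List of class `vf_metrics` with `accuracy`, `precision`,
#'   `sensitivity`, `specificity`, `f_score` (fractions in \[0, 1\]).
#' @examples
#' vf_metrics_from_confusion(vf_confusion_counts(tp = 10, fp = 1, fn = 2, tn = 15))
#' @export
vf_metrics_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "vf_confusion"))
  if (cm$n == 0) stop_vf("empty confusion matrix")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(cm$tp, cm$tp + cm$fp)
  sensitivity <- ratio(cm$tp, cm$tp + cm$fn)
  f <- if (is.na(precision) || is.na(sensitivity) ||
           precision + sensitivity == 0) NA_real_
  else 2 * precision * sensitivity / (precision + sensitivity)
  structure(list(accuracy = (cm$tp + cm$tn) / cm$n,
                 precision = precision, sensitivity = sensitivity,
                 specificity = ratio(cm$tn, cm$tn + cm$fp),
                 f_score = f, confusion = cm),
            class = "vf_metrics")
}

#' @export
print.vf_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "undefined" else sprintf("%.2f%%", 100 * v)
  cat(sprintf("accuracy %s  precision %s  sensitivity %s  F-score %s\n",
              fmt(x$accuracy), fmt(x$precision), fmt(x$sensitivity),
              fmt(x$f_score)))
  invisible(x)
}

#' ROC curve and AUC
#'
#' AUC by the midrank construction (equivalent to the probability that a
#' random positive scores above a random negative, counting ties as 1/2);
#' curve points by threshold sweep for plotting.
#'
#' @param labels True binary labels (both classes must be present).
#' @param probabilities Predicted scores or probabilities.
#' @return List with `auc` and `curve` (data frame of `threshold`, `fpr`,
#'   `tpr`).
#' @export
vf_roc_auc <- function(labels, probabilities) {
  y <- as_binary_label(labels)
  stopifnot(length(y) == length(probabilities))
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  if (n_pos == 0 || n_neg == 0) stop_vf("both classes must be present")
  r <- rank(probabilities, ties.method = "average")
  auc <- (sum(r[y == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
  thr <- c(Inf, sort(unique(probabilities), decreasing = TRUE))
  curve <- data.frame(
    threshold = thr,
    fpr = vapply(thr, function(t) sum(probabilities >= t & y == 0) / n_neg, 0),
    tpr = vapply(thr, function(t) sum(probabilities >= t & y == 1) / n_pos, 0))
  list(auc = auc, curve = curve)
}

#' Prediction entropy of a binary probability
#'
#' H(p) = -(p log p + (1 - p) log(1 - p)) with natural logarithm and the
#' 0 log 0 = 0 convention; maximal (ln 2) at p = 0.5, zero at certainty.
#'
#' @param p Probabilities in \[0, 1\] (vectorised).
#' @return Entropies in \[0, ln 2\].
#' @examples
#' vf_prediction_entropy(c(0, 0.5, 1))
#' @export
vf_prediction_entropy <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop_vf("p must lie in [0, 1]")
  term <- function(q) ifelse(q == 0, 0, q * log(q))
  -(term(p) + term(1 - p))
}

#' Tukey-fence outlier mask
#'
#' Flags values outside \[Q1 - k IQR, Q3 + k IQR\].
#'
#' @param values Numeric vector (at least 4 values).
#' @param k Fence factor (default 1.5).
#' @return Logical mask, `TRUE` for outliers.
#' @export
vf_iqr_outlier_mask <- function(values, k = 1.5) {
  if (length(values) < 4) stop_vf("need at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), na.rm = TRUE)
  iqr <- q[2] - q[1]
  values < q[1] - k * iqr | values > q[2] + k * iqr
}

#' Paired Wilcoxon signed-rank comparison of two models
#'
#' Two-sided signed-rank test on paired scores; zero differences are
#' dropped (the test's convention). If every difference is zero the test
#' is undefined and reported as such.
#'
#' @param a,b Paired score vectors of equal length.
#' @param alpha Significance level (default 0.05).
#' @return List with `statistic`, `p_value`, `significant`, `n_nonzero`.
#' @export
vf_compare_wilcoxon <- function(a, b, alpha = 0.05) {
  stopifnot(length(a) == length(b))
  d <- a - b
  nz <- sum(d != 0)
  if (nz == 0) {
    return(list(statistic = NA_real_, p_value = NA_real_,
                significant = FALSE, n_nonzero = 0L,
                note = "all paired differences are zero; test undefined"))
  }
  wt <- suppressWarnings(stats::wilcox.test(a, b, paired = TRUE,
                                            exact = FALSE, correct = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       significant = wt$p.value < alpha, n_nonzero = nz)
}

#' Permutation feature importance
#'
#' Per-feature drop in a score when that feature column is shuffled:
#' baseline score minus the mean score over `n_repeats` independent
#' within-column permutations. Model-agnostic via a prediction function.
#'
#' @param predict_fun Function taking a feature matrix and returning
#'   predicted labels (for the accuracy metric) or scores.
#' @param X Feature matrix (columns optionally named).
#' @param y True labels.
#' @param metric Function `(y, pred) -> score` (default accuracy of binary
#'   labels).
#' @param n_repeats Shuffles per feature (default 10).
#' @param seed Integer seed.
#' @return Data frame with `feature`, `importance`, sorted decreasing.
#' @export
vf_permutation_importance <- function(predict_fun, X, y,
                                      metric = NULL, n_repeats = 10,
                                      seed = 1) {
  if (n_repeats < 1) stop_vf("n_repeats must be >= 1")
  if (is.null(metric)) {
    metric <- function(y, pred) mean(as_binary_label(y) == as_binary_label(pred))
  }
  baseline <- metric(y, predict_fun(X))
  imp <- with_local_seed(seed, {
    vapply(seq_len(ncol(X)), function(j) {
      drops <- vapply(seq_len(n_repeats), function(r) {
        Xp <- X
        Xp[, j] <- Xp[sample(nrow(X)), j]
        baseline - metric(y, predict_fun(Xp))
      }, numeric(1))
      mean(drops)
    }, numeric(1))
  })
  out <- data.frame(
    feature = colnames(X) %||% paste0("f", seq_len(ncol(X))),
    importance = imp, stringsAsFactors = FALSE)
  out[order(-out$importance), ]
}

#' Aggregate per-location importances by anatomical sector
#'
#' @param importance Data frame from [vf_permutation_importance()] whose
#'   feature names end in the feature position (e.g. `td11`).
#' @param grid A [vf_grid()].
#' @return Data frame with `sector` and summed `importance`.
#' @export
vf_sector_importance <- function(importance, grid) {
  pos <- suppressWarnings(as.integer(sub("^[a-zA-Z_]+", "", importance$feature)))
  keep <- !is.na(pos) & pos >= 1 & pos <= 52
  sec <- vf_sector(grid, vf_location_of_feature(grid, pos[keep]))
  agg <- stats::aggregate(list(importance = importance$importance[keep]),
                          by = list(sector = sec), FUN = sum)
  agg[order(-agg$importance), ]
}
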