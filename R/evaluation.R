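# Metric suite for binary PPI classification: confusion-matrix metrics,
# ROC-AUC, prevalence-corrected precision-recall curves, the one-sided Welch
# t-test for comparing classifiers, and the one-hot memorization diagnostic.

#' Confusion matrix at a score threshold
#'
#' Predicts class 1 whenever `score >= tau` (the boundary counts as
#' positive).
#'
#' @param scores Numeric scores (class-1 probabilities).
#' @param labels Binary (0/1) labels.
#' @param tau Decision threshold (default 0.5).
#' @return A list of class `s2g_confusion` with integer `TP`, `FP`, `FN`,
#'   `TN`.
#' @export
confusion_at_threshold <- function(scores, labels, tau = 0.5) {
  if (length(scores) != length(labels)) stop("scores and labels differ in length")
  stopifnot(length(scores) >= 1, all(labels %in% c(0, 1)))
  pred <- scores >= tau
  pos <- labels == 1
  structure(list(TP = sum(pred & pos), FP = sum(pred & !pos),
                 FN = sum(!pred & pos), TN = sum(!pred & !pos)),
            class = "s2g_confusion")
}

#' Classification metrics from a confusion matrix
#'
#' Computes accuracy, precision, recall (sensitivity), specificity, negative
#' predictive value, F1 and the Matthews correlation coefficient. Ratios with
#' a zero denominator are reported as `NA` rather than coerced to 0, so fold
#' averages are not silently inflated.
#'
#' @param cm An `s2g_confusion` (or list with `TP`, `FP`, `FN`, `TN`).
#' @return A data frame of class `s2g_metrics` with one row.
#' @export
compute_metrics <- function(cm) {
  TP <- cm$TP; FP <- cm$FP; FN <- cm$FN; TN <- cm$TN
  n <- TP + FP + FN + TN
  stopifnot(n > 0)
  safe_div <- function(a, b) if (b == 0) NA_real_ else a / b
  precision <- safe_div(TP, TP + FP)
  recall <- safe_div(TP, TP + FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  mcc_den <- sqrt(TP + FP) * sqrt(TP + FN) * sqrt(TN + FP) * sqrt(TN + FN)
  structure(
    data.frame(
      accuracy = (TP + TN) / n,
      precision = precision,
      recall = recall,
      specificity = safe_div(TN, TN + FP),
      mcc = if (mcc_den == 0) NA_real_ else (TP * TN - FP * FN) / mcc_den,
      f1 = f1,
      npv = safe_div(TN, TN + FN)
    ),
    class = c("s2g_metrics", "data.frame")
  )
}

#' Area under the ROC curve
#'
#' Computed via the Mann-Whitney statistic: the probability that a uniformly
#' random positive outscores a uniformly random negative, with ties counting
#' one half.
#'
#' @param scores Numeric scores.
#' @param labels Binary (0/1) labels; both classes must be present.
#' @return A number in \[0, 1\].
#' @export
roc_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Full evaluation report for one score vector
#'
#' Convenience wrapper: [confusion_at_threshold()] + [compute_metrics()] with
#' ROC-AUC attached.
#'
#' @inheritParams confusion_at_threshold
#' @return An `s2g_metrics` data frame with an extra `roc_auc` column.
#' @export
evaluate_scores <- function(scores, labels, tau = 0.5) {
  rep_ <- compute_metrics(confusion_at_threshold(scores, labels, tau))
  rep_$roc_auc <- roc_auc(scores, labels)
  rep_
}

#' Prevalence-corrected precision-recall curve
#'
#' At each distinct score threshold the sensitivity `Se` and specificity `Sp`
#' are recomputed and precision is corrected to a deployment ratio of `r`
#' negatives per positive: `Se / (Se + r * (1 - Sp))`. With `r = 1` on a
#' dataset with equal class counts this reduces to ordinary precision. The
#' area under the curve is computed by the trapezoid rule over recall.
#'
#' @param scores Numeric scores.
#' @param labels Binary (0/1) labels; both classes must be present.
#' @param r Deployment negative:positive ratio (default 100).
#' @return A list of class `s2g_pr_curve`: data frame `curve` (`threshold`,
#'   `recall`, `precision`), the ratio `r`, and `auc`.
#' @export
prevalence_corrected_pr <- function(scores, labels, r = 100) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  if (r <= 0) stop("r must be positive")
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  thr <- sort(unique(scores))
  se <- sp <- prec <- numeric(length(thr))
  for (i in seq_along(thr)) {
    pred <- scores >= thr[i]
    se[i] <- sum(pred & labels == 1) / n_pos
    sp[i] <- sum(!pred & labels == 0) / n_neg
    den <- se[i] + r * (1 - sp[i])
    prec[i] <- if (den == 0) NA_real_ else se[i] / den
  }
  # terminal operating point: nothing predicted positive (recall 0); its
  # undefined precision is carried over from the strictest threshold
  last_def <- prec[max(which(!is.na(prec)))]
  curve <- data.frame(threshold = c(thr, Inf), recall = c(se, 0),
                      precision = c(prec, last_def))
  ok <- !is.na(curve$precision)
  cx <- curve$recall[ok]
  cy <- curve$precision[ok]
  auc <- sum(-diff(cx) * (head(cy, -1) + cy[-1]) / 2)
  structure(list(curve = curve, r = r, auc = auc), class = "s2g_pr_curve")
}

#' @export
print.s2g_pr_curve <- function(x, ...) {
  cat("<s2g_pr_curve> r = ", x$r, ", ", nrow(x$curve),
      " thresholds, AUC = ", format(x$auc, digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
plot.s2g_pr_curve <- function(x, ...) {
  plot(x$curve$recall, x$curve$precision, type = "l", xlim = c(0, 1),
       ylim = c(0, 1), xlab = "Recall",
       ylab = sprintf("Corrected precision (r = %g)", x$r), ...)
  invisible(x)
}

#' One-sided Welch t-test
#'
#' Tests `H1: mean(a) > mean(b)` for two independent samples with unequal
#' variances, using the Welch-Satterthwaite degrees of freedom.
#'
#' @param a,b Numeric metric samples (e.g. per-fold accuracies), each with at
#'   least two values.
#' @return A list of class `s2g_welch`: `t`, `df`, `p_value` (one-sided).
#' @export
welch_one_sided <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  va <- stats::var(a); vb <- stats::var(b)
  if (va == 0 && vb == 0) stop("zero variance in both samples")
  na <- length(a); nb <- length(b)
  se2a <- va / na; se2b <- vb / nb
  tstat <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df <- (se2a + se2b)^2 / (se2a^2 / (na - 1) + se2b^2 / (nb - 1))
  structure(list(t = tstat, df = df, p_value = pt(tstat, df, lower.tail = FALSE)),
            class = "s2g_welch")
}

#' @export
print.s2g_welch <- function(x, ...) {
  cat(sprintf("<s2g_welch> t = %.4f, df = %.2f, one-sided p = %.4g\n",
              x$t, x$df, x$p_value))
  invisible(x)
}

#' One-hot protein-identity features for a pair table
#'
#' Each protein gets a one-hot vector over the protein vocabulary; a pair's
#' feature vector is the sum of its two one-hots (order-invariant).
#'
#' @param pairs Data frame with columns `id1`, `id2`.
#' @param proteins Character vector of unique protein ids (the vocabulary);
#'   defaults to all ids appearing in `pairs`, in first-seen order.
#' @return An `nrow(pairs) x length(proteins)` 0/1/2 matrix.
#' @export
memorization_features <- function(pairs, proteins = NULL) {
  if (any(pairs$id1 == pairs$id2)) stop("self-pairs are not allowed")
  proteins <- proteins %||% unique(c(rbind(pairs$id1, pairs$id2)))
  X <- matrix(0L, nrow(pairs), length(proteins),
              dimnames = list(NULL, proteins))
  i1 <- match(pairs$id1, proteins)
  i2 <- match(pairs$id2, proteins)
  if (anyNA(i1) || anyNA(i2)) stop("pair references a protein outside the vocabulary")
  X[cbind(seq_len(nrow(pairs)), i1)] <- X[cbind(seq_len(nrow(pairs)), i1)] + 1L
  X[cbind(seq_len(nrow(pairs)), i2)] <- X[cbind(seq_len(nrow(pairs)), i2)] + 1L
  X
}

#' Memorization diagnostic
#'
#' Can pair labels be predicted from protein identity alone? Each pair is
#' encoded as the sum of its two one-hot protein vectors and fed to a generic
#' classifier (random forest by default), which is fit on the training split
#' and scored on both splits. High test accuracy indicates that labels are
#' memorizable from identity; chance-level test accuracy means a structural
#' model that performs well must be learning from structure.
#'
#' @param pairs Data frame with `id1`, `id2`, `label`.
#' @param train_idx,test_idx Integer row indices of the two splits.
#' @param classifier Function `(X_train, y_train)` returning a fitted object
#'   with a `predict(object, X)` method that yields class labels; defaults to
#'   [randomForest::randomForest()].
#' @param seed Seed for the classifier's internal randomness.
#' @return A list with `train_accuracy` and `test_accuracy`.
#' @export
memorization_test <- function(pairs, train_idx, test_idx, classifier = NULL,
                              seed = 1L) {
  X <- memorization_features(pairs)
  y <- factor(pairs$label, levels = c(0, 1))
  classifier <- classifier %||% function(Xtr, ytr) {
    randomForest::randomForest(Xtr, ytr)
  }
  fit <- with_seed(derive_seed(seed, "memtest"),
                   classifier(X[train_idx, , drop = FALSE], y[train_idx]))
  acc <- function(idx) {
    mean(predict(fit, X[idx, , drop = FALSE]) == y[idx])
  }
  list(train_accuracy = acc(train_idx), test_accuracy = acc(test_idx))
}
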