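# Confusion metrics, ROC-AUC, prevalence-corrected precision-recall, Welch
# one-sided test, and the memorization diagnostic.

test_that("confusion counting at a threshold", {
  cm <- confusion_at_threshold(c(0.7, 0.2), c(1, 0), 0.5)
  expect_equal(unclass(cm)[c("TP", "FP", "FN", "TN")],
               list(TP = 1L, FP = 0L, FN = 0L, TN = 1L),
               ignore_attr = TRUE)
  labels <- c(rep(1, 5), rep(0, 5))
  cm2 <- confusion_at_threshold(rep(1, 10), labels)
  expect_equal(cm2$FP, 5)
  expect_equal(cm2$FN, 0)
  cm3 <- confusion_at_threshold(stats::runif(10), labels, tau = 0)
  expect_equal(cm3$TN + cm3$FN, 0)
  expect_error(confusion_at_threshold(1:3, 1:2), "length")
})

test_that("metric formulas match closed-form evaluations", {
  m <- compute_metrics(list(TP = 8, FP = 2, FN = 2, TN = 8))
  expect_equal(m$accuracy, 0.8)
  expect_equal(m$precision, 0.8)
  expect_equal(m$recall, 0.8)
  expect_equal(m$specificity, 0.8)
  expect_equal(m$f1, 0.8)
  expect_equal(m$npv, 0.8)
  expect_equal(m$mcc, 0.6, tolerance = 1e-12)   # (64 - 4) / 100

  perfect <- compute_metrics(list(TP = 5, FP = 0, FN = 0, TN = 5))
  expect_equal(unname(unlist(perfect)), rep(1, 7), tolerance = 1e-12)

  even <- compute_metrics(list(TP = 3, FP = 3, FN = 3, TN = 3))
  expect_equal(even$mcc, 0)

  degenerate <- compute_metrics(list(TP = 0, FP = 0, FN = 2, TN = 3))
  expect_true(is.na(degenerate$precision))   # missing, not zero
})

test_that("metrics agree with direct confusion counting on random sets", {
  with_seed_test(17, {
    for (rep in 1:200) {
      n <- sample(5:40, 1)
      scores <- stats::runif(n)
      labels <- stats::rbinom(n, 1, 0.5)
      tau <- stats::runif(1)
      cm <- confusion_at_threshold(scores, labels, tau)
      expect_identical(cm$TP, sum(scores >= tau & labels == 1))
      expect_identical(cm$TN, sum(scores < tau & labels == 0))
      expect_equal(cm$TP + cm$FP + cm$FN + cm$TN, n)
      m <- compute_metrics(cm)
      expect_equal(m$accuracy, mean((scores >= tau) == (labels == 1)))
    }
  })
})

test_that("ROC-AUC equals the Mann-Whitney pairwise probability", {
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1.0)
  expect_equal(roc_auc(c(0.1, 0.4, 0.35, 0.8), c(1, 1, 0, 0)), 0.25)
  expect_error(roc_auc(c(0.3, 0.4), c(1, 1)), "both classes")

  brute_auc <- function(scores, labels) {
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    tot <- 0
    for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
    tot / (length(pos) * length(neg))
  }
  with_seed_test(19, {
    for (rep in 1:200) {
      n <- sample(4:30, 1)
      scores <- round(stats::runif(n), 2)   # rounding forces ties
      labels <- c(0, 1, stats::rbinom(n - 2, 1, 0.5))
      expect_equal(roc_auc(scores, labels), brute_auc(scores, labels),
                   tolerance = 1e-12)
    }
  })
})

test_that("prevalence-corrected precision follows Se/(Se + r(1-Sp))", {
  # Se = 0.9, Sp = 0.99 at threshold 0.9 by construction
  scores <- c(rep(0.9, 90), rep(0.1, 10), rep(0.2, 99), 0.95)
  labels <- c(rep(1, 100), rep(0, 100))
  pr <- prevalence_corrected_pr(scores, labels, r = 100)
  row <- pr$curve[pr$curve$threshold == 0.9, ]
  expect_equal(row$recall, 0.9)
  expect_equal(row$precision, 0.9 / (0.9 + 100 * 0.01), tolerance = 1e-12)
  expect_equal(row$precision, 0.47368, tolerance = 1e-5)
  # recall is nonincreasing along the sweep and everything is in [0, 1]
  expect_true(all(diff(pr$curve$recall) <= 0))
  expect_true(all(pr$curve$precision >= 0 & pr$curve$precision <= 1, na.rm = TRUE))

  # r = 1 on balanced data reduces to ordinary precision at every threshold
  with_seed_test(23, {
    scores <- stats::runif(40)
    labels <- rep(c(0, 1), 20)
    pr1 <- prevalence_corrected_pr(scores, labels, r = 1)
    for (k in 2:nrow(pr1$curve)) {
      thr <- pr1$curve$threshold[k]
      cm <- confusion_at_threshold(scores, labels, thr)
      if (cm$TP + cm$FP > 0) {
        expect_equal(pr1$curve$precision[k], cm$TP / (cm$TP + cm$FP),
                     tolerance = 1e-12)
      }
    }
  })

  # perfect separation has unit AUC at any r
  sep_scores <- c(stats::runif(20, 0.8, 1), stats::runif(20, 0, 0.2))
  sep_labels <- rep(1:0, each = 20)
  expect_equal(prevalence_corrected_pr(sep_scores, sep_labels, r = 100)$auc, 1,
               tolerance = 1e-12)
  expect_error(prevalence_corrected_pr(sep_scores, sep_labels, r = 0), "positive")
})

test_that("Welch one-sided test matches the textbook formula and t.test", {
  a <- c(0.99, 0.98, 0.97, 0.99, 0.98)
  b <- c(0.95, 0.94, 0.96, 0.95, 0.94)
  res <- welch_one_sided(a, b)
  # independent closed-form computation
  se2a <- stats::var(a) / 5; se2b <- stats::var(b) / 5
  t_ref <- (mean(a) - mean(b)) / sqrt(se2a + se2b)
  df_ref <- (se2a + se2b)^2 / (se2a^2 / 4 + se2b^2 / 4)
  p_ref <- stats::pt(t_ref, df_ref, lower.tail = FALSE)
  expect_equal(res$t, t_ref, tolerance = 1e-6)
  expect_equal(res$df, df_ref, tolerance = 1e-6)
  expect_equal(res$p_value, p_ref, tolerance = 1e-6)
  # cross-check against the stats implementation
  tt <- stats::t.test(a, b, alternative = "greater", var.equal = FALSE)
  expect_equal(res$t, unname(tt$statistic), tolerance = 1e-10)
  expect_equal(res$p_value, tt$p.value, tolerance = 1e-10)

  same <- welch_one_sided(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p_value, 0.5)
  expect_lt(welch_one_sided(c(10, 11, 12), c(1, 2, 3))$p_value, 0.01)
  expect_error(welch_one_sided(c(1, 1), c(1, 1)), "zero variance")
})

test_that("Welch p-values decrease monotonically in the mean gap", {
  base <- c(0.1, 0.2, 0.3, 0.2)
  gaps <- c(0, 0.05, 0.1, 0.2, 0.4)
  ps <- vapply(gaps, function(g) welch_one_sided(base + g, base)$p_value,
               numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("one-hot pair features sum the two protein indicators", {
  pairs <- data.frame(id1 = c("p0", "p1"), id2 = c("p2", "p3"),
                      label = c(1, 0), stringsAsFactors = FALSE)
  X <- memorization_features(pairs, proteins = c("p0", "p1", "p2", "p3"))
  expect_equal(X[1, ], c(p0 = 1, p1 = 0, p2 = 1, p3 = 0))
  # order invariance
  swapped <- data.frame(id1 = "p2", id2 = "p0", label = 1)
  Xs <- memorization_features(swapped, proteins = c("p0", "p1", "p2", "p3"))
  expect_equal(unname(Xs[1, ]), unname(X[1, ]))
  expect_error(memorization_features(data.frame(id1 = "a", id2 = "a")), "self-pairs")
})

test_that("identity features score at chance when labels are random per pair", {
  # every protein appears in exactly one pair, labels random: nothing to
  # memorize, so held-out accuracy must hover around 0.5
  accs <- vapply(1:10, function(s) {
    with_seed_test(3000 + s, {
      n <- 60
      pairs <- data.frame(id1 = sprintf("a%03d", 1:n),
                          id2 = sprintf("b%03d", 1:n),
                          label = stats::rbinom(n, 1, 0.5),
                          stringsAsFactors = FALSE)
      idx <- sample(n)
      memorization_test(pairs, train_idx = idx[1:40], test_idx = idx[41:60],
                        seed = s)$test_accuracy
    })
  }, numeric(1))
  expect_gte(mean(accs), 0.4)
  expect_lte(mean(accs), 0.6)
})
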