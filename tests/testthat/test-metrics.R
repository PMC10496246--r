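# evaluation metrics: confusion rates and rank-based ROC/AUC

test_that("confusion_metrics computes the standard rates in percent", {
  pred <- c(rep(TRUE, 4), rep(FALSE, 6))
  truth <- c(TRUE, TRUE, TRUE, FALSE, TRUE, rep(FALSE, 5))
  cm <- confusion_metrics(pred, truth)
  expect_equal(c(cm$TP, cm$FP, cm$FN, cm$TN), c(3, 1, 1, 5))
  expect_equal(cm$accuracy, 80)
  expect_equal(cm$sensitivity, 75)
  expect_equal(cm$specificity, 100 * 5 / 6, tolerance = 1e-9)
  expect_equal(cm$ppv, 75)
  expect_equal(cm$npv, 100 * 5 / 6, tolerance = 1e-9)
  expect_length(cm$undefined, 0)

  perfect <- confusion_metrics(truth, truth)
  expect_equal(c(perfect$accuracy, perfect$sensitivity, perfect$specificity,
                 perfect$ppv, perfect$npv), rep(100, 5))

  none <- confusion_metrics(rep(FALSE, 5), rep(FALSE, 5))
  expect_true(is.nan(none$sensitivity))
  expect_true("sensitivity" %in% none$undefined)

  expect_error(confusion_metrics(TRUE, c(TRUE, FALSE)),
               class = "noderad_input_error")
})

test_that("roc_auc: perfect ordering, permutation null, tie handling", {
  truth <- rep(c(TRUE, FALSE), each = 10)
  expect_equal(roc_auc(c(rep(2, 10), rep(1, 10)), truth)$auc, 100)

  set.seed(40)
  big <- roc_auc(runif(2000), sample(c(TRUE, FALSE), 2000, TRUE))$auc
  expect_lt(abs(big - 50), 5)

  # 6-point toy set with ties vs the all-pairs oracle
  scores <- c(0.9, 0.8, 0.8, 0.5, 0.5, 0.1)
  truth6 <- c(TRUE, TRUE, FALSE, TRUE, FALSE, FALSE)
  expect_equal(roc_auc(scores, truth6)$auc, oracle_auc(scores, truth6))

  set.seed(41)
  for (rep in 1:20) {
    s <- sample(seq(0, 1, by = 0.1), 12, replace = TRUE)
    t <- sample(c(TRUE, FALSE), 12, replace = TRUE)
    if (all(t) || !any(t)) next
    expect_equal(roc_auc(s, t)$auc, oracle_auc(s, t), tolerance = 1e-9)
  }

  expect_error(roc_auc(1:5, rep(TRUE, 5)), class = "noderad_undefined_auc")
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(42)
  s <- rnorm(60)
  t <- s + rnorm(60) > 0
  a1 <- roc_auc(s, t)$auc
  expect_equal(roc_auc(exp(s), t)$auc, a1)
  expect_equal(roc_auc(2 * s - 7, t)$auc, a1)
})

test_that("threshold-0.5 binarization of vote scores matches the counts", {
  set.seed(43)
  score <- sample(0:31, 50, replace = TRUE) / 31
  truth <- runif(50) > 0.5
  cm <- confusion_metrics(score > 0.5, truth)
  roc <- roc_auc(score, truth)$roc
  # the ROC point just above 0.5 reproduces the confusion rates
  thr <- min(roc$threshold[roc$threshold > 0.5])
  idx <- which(roc$threshold == thr)
  expect_equal(roc$tpr[idx], cm$TP / (cm$TP + cm$FN))
  expect_equal(roc$fpr[idx], cm$FP / (cm$FP + cm$TN))
})

test_that("ROC endpoints span (0,0) to (1,1) and are monotone", {
  set.seed(44)
  r <- roc_auc(rnorm(40), runif(40) > 0.4)$roc
  expect_equal(c(r$tpr[1], r$fpr[1]), c(0, 0))
  expect_equal(c(r$tpr[nrow(r)], r$fpr[nrow(r)]), c(1, 1))
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))
})
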