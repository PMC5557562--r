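# Confusion metrics, ROC/AUC and the cross-validation harness.

test_that("confusion metrics evaluate the printed formulas", {
  # perfect prediction
  r <- confusion_metrics(rep(c("positive", "negative"), each = 50),
                         rep(c("positive", "negative"), each = 50))
  expect_equal(c(r$Sn, r$Sp, r$Acc, r$MCC), c(1, 1, 1, 1))
  # hand-evaluated case: TP=40 FN=10 TN=45 FP=5
  y <- rep(c("positive", "negative"), c(50, 50))
  p <- c(rep("positive", 40), rep("negative", 10),
         rep("positive", 5), rep("negative", 45))
  r <- confusion_metrics(y, p)
  expect_equal(r$tp, 40); expect_equal(r$fn, 10)
  expect_equal(r$tn, 45); expect_equal(r$fp, 5)
  expect_equal(r$Sn, 0.8)
  expect_equal(r$Sp, 0.9)
  expect_equal(r$Acc, 0.85)
  expect_equal(r$MCC, 1750 / sqrt(6187500), tolerance = 1e-12)
  # degenerate: all predicted positive => Sp=0 and MCC defined as 0
  r <- confusion_metrics(y, rep("positive", 100))
  expect_equal(r$Sn, 1); expect_equal(r$Sp, 0); expect_equal(r$MCC, 0)
  expect_error(confusion_metrics(character(0), character(0)), "empty")
})

test_that("MCC symmetries hold", {
  set.seed(41)
  for (rep in 1:20) {
    y <- sample(c("positive", "negative"), 40, replace = TRUE)
    p <- sample(c("positive", "negative"), 40, replace = TRUE)
    if (length(unique(y)) < 2) next
    flip <- function(v) ifelse(v == "positive", "negative", "positive")
    m <- confusion_metrics(y, p)$MCC
    expect_gte(m, -1); expect_lte(m, 1)
    # swapping classes AND predictions leaves MCC unchanged
    expect_equal(confusion_metrics(flip(y), flip(p))$MCC, m,
                 tolerance = 1e-12)
    # inverting predictions alone negates it
    expect_equal(confusion_metrics(y, flip(p))$MCC, -m, tolerance = 1e-12)
  }
})

test_that("ROC is monotone from (0,0) to (1,1) and AUC is Mann-Whitney", {
  # all positives above all negatives
  expect_equal(roc_auc(c(1, 1, 0, 0), c(4, 3, 2, 1))$auc, 1.0)
  # spec example: 3 of 4 concordant pairs
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.7, 0.1))$auc, 0.75)
  # all-tied scores: pure chance
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(2, 4))$auc, 0.5)
  expect_error(roc_auc(rep(1, 4), 1:4), "both classes")

  set.seed(42)
  for (rep in 1:30) {
    n <- sample(10:30, 1)
    y <- sample(c("positive", "negative"), n, replace = TRUE)
    if (length(unique(y)) < 2) next
    s <- round(rnorm(n), sample(c(0, 1, 9), 1))  # sometimes heavy ties
    out <- roc_auc(y, s)
    expect_equal(out$auc, oracle_mw_auc(y, s), tolerance = 1e-12)
    expect_equal(out$roc$fpr[1], 0); expect_equal(out$roc$tpr[1], 0)
    expect_equal(utils::tail(out$roc$fpr, 1), 1)
    expect_equal(utils::tail(out$roc$tpr, 1), 1)
    expect_true(all(diff(out$roc$fpr) >= 0))
    expect_true(all(diff(out$roc$tpr) >= 0))
    # AUC invariant under strictly monotone transforms
    expect_equal(roc_auc(y, exp(s))$auc, out$auc, tolerance = 1e-12)
  }
})

test_that("cross-validation partitions, pools, and reproduces under seed", {
  toy <- separable_toy(25, d = 2, gap = 3, seed = 43)
  cfg <- svm_config(C = 10, gamma = 0.5, folds = 5, seed = 9)
  cv <- cross_validate(toy$X, toy$y, cfg)
  # every sample in exactly one test fold
  expect_equal(sort(unique(cv$fold_id)), 1:5)
  expect_equal(length(cv$fold_id), 50L)
  # both classes in every fold (stratified)
  for (f in 1:5) {
    expect_setequal(unique(toy$y[cv$fold_id == f]),
                    c("positive", "negative"))
  }
  # pooled counts cover all samples
  rep_p <- cv$pooled
  expect_equal(rep_p$tp + rep_p$tn + rep_p$fp + rep_p$fn, 50)
  expect_gt(rep_p$auc, 0.95)
  # pooled Acc with equal class sizes equals (Sn+Sp)/2
  expect_equal(rep_p$Acc, (rep_p$Sn + rep_p$Sp) / 2, tolerance = 1e-12)
  # determinism
  cv2 <- cross_validate(toy$X, toy$y, cfg)
  expect_identical(cv$scores, cv2$scores)
  expect_identical(cv$fold_id, cv2$fold_id)
  expect_error(cross_validate(toy$X[1:3, ], toy$y[1:3], cfg), "folds")
})
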