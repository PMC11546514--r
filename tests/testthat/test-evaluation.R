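test_that("confusion counts use a strictly-greater threshold", {
  cc <- confusion(c(0.6, 0.4), c(1, 0), 0.5)
  expect_equal(cc[c("TP", "TN", "FP", "FN")],
               list(TP = 1L, TN = 1L, FP = 0L, FN = 0L),
               ignore_attr = TRUE)
  # a score exactly at the threshold is a negative call
  expect_equal(confusion(0.5, 1, 0.5)$FN, 1L)
  expect_equal(confusion(0.504, 1, 0.5)$TP, 1L)
  expect_error(confusion(c(0.1), c(0.1, 0.2)), "equal length")
  expect_error(confusion(0.3, 2), "0 or 1")
})

test_that("confusion matches a brute-force per-item tally", {
  set.seed(61)
  for (rep in 1:5) {
    s <- runif(20)
    y <- rbinom(20, 1, 0.5)
    cc <- confusion(s, y, 0.5)
    tp <- fp <- tn <- fn <- 0
    for (i in 1:20) {
      if (s[i] > 0.5 && y[i] == 1) tp <- tp + 1
      if (s[i] > 0.5 && y[i] == 0) fp <- fp + 1
      if (s[i] <= 0.5 && y[i] == 0) tn <- tn + 1
      if (s[i] <= 0.5 && y[i] == 1) fn <- fn + 1
    }
    expect_equal(unlist(cc[c("TP", "FP", "TN", "FN")], use.names = FALSE),
                 c(tp, fp, tn, fn))
    expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 20)
  }
})

test_that("precision, recall and F1 follow their definitions", {
  prf <- precision_recall_f1(list(TP = 8, FP = 2, FN = 2))
  expect_equal(prf$precision, 0.8)
  expect_equal(prf$recall, 0.8)
  expect_equal(prf$f1, 0.8)  # harmonic mean of equal values

  f1 <- function(p, r) 2 * p * r / (p + r)
  expect_equal(f1(0.8, 0.6), 0.96 / 1.4)
  expect_equal(precision_recall_f1(list(TP = 0, FP = 3, FN = 4)),
               list(precision = 0, recall = 0, f1 = 0))

  # invariance under scaling all counts by a positive integer
  for (k in c(2, 5)) {
    a <- precision_recall_f1(list(TP = 6, FP = 3, FN = 2))
    b <- precision_recall_f1(list(TP = 6 * k, FP = 3 * k, FN = 2 * k))
    expect_equal(a$f1, b$f1)
  }
})

test_that("false-positive rate and row normalization", {
  expect_equal(fpr(list(FP = 0, TN = 10)), 0)
  expect_error(fpr(list(FP = 0, TN = 0)), "undefined")
  nc <- normalize_confusion(list(TP = 30, FN = 10, FP = 5, TN = 15))
  expect_equal(nc$TPR + nc$FNR, 1, tolerance = 1e-12)
  expect_equal(nc$FPR + nc$TNR, 1, tolerance = 1e-12)
  expect_equal(normalize_confusion(list(TP = 1, FN = 1, FP = 0, TN = 7))$TNR, 1)
  expect_error(normalize_confusion(list(TP = 0, FN = 0, FP = 1, TN = 1)),
               "empty")
  set.seed(5)
  for (rep in 1:10) {
    cc <- as.list(stats::setNames(sample(1:50, 4), c("TP", "FN", "FP", "TN")))
    nc <- normalize_confusion(cc)
    expect_equal(nc$TPR + nc$FNR, 1, tolerance = 1e-12)
    expect_equal(nc$FPR + nc$TNR, 1, tolerance = 1e-12)
  }
})

test_that("ROC area equals the exhaustive concordance probability", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.4, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_equal(roc_auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_error(roc_auc(c(0.2, 0.3), c(1, 1)), "both classes")

  set.seed(77)
  for (rep in 1:20) {
    n <- sample(4:50, 1)
    s <- round(runif(n), sample(1:3, 1))  # coarse rounding forces ties
    y <- c(0, 1, rbinom(n - 2, 1, 0.5))
    expect_equal(roc_auc(s, y)$auc, concordance_oracle(s, y),
                 tolerance = 1e-12)
  }
})

test_that("ROC curve runs from (0,0) to (1,1) and is monotone-invariant", {
  set.seed(13)
  s <- runif(30)
  y <- c(0, 1, rbinom(28, 1, 0.5))
  r <- roc_auc(s, y)
  expect_equal(r$fpr[1], 0)
  expect_equal(r$tpr[1], 0)
  expect_equal(r$fpr[length(r$fpr)], 1)
  expect_equal(r$tpr[length(r$tpr)], 1)
  # any strictly monotone transform of the scores leaves the area unchanged
  expect_equal(roc_auc(exp(3 * s), y)$auc, r$auc, tolerance = 1e-12)
  expect_equal(roc_auc(rank(s, ties.method = "min"), y)$auc, r$auc,
               tolerance = 1e-12)
})

test_that("ROC area agrees with an established implementation", {
  set.seed(42)
  s <- runif(40)
  y <- c(0, 1, rbinom(38, 1, 0.5))
  expect_equal(roc_auc(s, y)$auc,
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                              direction = "<"))),
               tolerance = 1e-12)
})

test_that("PR curve area by manual threshold sweep", {
  expect_equal(pr_auc(c(0.9, 0.8, 0.4, 0.1), c(1, 1, 0, 0))$auc, 1.0)
  expect_error(pr_auc(c(0.2, 0.3), c(0, 0)), "positive")

  # single positive ranked last among 4: sweep thresholds by hand.
  # points (recall, precision): (0,0), (0,1/2)... descending distinct scores
  # 0.9, 0.7, 0.5, 0.2 with labels 0,0,0,1 give
  # (0, 0), (0, 0), (0, 0), (1, 1/4); anchored at (0, p1); trapezoid = 1/8.
  pa <- pr_auc(c(0.9, 0.7, 0.5, 0.2), c(0, 0, 0, 1))
  expect_equal(pa$auc, 0.125, tolerance = 1e-12)

  set.seed(3)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    s <- runif(n)
    y <- c(1, rbinom(n - 1, 1, 0.4))
    a <- pr_auc(s, y)$auc
    expect_gte(a, 0)
    expect_lte(a, 1)
  }
})

test_that("relative improvement arithmetic", {
  expect_equal(relative_improvement(0.9, 0.9), 0)
  expect_equal(relative_improvement(1.2, 1.0), 20)
  expect_error(relative_improvement(0.9, 0), "> 0")
  expect_equal(round_half_up(2.665, 2), 2.67)  # not banker's rounding
  expect_equal(round_half_up(-2.5), -3)
  expect_equal(round_half_up(2.29499, 2), 2.29)
})

test_that("Tanimoto similarity over bit sets", {
  expect_equal(tanimoto(c(1, 5, 9), c(1, 5, 9)), 1.0)
  expect_equal(tanimoto(c(1, 2), c(3, 4)), 0.0)
  expect_equal(tanimoto(1:4, c(3, 4, 10, 11, 12, 13)), 0.25)  # 2 / 8
  expect_equal(tanimoto(integer(0), integer(0)), 0)
  expect_equal(tanimoto(c(1, 1, 2), c(2, 2, 1)), 1.0)  # duplicates ignored
})

test_that("n-gram fingerprints are deterministic, bounded and discriminative", {
  f1 <- ngram_fingerprint("c1ccccc1Cl")
  expect_identical(f1, ngram_fingerprint("c1ccccc1Cl"))
  expect_true(all(f1 >= 0 & f1 < 2048))
  f2 <- ngram_fingerprint("NCCS")
  expect_lt(tanimoto(f1, f2), tanimoto(f1, ngram_fingerprint("c1ccccc1Br")))
})

test_that("evaluation report assembles consistent metrics", {
  set.seed(19)
  scores <- runif(40)
  labels <- c(0, 1, rbinom(38, 1, 0.5))
  rep <- ddipair:::report_from_scores(scores, labels)
  expect_s3_class(rep, "ddi_eval")
  expect_equal(rep$n, 40)
  cc <- rep$counts
  expect_equal(cc$TP + cc$FP + cc$TN + cc$FN, 40)
  expect_equal(rep$auc_roc, concordance_oracle(scores, labels),
               tolerance = 1e-12)
  prf <- precision_recall_f1(cc)
  expect_equal(rep$f1, prf$f1)
  expect_equal(rep$rates$FPR, fpr(cc))
})
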