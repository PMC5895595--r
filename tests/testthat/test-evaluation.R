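# ROC, AUC, Youden threshold selection, confusion matrices.

test_that("roc_curve covers its canonical small cases", {
  # perfectly separated: the curve passes through (fpr 0, tpr 1)
  cv <- roc_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  expect_true(any(cv$fpr == 0 & cv$tpr == 1))
  expect_equal(cv$fpr[1], 0); expect_equal(cv$tpr[1], 0)
  expect_equal(cv$fpr[length(cv$fpr)], 1)
  expect_equal(cv$tpr[length(cv$tpr)], 1)
  # all scores tied: only the two endpoints
  cv2 <- roc_curve(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))
  expect_equal(cv2$fpr, c(0, 1)); expect_equal(cv2$tpr, c(0, 1))
  expect_error(roc_curve(c(0.1, 0.2), c(1, 1)), "both classes")
})

test_that("auc matches its closed-form small cases", {
  expect_equal(roc_auc(roc_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))), 1.0)
  expect_equal(roc_auc(roc_curve(rep(0.4, 6), c(1, 0, 1, 0, 1, 0))), 0.5)
  # 3 of 4 positive/negative pairs concordant -> 0.75
  expect_equal(roc_auc(roc_curve(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0))), 0.75)
})

test_that("auc equals the tie-corrected pair-count oracle on random batches", {
  set.seed(20)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), sample(c(1, 2), 1))  # coarse grid forces ties
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    got <- roc_auc(roc_curve(scores, labels))
    expect_equal(got, auc_pair_oracle(scores, labels), tolerance = 1e-12)
  }
})

test_that("auc agrees with an independent ROC library", {
  skip_if_not_installed("pROC")
  set.seed(21)
  for (i in 1:10) {
    scores <- runif(40); labels <- rbinom(40, 1, 0.5)
    if (length(unique(labels)) < 2) next
    ref <- suppressMessages(as.numeric(
      pROC::auc(labels, scores, levels = c(0, 1), direction = "<")))
    expect_equal(roc_auc(roc_curve(scores, labels)), ref, tolerance = 1e-12)
  }
})

test_that("youden_best maximizes tpr - fpr with smallest-threshold ties", {
  yb <- youden_best(roc_curve(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0)))
  expect_equal(yb$youden_j, 1.0)
  yb2 <- youden_best(roc_curve(rep(0.4, 4), c(1, 0, 1, 0)))
  expect_equal(yb2$youden_j, 0.0)
  # both cuts reach j = 0.5; the tie goes to the smaller threshold (0.4)
  yb3 <- youden_best(roc_curve(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0)))
  expect_equal(yb3$youden_j, 0.5)
  expect_equal(yb3$best_threshold, 0.4)
})

test_that("youden_best equals the exhaustive threshold scan on random batches", {
  set.seed(22)
  for (i in 1:50) {
    n <- sample(4:30, 1)
    scores <- round(runif(n), sample(c(1, 2), 1))
    labels <- c(0, 1, rbinom(n - 2, 1, 0.5))
    got <- youden_best(roc_curve(scores, labels))
    ref <- youden_scan_oracle(scores, labels)
    expect_equal(got$youden_j, ref$youden_j, tolerance = 1e-12)
    expect_equal(got$best_threshold, ref$best_threshold)
  }
})

test_that("threshold metrics count with the >= convention", {
  m <- threshold_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(m), c(acc = 1, sen = 1, spe = 1))
  m0 <- threshold_metrics(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0), 0)
  expect_equal(m0$sen, 1); expect_equal(m0$spe, 0)
  m5 <- threshold_metrics(c(0.9, 0.4, 0.6, 0.1), c(1, 1, 0, 0), 0.5)
  expect_equal(unlist(m5), c(acc = 0.5, sen = 0.5, spe = 0.5))
})

test_that("at the best threshold, youden_j = sen + spe - 1 exactly", {
  set.seed(23)
  for (i in 1:20) {
    scores <- round(runif(25), 2)
    labels <- c(0, 1, rbinom(23, 1, 0.4))
    r <- threshold_report(scores, labels)
    expect_equal(r$youden_j, r$sen + r$spe - 1, tolerance = 1e-9)
  }
})

test_that("one-vs-rest batches mirror for two complementary columns", {
  set.seed(24)
  p1 <- runif(30)
  probs <- cbind(p1, 1 - p1)
  labels <- rbinom(30, 1, 0.5) + 1L
  batches <- one_vs_rest_batches(probs, labels)
  a0 <- roc_auc(roc_curve(batches[[1]]$scores, batches[[1]]$labels))
  a1 <- roc_auc(roc_curve(batches[[2]]$scores, batches[[2]]$labels))
  expect_equal(a0, a1, tolerance = 1e-12)
  # one item per class -> each batch has exactly one positive
  ph <- diag(7)
  b7 <- one_vs_rest_batches(ph, 1:7)
  for (i in 1:7) expect_equal(sum(b7[[i]]$labels), 1L)
})

test_that("confusion matrices tally and normalize correctly", {
  cm <- confusion_matrix(c(1, 2, 2), c(1, 1, 2), 2)
  expect_equal(unclass(unname(cm)), matrix(c(1L, 0L, 1L, 1L), 2))
  expect_equal(sum(cm), 3)
  # perfect predictions -> diagonal with the class counts
  cmp <- confusion_matrix(rep(1:3, times = c(5, 2, 3)),
                          rep(1:3, times = c(5, 2, 3)), 3)
  expect_equal(unname(diag(cmp)), c(5L, 2L, 3L))
  nm <- normalize_rows(matrix(c(8, 2, 0, 0), 2, byrow = TRUE))
  expect_equal(nm[1, ], c(0.8, 0.2))
  expect_equal(attr(nm, "zero_rows"), 2L)
  # scale invariance
  m <- matrix(c(3, 1, 2, 6), 2)
  expect_equal(normalize_rows(m), normalize_rows(m * 10))
  expect_error(confusion_matrix(c(0, 1), c(1, 1), 2), "1..k")
})

test_that("report writers produce the documented CSV schemas", {
  dir <- withr::local_tempdir()
  r <- threshold_report(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))
  df <- write_threshold_reports(list("My CNN/Class 0" = r),
                                file.path(dir, "t4.csv"))
  expect_equal(names(df), c("Model", "Class", "AUC", "Y index", "Best T",
                            "ACC", "SEN", "SPE"))
  cm <- confusion_matrix(1:7, 1:7, 7, acne_classes())
  write_confusion(normalize_rows(cm), file.path(dir, "cm.csv"))
  back <- read.csv(file.path(dir, "cm.csv"), row.names = 1)
  expect_equal(dim(back), c(7L, 7L))
  expect_equal(unname(diag(as.matrix(back))), rep(1, 7))
})
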