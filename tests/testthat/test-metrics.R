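# Confusion matrix and evaluation metrics.

test_that("confusion matrix counts true/predicted pairs", {
  cm <- confusion_matrix(c(0, 1, 1), c(0, 1, 0), 2)
  expect_equal(unclass(cm), matrix(c(1L, 1L, 0L, 1L), 2, 2),
               ignore_attr = TRUE)

  y <- c(0L, 1L, 2L, 2L, 1L)
  cmd <- confusion_matrix(y, y, 3)
  expect_equal(diag(unclass(cmd)), c(1L, 2L, 2L), ignore_attr = TRUE)
  expect_equal(sum(cmd) , length(y))

  expect_error(confusion_matrix(c(0, 1), c(0), 2), "length")
  expect_error(confusion_matrix(c(0, 5), c(0, 1), 2), "index 2")
})

test_that("confusion matrix equals the counting-loop oracle on random labels", {
  withr::with_seed(101, {
    for (rep in 1:5) {
      yt <- sample(0:6, 500, replace = TRUE)
      yp <- sample(0:6, 500, replace = TRUE)
      expect_equal(unclass(confusion_matrix(yt, yp, 7)),
                   oracle_confusion(yt, yp, 7), ignore_attr = TRUE)
    }
  })
})

test_that("one-vs-rest counts conserve the sample total", {
  cm <- confusion_matrix(c(0, 1, 1), c(0, 1, 0), 2)
  expect_equal(one_vs_rest_counts(cm, 0),
               c(TP = 1, FP = 1, FN = 0, TN = 1))
  # perfect prediction has no off-diagonal mass
  cmd <- confusion_matrix(0:4, 0:4, 5)
  for (k in 0:4) {
    ct <- one_vs_rest_counts(cmd, k)
    expect_equal(unname(ct[c("FP", "FN")]), c(0, 0))
  }
  withr::with_seed(102, {
    yt <- sample(0:4, 200, replace = TRUE)
    yp <- sample(0:4, 200, replace = TRUE)
    cmr <- confusion_matrix(yt, yp, 5)
    for (k in 0:4) expect_equal(sum(one_vs_rest_counts(cmr, k)), 200)
  })
  expect_error(one_vs_rest_counts(cm, 2), "out of range")
})

test_that("precision, recall, F1 and accuracy follow their definitions", {
  # TP = 9, FP = 1 in class 0 -> precision 0.9
  cm <- confusion_matrix(c(rep(0, 9), rep(1, 1), rep(1, 10)),
                         c(rep(0, 9), rep(0, 1), rep(1, 10)), 2)
  rep1 <- metric_report(cm)
  expect_equal(rep1$per_class$precision[1], 0.9)

  # TP = 8, FP = 2, FN = 2 -> F1 = 16/20 = 0.8
  yt <- c(rep(0, 8), rep(0, 2), rep(1, 2), rep(1, 8))
  yp <- c(rep(0, 8), rep(1, 2), rep(0, 2), rep(1, 8))
  rep2 <- metric_report(confusion_matrix(yt, yp, 2))
  expect_equal(rep2$per_class$f1[1], 0.8)

  # perfect prediction: everything 1
  repp <- metric_report(confusion_matrix(0:3, 0:3, 4))
  expect_equal(repp$accuracy, 1)
  expect_equal(repp$macro_precision, 1)
  expect_equal(repp$macro_recall, 1)
  expect_equal(repp$macro_f1, 1)
})

test_that("macro F1 equals an independent per-class computation", {
  withr::with_seed(103, {
    yt <- sample(0:4, 200, replace = TRUE)
    yp <- sample(0:4, 200, replace = TRUE)
  })
  cm <- confusion_matrix(yt, yp, 5)
  rep <- metric_report(cm)
  f1s <- numeric(5)
  for (k in 0:4) {
    tp <- sum(yt == k & yp == k)
    fp <- sum(yt != k & yp == k)
    fn <- sum(yt == k & yp != k)
    f1s[k + 1] <- 2 * tp / (2 * tp + fp + fn)
  }
  expect_equal(rep$macro_f1, mean(f1s))
  expect_equal(rep$accuracy, mean(yt == yp))
  # micro pooling collapses to accuracy for single-label problems
  expect_equal(rep$micro_precision, rep$accuracy)
  expect_equal(rep$micro_f1, rep$accuracy)
})

test_that("metrics lie in [0,1]; F1 sits between precision and recall", {
  withr::with_seed(104, {
    for (rep_i in 1:10) {
      yt <- sample(0:3, 80, replace = TRUE)
      yp <- sample(0:3, 80, replace = TRUE)
      r <- metric_report(confusion_matrix(yt, yp, 4))
      vals <- c(r$accuracy, r$macro_precision, r$macro_recall, r$macro_f1,
                r$micro_precision, r$micro_recall, r$micro_f1)
      expect_true(all(vals >= 0 & vals <= 1))
      pc <- r$per_class
      ok <- !is.na(pc$precision) & !is.na(pc$recall) & !is.na(pc$f1)
      expect_true(all(pc$f1[ok] <= pmax(pc$precision, pc$recall)[ok] + 1e-12))
      expect_true(all(pc$f1[ok] >= pmin(pc$precision, pc$recall)[ok] - 1e-12))
    }
  })
})

test_that("relabeling classes permutes per-class metrics, fixing aggregates", {
  withr::with_seed(105, {
    yt <- sample(0:4, 300, replace = TRUE)
    yp <- ifelse(stats::runif(300) < 0.7, yt, sample(0:4, 300, replace = TRUE))
  })
  perm <- c(3L, 0L, 4L, 1L, 2L)   # class k -> perm[k+1]
  r1 <- metric_report(confusion_matrix(yt, yp, 5))
  r2 <- metric_report(confusion_matrix(perm[yt + 1], perm[yp + 1], 5))
  expect_equal(r2$accuracy, r1$accuracy)
  expect_equal(r2$macro_f1, r1$macro_f1)
  expect_equal(r2$macro_precision, r1$macro_precision)
  # per-class rows are permuted: class k of r1 appears at perm[k+1] in r2
  expect_equal(r2$per_class$f1[perm + 1], r1$per_class$f1)
})

test_that("zero-denominator classes are excluded from macro means, with a count", {
  # class 2 never occurs and is never predicted
  yt <- c(0, 0, 1, 1)
  yp <- c(0, 1, 1, 1)
  r <- metric_report(confusion_matrix(yt, yp, 3))
  expect_true(is.na(r$per_class$precision[3]))
  expect_identical(r$n_undefined, 1L)
  expect_false(is.na(r$macro_f1))
})

test_that("metrics artifacts round-trip through CSV/JSON", {
  cm <- confusion_matrix(c(0, 1, 1, 2), c(0, 1, 0, 2), 3,
                         class_names = c("apple", "banana", "cherry"))
  r <- metric_report(cm)
  dir <- withr::local_tempdir()
  paths <- write_metrics(r, cm, dir)
  expect_true(all(file.exists(paths)))
  js <- jsonlite::read_json(file.path(dir, "metrics.json"))
  expect_equal(js$accuracy, r$accuracy)
  cm2 <- utils::read.csv(file.path(dir, "confusion.csv"), row.names = 1)
  expect_equal(unname(as.matrix(cm2)), unclass(cm), ignore_attr = TRUE)
})
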