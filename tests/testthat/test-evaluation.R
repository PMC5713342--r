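test_that("confusion tallies predictions against labels", {
  cc <- confusion(c(1, 1, 0, 0), c(0.9, 0.4, 0.2, 0.6))
  expect_identical(cc[c("TP", "FN", "TN", "FP")],
                   list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  perfect <- confusion(c(1, 0), c(0.8, 0.1))
  expect_identical(perfect$FP + perfect$FN, 0L)
  all_pos <- confusion(c(1, 0, 0), c(0.1, 0.2, 0.3), threshold = 0)
  expect_identical(all_pos$TN, 0L)
  expect_error(confusion(integer(0), numeric(0)), "empty")
})

test_that("metric formulas reproduce hand-computed values", {
  m <- classification_metrics(list(TP = 5, TN = 5, FP = 0, FN = 0))
  expect_equal(unname(m), rep(1, 6))
  m <- classification_metrics(list(TP = 8, FN = 2, TN = 7, FP = 3))
  expect_equal(m[["ACC"]], 0.75)
  expect_equal(m[["PE"]], 8 / 11, tolerance = 1e-9)
  expect_equal(m[["RE"]], 0.8)
  expect_equal(m[["SPE"]], 0.7)
  expect_equal(m[["MCC"]], 0.5025, tolerance = 1e-4)
  expect_equal(m[["F1"]], 0.7619, tolerance = 1e-4)
  # every call wrong: accuracy 0, MCC at its -1 extreme
  m <- classification_metrics(list(TP = 0, TN = 0, FP = 5, FN = 5))
  expect_equal(m[["ACC"]], 0)
  expect_equal(m[["MCC"]], -1)
  expect_equal(m[["F1"]], 0)
  # a truly zero MCC denominator: no positive predictions at all
  m <- classification_metrics(list(TP = 0, TN = 5, FP = 0, FN = 5))
  expect_true(is.na(m[["MCC"]]))
})

test_that("undefined denominators are flagged, never zeroed", {
  m <- classification_metrics(list(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_true(is.na(m[["PE"]]))
  expect_true(is.na(m[["RE"]]))
  expect_equal(m[["SPE"]], 1)
})

test_that("metrics satisfy the accuracy decomposition on random tables", {
  set.seed(31)
  for (rep in 1:50) {
    cc <- as.list(setNames(sample(0:30, 4, replace = TRUE),
                           c("TP", "FP", "TN", "FN")))
    m <- classification_metrics(cc)
    P <- cc$TP + cc$FN
    N <- cc$TN + cc$FP
    if (P > 0 && N > 0) {
      expect_equal(m[["ACC"]],
                   (m[["RE"]] * P + m[["SPE"]] * N) / (P + N),
                   tolerance = 1e-12)
    }
  }
})

test_that("rank AUC equals brute-force pairwise comparison", {
  expect_equal(roc_auc(c(1, 0, 1, 0), c(0.8, 0.7, 0.6, 0.3)), 0.75)
  expect_equal(roc_auc(c(1, 1, 0, 0), c(0.9, 0.8, 0.2, 0.1)), 1)
  expect_equal(roc_auc(c(1, 0, 1, 0), rep(0.5, 4)), 0.5)  # all ties
  expect_error(roc_auc(c(1, 1), c(0.2, 0.3)), "one class")
  set.seed(67)
  for (rep in 1:30) {
    n <- sample(4:25, 1)
    labels <- c(1, 0, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 2)  # rounding forces ties
    expect_equal(roc_auc(labels, scores), naive_auc(labels, scores),
                 tolerance = 1e-12)
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(labels, qlogis(pmin(pmax(scores, 0.01), 0.99))),
                 roc_auc(labels, pmin(pmax(scores, 0.01), 0.99)),
                 tolerance = 1e-12)
  }
})

test_that("rank AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(91)
  labels <- sample(0:1, 200, replace = TRUE)
  scores <- runif(200) + 0.3 * labels
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(roc_auc(labels, scores), ref, tolerance = 1e-9)
})

test_that("ROC curve is a valid staircase from (0,0) to (1,1)", {
  set.seed(8)
  labels <- sample(0:1, 60, replace = TRUE)
  scores <- runif(60)
  rc <- roc_curve(labels, scores)
  expect_equal(rc$FPR[1], 0)
  expect_equal(rc$TPR[1], 0)
  expect_equal(rc$FPR[nrow(rc)], 1)
  expect_equal(rc$TPR[nrow(rc)], 1)
  expect_true(all(diff(rc$FPR) >= 0))
  expect_true(all(diff(rc$TPR) >= 0))
})

test_that("stratified folds are balanced, disjoint and seed-stable", {
  labels <- rep(c(1L, 0L), each = 50)
  f1 <- make_folds(labels, k = 5, seed = 42)
  f2 <- make_folds(labels, k = 5, seed = 42)
  f3 <- make_folds(labels, k = 5, seed = 43)
  expect_identical(f1, f2)
  expect_false(identical(f1, f3))
  expect_identical(as.integer(table(f1)), rep(20L, 5))  # equal folds
  for (k in 1:5) {
    expect_identical(sum(labels[f1 == k]), 10L)  # class balance kept
  }
})

test_that("fold aggregation uses mean and sample standard deviation", {
  vals <- c(0.90, 0.92, 0.94)
  expect_equal(mean(vals), 0.92)
  expect_equal(sd(vals), 0.02, tolerance = 1e-9)
})

test_that("cross-validation trains per fold and aggregates", {
  set.seed(55)
  n <- 160
  x <- cbind(matrix(rnorm(n * 3), n, 3), runif(n))
  w <- c(2.5, -2, 1.5, 0)
  y <- as.integer(plogis(x %*% w) > runif(n))
  cfg <- tiny_mlp(4, epochs = 40L, patience = Inf, seed = 2)
  rep1 <- cross_validate(x, y, k = 4, config = cfg, seed = 9)
  rep2 <- cross_validate(x, y, k = 4, config = cfg, seed = 9)
  expect_identical(rep1$fold_assignment, rep2$fold_assignment)
  expect_equal(rep1$folds, rep2$folds)
  expect_identical(nrow(rep1$folds), 4L)
  expect_equal(rep1$mean[["AUC"]], mean(rep1$folds$AUC), tolerance = 1e-12)
  expect_equal(rep1$sd[["ACC"]], sd(rep1$folds$ACC), tolerance = 1e-12)
  # the learnable signal is found on held-out folds
  expect_gt(rep1$mean[["AUC"]], 0.8)
})
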