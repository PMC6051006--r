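test_that("the split reproduces the published train/test protocol sizes", {
  ft <- fake_feature_table(rep(30, 218), rep(60, 232))
  sp <- split_features(ft, seed = 17)
  expect_equal(nrow(sp$train), 200)
  expect_equal(nrow(sp$test), 250)
  expect_equal(sum(sp$test$group == "encephalopathy"), 132)
  expect_equal(sum(sp$test$group == "normal"), 118)
  expect_length(intersect(sp$train$epoch_id, sp$test$epoch_id), 0)
  sp2 <- split_features(ft, seed = 17)
  expect_identical(sp$train$epoch_id, sp2$train$epoch_id)
  expect_error(split_features(ft, c(encephalopathy = 300L, normal = 100L)),
               class = "eegsubband_input_error")
  expect_warning(split_features(ft, c(encephalopathy = 232L, normal = 100L)),
                 "no test epochs")
})

test_that("a separable 1-D problem yields a threshold between the classes", {
  tr <- fake_feature_table(rep(20, 10), rep(80, 10))
  m <- train_linear_svm(tr, bands = "delta")
  thr <- -m$b / m$w[["delta"]]
  expect_gt(thr, 20)
  expect_lt(thr, 80)
  expect_equal(evaluate_classifier(m, tr)$accuracy_pct, 100)
})

test_that("the solver matches the analytic hard-margin oracle and ignores duplicates", {
  # points 0 (normal) and 2 (encephalopathy): minimizing ||(w,b)||^2 under
  # 2w + b >= 1 and -b >= 1 gives w = 1, b = -1 (both constraints active)
  # the weakly regularized intercept (bias feature scale 100) perturbs the
  # ideal solution at O(1e-4); compare at 1e-3
  tr <- fake_feature_table(c(0, 0), c(2, 2))
  m <- train_linear_svm(tr, bands = "delta", C = 100)
  expect_equal(m$w[["delta"]], 1, tolerance = 1e-3)
  expect_equal(m$b, -1, tolerance = 1e-3)
  m_dup <- train_linear_svm(rbind(tr, tr, tr), bands = "delta", C = 100)
  expect_equal(m_dup$w[["delta"]], m$w[["delta"]], tolerance = 1e-3)
  expect_equal(m_dup$b, m$b, tolerance = 1e-3)
})

test_that("training contracts: one-class data and empty subsets error", {
  ft <- fake_feature_table(rep(30, 218), rep(60, 232))
  expect_error(train_linear_svm(ft[ft$group == "normal", ]),
               class = "eegsubband_input_error")
  expect_error(train_linear_svm(ft, bands = character(0)))
  expect_error(train_linear_svm(ft, bands = "gamma"))
})

test_that("metric arithmetic and identities", {
  m <- metrics_from_counts(10, 20, 0, 0)
  expect_equal(c(m$sensitivity_pct, m$specificity_pct, m$accuracy_pct),
               c(100, 100, 100))
  # recomputing from emitted counts reproduces emitted percentages exactly
  set.seed(30)
  ft <- fake_feature_table(rnorm(60, 30, 8), rnorm(60, 60, 12))
  cmp <- run_feature_set_comparison(
    ft, n_train_per_group = c(encephalopathy = 30L, normal = 30L), seed = 2)
  for (i in seq_len(nrow(cmp))) {
    again <- metrics_from_counts(cmp$TP[i], cmp$TN[i], cmp$FP[i], cmp$FN[i])
    expect_identical(again$sensitivity_pct, cmp$sensitivity_pct[i])
    expect_identical(again$specificity_pct, cmp$specificity_pct[i])
    expect_identical(again$accuracy_pct, cmp$accuracy_pct[i])
  }
  expect_error(metrics_from_counts(-1, 2, 3, 4),
               class = "eegsubband_input_error")
})

test_that("a boundary score of exactly zero predicts the positive class", {
  m <- structure(list(w = c(delta = 0), b = 0, bands = "delta", C = 1),
                 class = "linear_svm")
  newdata <- fake_feature_table(25, 75)
  expect_equal(predict(m, newdata), rep("encephalopathy", 2))
})

test_that("metrics are invariant under duplicating the test set", {
  set.seed(31)
  ft <- fake_feature_table(rnorm(40, 30, 8), rnorm(40, 60, 12))
  sp <- split_features(ft, c(encephalopathy = 20L, normal = 20L), seed = 4)
  m <- train_linear_svm(sp$train, bands = "delta")
  one <- evaluate_classifier(m, sp$test)
  two <- evaluate_classifier(m, rbind(sp$test, sp$test))
  expect_equal(two$sensitivity_pct, one$sensitivity_pct)
  expect_equal(two$specificity_pct, one$specificity_pct)
  expect_equal(two$accuracy_pct, one$accuracy_pct)
  expect_equal(two$TP, 2 * one$TP)
})

test_that("subset comparison reuses one split and supports single subsets", {
  set.seed(32)
  ft <- fake_feature_table(rnorm(60, 30, 8), rnorm(60, 60, 12))
  one <- run_feature_set_comparison(
    ft, subsets = list(delta = "delta"),
    n_train_per_group = c(encephalopathy = 30L, normal = 30L), seed = 9)
  expect_equal(nrow(one), 1)
  full <- run_feature_set_comparison(
    ft, n_train_per_group = c(encephalopathy = 30L, normal = 30L), seed = 9)
  expect_equal(full[full$subset == "delta", -1], one[, -1],
               ignore_attr = TRUE)
  expect_equal(full$TP + full$FN + full$TN + full$FP, rep(60L, 4))
})
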