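test_that("k-fold partitions are disjoint, near-equal and seed-reproducible", {
  f <- kfold_partition(1:10, 5, seed = 1)
  expect_equal(lengths(f), rep(2L, 5))
  expect_setequal(unlist(f), 1:10)
  f11 <- kfold_partition(1:11, 5, seed = 1)
  expect_equal(sort(lengths(f11), decreasing = TRUE), c(3L, 2L, 2L, 2L, 2L))
  expect_identical(kfold_partition(letters, 4, seed = 9),
                   kfold_partition(letters, 4, seed = 9))
  expect_error(kfold_partition(1:3, 4), "exceeds")
  expect_error(kfold_partition(1:3, 1), ">= 2")
  # stratified mode keeps classes spread across folds
  lab <- rep(c(TRUE, FALSE), c(5, 15))
  fs <- kfold_partition(1:20, 5, seed = 2, stratify = lab)
  expect_equal(vapply(fs, function(i) sum(lab[i]), 0L), rep(1L, 5))
})

test_that("optimisation reaches AUC 1 on an E/N-separable instance", {
  set.seed(3)
  n <- 100
  fv <- data.frame(E_over_N = c(rnorm(n / 2, -0.02, 0.005),
                                rnorm(n / 2, -0.08, 0.005)),
                   lnS1 = abs(rnorm(n)), lnlp = log(sample(4:9, n, TRUE)),
                   P = rnorm(n, 0, 1e-4))
  lab <- rep(c(1, 0), each = n / 2)
  fit <- optimize_weights(fv, lab, "s1", seed = 3)
  expect_equal(fit$train_auc, 1)
  expect_gt(fit$weights[["alpha"]], 0)
})

test_that("training never falls below the zero-weight starting AUC", {
  sim <- generate_feature_dataset(n = 300, seed = 5)
  fit <- optimize_weights(sim$features, sim$labels, "s1", seed = 5)
  # zero weights make s1 equal P alone
  expect_equal(fit$start_auc, auc(sim$features$P, sim$labels))
  expect_gte(fit$train_auc, fit$start_auc)
  expect_error(optimize_weights(sim$features, rep(1, 300), "s1"), "both classes")
})

test_that("cross_validate yields k x M folds, reproducibly", {
  sim <- generate_feature_dataset(n = 200, seed = 6)
  cv <- cross_validate(sim$features, sim$labels, score = "s2", k = 4, M = 3,
                       seed = 6, restarts = 2)
  expect_equal(nrow(cv$folds), 12L)
  expect_equal(sort(unique(cv$folds$realisation)), 1:3)
  expect_true(all(cv$folds$train_auc >= 0 & cv$folds$train_auc <= 1))
  cv2 <- cross_validate(sim$features, sim$labels, score = "s2", k = 4, M = 3,
                        seed = 6, restarts = 2)
  expect_identical(cv$folds, cv2$folds)
  expect_identical(cv$summary, cv2$summary)
})

test_that("test folds never leak into training", {
  sim <- generate_feature_dataset(n = 200, seed = 8)
  folds <- kfold_partition(seq_len(200), 4, seed = 8)
  test <- folds[[1L]]
  train <- setdiff(seq_len(200), test)
  fit <- optimize_weights(sim$features[train, ], sim$labels[train], "s1", seed = 8)
  s_test <- composite_score("s1", sim$features[test, ], fit$weights)
  a1 <- auc(s_test, sim$labels[test])
  set.seed(80)
  perm <- sample(sim$labels[test])
  if (length(unique(perm)) == 2 && !identical(perm, sim$labels[test])) {
    fit2 <- optimize_weights(sim$features[train, ], sim$labels[train], "s1",
                             seed = 8)
    expect_identical(fit2$train_auc, fit$train_auc) # unchanged by test labels
    expect_false(isTRUE(all.equal(auc(s_test, perm), a1)))
  }
})

test_that("training-set AUC dominates test-set AUC in expectation", {
  sim <- generate_feature_dataset(n = 160, seed = 12)
  cv <- cross_validate(sim$features, sim$labels, score = "s3", k = 2, M = 12,
                       seed = 12, restarts = 2)
  expect_gte(nrow(cv$folds), 20L)
  expect_gt(mean(cv$folds$train_auc), mean(cv$folds$test_auc))
})

test_that("fixed pre-trained scores evaluate per fold without fitting", {
  lab <- rep(c(1, 0), each = 20)
  folds <- kfold_partition(seq_len(40), 4, seed = 2, stratify = lab)
  perfect <- evaluate_fixed_score(as.numeric(lab), lab, folds)
  expect_equal(perfect$test_auc, rep(1, 4))
  expect_identical(evaluate_fixed_score(as.numeric(lab), lab, folds), perfect)
  set.seed(30)
  lab2 <- rep(c(1, 0), each = 300)
  folds2 <- kfold_partition(seq_len(600), 3, seed = 3, stratify = lab2)
  nullsc <- evaluate_fixed_score(rnorm(600), lab2, folds2)
  expect_lt(abs(mean(nullsc$test_auc) - 0.5), 0.1)
})

test_that("single-class folds are skipped with a warning, not an error", {
  sim <- generate_feature_dataset(n = 40, seed = 31)
  lab <- sim$labels
  lab[] <- 0; lab[1:3] <- 1 # 3 positives in 40: single-class folds likely
  w <- capture_warnings(
    cv <- cross_validate(sim$features, lab, score = "s1", k = 5, M = 2,
                         seed = 31, restarts = 1))
  expect_true(all(grepl("single-class", w)) && length(w) > 0)
  expect_lt(nrow(cv$folds), 10L)
  expect_equal(nrow(cv$folds) + cv$skipped, 10L)
})

test_that("llps_train returns a fitted model with working S3 methods", {
  sim <- generate_feature_dataset(n = 250, seed = 13)
  fit <- llps_train(sim$features, sim$labels, score = "s4", k = 5, M = 2,
                    seed = 13, restarts = 2)
  expect_s3_class(fit, "llps_cv")
  expect_named(coef(fit), c("alpha", "beta", "gamma"))
  expect_output(print(fit), "test AUC")
  expect_output(print(summary(fit)), "Fold summary")
  expect_equal(predict(fit),
               composite_score("s4", sim$features, coef(fit)))
  expect_equal(predict(fit, sim$features[1:5, ]),
               predict(fit)[1:5])
  pdf(NULL)
  on.exit(dev.off(), add = TRUE)
  r <- plot(fit)
  expect_s3_class(r, "data.frame")
  expect_named(r, c("threshold", "fpr", "tpr", "mcc"))
})
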