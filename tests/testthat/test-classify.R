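# Classifier fixtures are kept small (<= 27 samples, <= 20 features,
# 100-200 trees) so the LOO-CV loops stay fast while remaining separable.

scaled_fixture <- function(..., seed) {
  sim <- generate_profiles(..., seed = seed)
  list(x = scale_cols_minmax(scale_rows_minmax(impute_missing_zero(sim$profiles))),
       labels = sim$labels, informative = sim$informative_features)
}

test_that("a strongly separable fixture reaches perfect LOO-CV accuracy", {
  fx <- scaled_fixture(n_features = 15, n_informative = 5, class_effect = 10,
                       substance_sd = 0, replicate_sd = 0, seed = 61)
  fit <- tune_and_fit_forest(fx$x, fx$labels, n_trees = 100, seed = 61)
  expect_equal(fit$cv_accuracy, 1)
  expect_equal(sum(diag(fit$cv_confusion)), 27)
})

test_that("confusion matrix bookkeeping is internally consistent", {
  fx <- scaled_fixture(n_features = 12, n_informative = 4, class_effect = 3,
                       seed = 62)
  fit <- tune_and_fit_forest(fx$x, fx$labels, n_trees = 100, seed = 62)
  cm <- fit$cv_confusion
  expect_equal(sum(cm), nrow(fx$x))
  counts <- table(fx$labels$category)
  expect_equal(unname(rowSums(cm)), as.vector(counts[rownames(cm)]))
  expect_equal(accuracy_from_confusion(cm), fit$cv_accuracy)
  expect_equal(nrow(cm), 3L)
  expect_equal(ncol(cm), 3L)
})

test_that("a singleton grid pins the tuned mtry", {
  fx <- scaled_fixture(n_features = 10, n_informative = 4, seed = 63,
                       substances_per_class = 2, replicates_per_substance = 2)
  fit <- tune_and_fit_forest(fx$x, fx$labels, grid = 1, n_trees = 50, seed = 63)
  expect_equal(fit$tuned_mtry, 1L)
  expect_error(
    tune_and_fit_forest(fx$x, fx$labels, grid = 99, n_trees = 50, seed = 1),
    "\\[1, 10\\]"
  )
})

test_that("accuracy_from_confusion computes trace over total", {
  expect_equal(accuracy_from_confusion(matrix(c(5, 0, 0, 5), 2)), 1)
  expect_equal(accuracy_from_confusion(matrix(c(3, 1, 2, 4), 2)), 0.7)
  expect_equal(accuracy_from_confusion(matrix(c(0, 1, 1, 0), 2)), 0)
  expect_error(accuracy_from_confusion(matrix(1:6, 2)), "square")
  expect_error(accuracy_from_confusion(matrix(0, 2, 2)), "zero")
  expect_error(accuracy_from_confusion(matrix(c(1, -1, 0, 2), 2)), "non-negative")
})

test_that("holding out a singleton class errors by name unless dropped", {
  x <- toy_table(rbind(c(0, 1), c(0.1, 0.9), c(1, 0), c(0.9, 0.1), c(0.5, 0.5)))
  labs <- tibble::tibble(sample = x$sample,
                         category = c("a", "a", "b", "b", "lonely"))
  expect_error(tune_and_fit_forest(x, labs, n_trees = 25, seed = 1), "lonely")
  fit <- tune_and_fit_forest(x, labs, n_trees = 25, seed = 1,
                             on_empty_class = "drop")
  # the singleton-class sample can never be predicted correctly
  pred <- fit$cv_predictions
  expect_false(pred$predicted[pred$truth == "lonely"] == "lonely")
})

test_that("predictions are invariant to feature column order", {
  fx <- scaled_fixture(n_features = 12, n_informative = 4, class_effect = 2,
                       seed = 64)
  fit1 <- tune_and_fit_forest(fx$x, fx$labels, grid = 3, n_trees = 50, seed = 64)
  shuffled <- fx$x[, c("sample", sample(names(fx$x)[-1]))]
  fit2 <- tune_and_fit_forest(shuffled, fx$labels, grid = 3, n_trees = 50,
                              seed = 64)
  expect_identical(fit1$cv_predictions, fit2$cv_predictions)
  expect_identical(fit1$importance, fit2$importance)
})

test_that("label permutation drives accuracy to chance and is seed-stable", {
  fx <- scaled_fixture(n_features = 10, n_informative = 4, class_effect = 10,
                       substance_sd = 0, replicate_sd = 0.1,
                       substances_per_class = 2, replicates_per_substance = 2,
                       seed = 65)
  res <- permutation_test_accuracy(fx$x, fx$labels, n_perm = 30, seed = 65,
                                   n_trees = 50, grid = 2)
  expect_equal(res$observed_accuracy, 1)
  expect_lte(res$p_value, 0.05)
  expect_lt(res$null_mean, 0.7)  # far below the separable observed accuracy

  res2 <- permutation_test_accuracy(fx$x, fx$labels, n_perm = 30, seed = 65,
                                    n_trees = 50, grid = 2)
  expect_identical(res$null_accuracies, res2$null_accuracies)
  expect_error(permutation_test_accuracy(fx$x, fx$labels, n_perm = 0, seed = 1),
               "n_perm")
})

test_that("leave-one-substance-out is perfect on separable fixtures", {
  fx <- scaled_fixture(n_features = 15, n_informative = 5, class_effect = 10,
                       substance_sd = 0.2, replicate_sd = 0.2, seed = 66)
  res <- leave_one_substance_out(fx$x, fx$labels, n_trees = 100, seed = 66)
  expect_equal(res$overall_accuracy, 1)
  expect_equal(nrow(res$skipped), 0L)
  expect_equal(nrow(res$predictions), 27L)
})

test_that("substances whose removal empties a class are skipped with reason", {
  fx <- scaled_fixture(n_features = 10, n_informative = 4, class_effect = 8,
                       substances_per_class = 2, replicates_per_substance = 2,
                       seed = 67)
  labs <- fx$labels
  # give one class a single substance by relabeling
  labs$category[labs$substance == "sub01"] <- "unique_class"
  labs$category[labs$substance == "sub02"] <- labs$category[labs$substance == "sub03"][1]
  res <- leave_one_substance_out(fx$x, labs, n_trees = 50, seed = 67)
  expect_equal(res$skipped$substance, "sub01")
  expect_equal(res$skipped$reason, "class emptied")
  expect_false("sub01" %in% res$predictions$substance)
})

test_that("a substance drawn from another class's profile is misclassified", {
  # 4 substances per class so a single rogue substance is outvoted in the
  # training set of its adopted class; noise-free replicates keep the
  # majority decision deterministic
  sim <- generate_profiles(substances_per_class = 4, n_features = 15,
                           n_informative = 5, class_effect = 10,
                           substance_sd = 0, replicate_sd = 0, seed = 68)
  prof <- sim$profiles
  # relocate substance sub01 (class1) onto the class2 profile
  class2_mean <- colMeans(as.matrix(prof[sim$labels$category == "class2", -1]))
  dst <- which(sim$labels$substance == "sub01")
  prof[dst, -1] <- as.data.frame(matrix(class2_mean, length(dst),
                                        length(class2_mean), byrow = TRUE))
  x <- scale_cols_minmax(scale_rows_minmax(prof))
  res <- leave_one_substance_out(x, sim$labels, n_trees = 100, seed = 68)
  wrong <- res$predictions[res$predictions$substance == "sub01", ]
  expect_true(all(!wrong$correct))
  expect_equal(res$overall_accuracy, (36 - 3) / 36)
})

test_that("importance ranking is deterministic, bounded for constants, sliceable", {
  fx <- scaled_fixture(n_features = 12, n_informative = 4, class_effect = 8,
                       seed = 69)
  x <- fx$x
  x$dead_flat <- 0.5
  fit <- tune_and_fit_forest(x, fx$labels, grid = 3, n_trees = 200, seed = 69)
  rk <- rank_features_importance(fit)
  expect_equal(nrow(rk), 13L)
  expect_true(all(diff(rk$importance) <= 0))
  expect_lt(abs(rk$importance[rk$feature == "dead_flat"]), 0.01)
  expect_equal(nrow(rank_features_importance(fit, top = 10)), 10L)

  fit2 <- tune_and_fit_forest(x, fx$labels, grid = 3, n_trees = 200, seed = 69)
  expect_identical(rank_features_importance(fit), rank_features_importance(fit2))
})
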