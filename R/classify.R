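# Random-forest classification of substance categories with leave-one-out
# cross-validated tuning, label-permutation significance, and
# leave-one-substance-out generalization to unseen substances.

default_mtry_grid <- function(p) {
  sort(unique(pmin(pmax(c(1L, ceiling(sqrt(p)), ceiling(p / 3),
                          ceiling(p / 2), p), 1L), p)))
}

# canonical feature order (sorted IDs) so results do not depend on the
# incidental column order of the input table
canonical_features <- function(m) m[, sort(colnames(m)), drop = FALSE]

check_loo_classes <- function(y, on_empty_class) {
  singles <- names(which(table(y) == 1L))
  if (length(singles) && on_empty_class == "error") {
    abort(sprintf(
      "Class(es) emptied by a leave-one-out split: %s. Use on_empty_class = \"drop\" to train without the held-out sample's class.",
      paste(singles, collapse = ", ")
    ))
  }
  invisible(y)
}

# LOO-CV predictions at a fixed mtry; consumes the ambient RNG stream
loo_predictions <- function(m, y, mtry, n_trees, on_empty_class) {
  check_loo_classes(y, on_empty_class)
  pred <- factor(rep(NA_character_, length(y)), levels = levels(y))
  for (i in seq_along(y)) {
    ytr <- droplevels(y[-i])
    fit <- randomForest::randomForest(
      x = m[-i, , drop = FALSE], y = ytr,
      mtry = min(mtry, ncol(m)), ntree = n_trees
    )
    pred[i] <- as.character(predict(fit, m[i, , drop = FALSE]))
  }
  pred
}

confusion_matrix <- function(truth, predicted) {
  cm <- table(true = truth, predicted = factor(predicted, levels = levels(truth)))
  matrix(as.integer(cm), nrow = nrow(cm), dimnames = dimnames(cm))
}

#' Tune and fit a random-forest categorization model
#'
#' Grid-tunes the number of features tried at each split (`mtry`) by
#' leave-one-out cross-validation - one forest per held-out sample per grid
#' value - selects the value with the highest CV accuracy (ties broken
#' toward the smallest), and refits the final forest on all samples at the
#' tuned value with permutation feature importance enabled.
#'
#' @param x A feature table, normally column min-max scaled (see
#'   [scale_cols_minmax()]) so features carry comparable weight.
#' @param labels Label table with `sample` and `category`; at least two
#'   categories.
#' @param grid Integer candidate values for `mtry`, each in
#'   `[1, n_features]`. Default: `{1, ceil(sqrt(p)), ceil(p/3), ceil(p/2),
#'   p}`.
#' @param n_trees Trees per forest (default 500).
#' @param seed Integer seed; all bootstrap and feature-subsampling
#'   randomness flows from it.
#' @param on_empty_class What to do when holding out a sample empties its
#'   class: `"error"` (default) stops naming the class, `"drop"` trains
#'   without the class so the held-out sample is necessarily misclassified
#'   (the situation arising when a category is represented by a single
#'   sample).
#' @return An object of class `forest_eval` with the tuned `mtry`, the CV
#'   accuracy per grid value, the k-by-k CV confusion matrix (rows = true
#'   class), `cv_accuracy`, out-of-bag accuracy of the final fit, per-sample
#'   CV predictions, the permutation importance of every feature, and the
#'   fitted [randomForest::randomForest]. [tidy()] returns the ranked
#'   feature importances, [glance()] a one-row model summary, [autoplot()]
#'   the confusion matrix.
#' @details Features are put in a canonical (sorted) order internally, so
#'   results are invariant to the column order of `x` given the same seed.
#' @export
#' @examples
#' sim <- generate_profiles(n_features = 12, n_informative = 4, seed = 2)
#' x <- sim$profiles |> scale_rows_minmax() |> scale_cols_minmax()
#' fit <- tune_and_fit_forest(x, sim$labels, n_trees = 100, seed = 2)
#' glance(fit)
tune_and_fit_forest <- function(x, labels, grid = NULL, n_trees = 500, seed,
                                on_empty_class = c("error", "drop")) {
  on_empty_class <- match.arg(on_empty_class)
  check_feature_table(x)
  check_no_missing(x, "tune_and_fit_forest")
  check_label_table(labels)
  if (missing(seed) || !is.numeric(seed)) abort("`seed` must be supplied as an integer.")
  m <- canonical_features(feature_matrix(x))
  labels <- align_labels(labels, rownames(m))
  y <- factor(labels$category)
  if (nlevels(y) < 2L) abort("Need at least two categories.")
  p <- ncol(m)
  grid <- if (is.null(grid)) default_mtry_grid(p) else sort(unique(as.integer(grid)))
  if (any(grid < 1L | grid > p)) {
    abort(sprintf("All grid values must lie in [1, %d].", p))
  }

  res <- withr::with_seed(as.integer(seed), {
    preds <- lapply(grid, function(mt) loo_predictions(m, y, mt, n_trees, on_empty_class))
    acc <- vapply(preds, function(pr) mean(pr == y), numeric(1))
    best <- grid[which.max(acc)]  # which.max takes the first (smallest) tie
    final <- randomForest::randomForest(
      x = m, y = y, mtry = best, ntree = n_trees, importance = TRUE
    )
    list(preds = preds, acc = acc, best = best, final = final)
  })

  best_pred <- res$preds[[match(res$best, grid)]]
  imp <- randomForest::importance(res$final, type = 1, scale = FALSE)
  importance <- tibble(feature = rownames(imp),
                       importance = as.numeric(imp[, 1])) |>
    dplyr::arrange(dplyr::desc(.data$importance)) |>
    dplyr::mutate(rank = dplyr::row_number(), .before = 1)

  structure(
    list(
      tuned_mtry = res$best,
      n_trees = n_trees,
      grid = grid,
      grid_accuracy = tibble(mtry = grid, cv_accuracy = res$acc),
      cv_confusion = confusion_matrix(y, best_pred),
      cv_accuracy = mean(best_pred == y),
      oob_accuracy = 1 - res$final$err.rate[n_trees, "OOB"],
      cv_predictions = tibble(sample = rownames(m),
                              truth = as.character(y),
                              predicted = as.character(best_pred)),
      importance = importance,
      forest = res$final,
      seed = as.integer(seed),
      on_empty_class = on_empty_class
    ),
    class = "forest_eval"
  )
}

#' @export
print.forest_eval <- function(x, ...) {
  cat(sprintf("Random-forest categorization (%d trees, tuned mtry = %d)\n",
              x$n_trees, x$tuned_mtry))
  cat(sprintf("  LOO-CV accuracy: %.3f   OOB accuracy: %.3f\n",
              x$cv_accuracy, x$oob_accuracy))
  cat("  CV confusion matrix (rows = true class):\n")
  print(x$cv_confusion)
  invisible(x)
}

#' @rdname tune_and_fit_forest
#' @param x,object A `forest_eval` object.
#' @param ... Unused.
#' @export
tidy.forest_eval <- function(x, ...) x$importance

#' @rdname tune_and_fit_forest
#' @export
glance.forest_eval <- function(x, ...) {
  tibble(
    tuned_mtry = x$tuned_mtry, n_trees = x$n_trees,
    cv_accuracy = x$cv_accuracy, oob_accuracy = x$oob_accuracy,
    n_samples = sum(x$cv_confusion), n_classes = nrow(x$cv_confusion)
  )
}

#' @rdname tune_and_fit_forest
#' @export
autoplot.forest_eval <- function(object, ...) {
  d <- as.data.frame(as.table(object$cv_confusion))
  names(d) <- c("true", "predicted", "n")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$predicted, y = .data$true,
                                  fill = .data$n)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2166ac") +
    ggplot2::scale_y_discrete(limits = rev) +
    ggplot2::labs(x = "Predicted class", y = "True class",
                  title = sprintf("LOO-CV confusion matrix (accuracy %.2f)",
                                  object$cv_accuracy)) +
    ggplot2::theme_minimal()
}

#' Classification accuracy from a confusion matrix
#'
#' The fraction of correctly predicted samples: the trace of the confusion
#' matrix over its total.
#'
#' @param cm A square, non-negative integer matrix (rows = true class,
#'   columns = predicted class) with a positive total.
#' @return A number in \[0, 1\].
#' @export
#' @examples
#' accuracy_from_confusion(matrix(c(3, 1, 2, 4), 2))
accuracy_from_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm)) abort("Confusion matrix must be square.")
  if (any(cm < 0)) abort("Confusion matrix entries must be non-negative.")
  total <- sum(cm)
  if (total == 0) abort("Confusion matrix total is zero.")
  sum(diag(cm)) / total
}

#' Label-permutation test of classification accuracy
#'
#' Compares the observed LOO-CV accuracy of the tuned forest to the
#' distribution of accuracies obtained after randomly permuting the
#' category labels over samples (class sizes preserved) and re-running the
#' whole fit-and-evaluate procedure. The empirical p-value is the
#' proportion of permuted accuracies at least as large as the observed one.
#'
#' @inheritParams tune_and_fit_forest
#' @param n_perm Number of label permutations (default 1000).
#' @param mtry Features tried per split during permutation runs. `NULL`
#'   (default) freezes it at the value tuned on the observed labels;
#'   supply an integer to fix it, or set `retune = TRUE` to re-tune for
#'   every permutation (much slower).
#' @param retune Re-run the grid tuning inside every permutation.
#' @return An object of class `accuracy_permutation` with
#'   `observed_accuracy`, the tuned fit (`fit`), `null_accuracies`,
#'   `null_mean`, `null_sd`, `p_value` and bookkeeping fields;
#'   [tidy()]/[glance()] give a one-row summary, [autoplot()] the null
#'   histogram.
#' @export
permutation_test_accuracy <- function(x, labels, n_perm = 1000, seed,
                                      n_trees = 500, grid = NULL,
                                      mtry = NULL, retune = FALSE,
                                      on_empty_class = c("error", "drop")) {
  on_empty_class <- match.arg(on_empty_class)
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1) {
    abort("`n_perm` must be a positive integer.")
  }
  n_perm <- as.integer(n_perm)
  if (missing(seed) || !is.numeric(seed)) abort("`seed` must be supplied as an integer.")

  fit <- tune_and_fit_forest(x, labels, grid = grid, n_trees = n_trees,
                             seed = seed, on_empty_class = on_empty_class)
  mtry_used <- if (is.null(mtry)) fit$tuned_mtry else as.integer(mtry)

  m <- canonical_features(feature_matrix(x))
  labs <- align_labels(labels, rownames(m))
  y <- factor(labs$category)

  null_accuracies <- withr::with_seed(as.integer(seed) + 1L, {
    vapply(seq_len(n_perm), function(i) {
      yp <- sample(y)
      if (retune) {
        p <- ncol(m)
        g <- if (is.null(grid)) default_mtry_grid(p) else sort(unique(as.integer(grid)))
        accs <- vapply(g, function(mt) {
          mean(loo_predictions(m, yp, mt, n_trees, on_empty_class) == yp)
        }, numeric(1))
        max(accs)
      } else {
        mean(loo_predictions(m, yp, mtry_used, n_trees, on_empty_class) == yp)
      }
    }, numeric(1))
  })

  p_value <- sum(null_accuracies >= fit$cv_accuracy) / n_perm
  structure(
    list(
      observed_accuracy = fit$cv_accuracy,
      fit = fit,
      null_accuracies = null_accuracies,
      null_mean = mean(null_accuracies),
      null_sd = sd(null_accuracies),
      p_value = p_value,
      n_perm = n_perm,
      mtry = mtry_used,
      retune = retune,
      n_trees = n_trees,
      seed = as.integer(seed)
    ),
    class = "accuracy_permutation"
  )
}

#' @export
print.accuracy_permutation <- function(x, ...) {
  cat(sprintf("Label-permutation test of LOO-CV accuracy (%d permutations)\n",
              x$n_perm))
  cat(sprintf("  Observed accuracy: %.3f   permuted: %.3f +/- %.3f\n",
              x$observed_accuracy, x$null_mean, x$null_sd))
  cat(sprintf("  p = %.4g\n", x$p_value))
  invisible(x)
}

#' @rdname permutation_test_accuracy
#' @param x,object An `accuracy_permutation` object.
#' @param ... Unused.
#' @export
tidy.accuracy_permutation <- function(x, ...) {
  tibble(
    observed_accuracy = x$observed_accuracy,
    null_mean = x$null_mean, null_sd = x$null_sd,
    p_value = x$p_value, n_perm = x$n_perm,
    mtry = x$mtry, n_trees = x$n_trees
  )
}

#' @rdname permutation_test_accuracy
#' @export
glance.accuracy_permutation <- function(x, ...) tidy(x)

#' @rdname permutation_test_accuracy
#' @export
autoplot.accuracy_permutation <- function(object, ...) {
  d <- tibble(accuracy = object$null_accuracies)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$accuracy)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey75", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$observed_accuracy,
                        colour = "#b2182b", linewidth = 1) +
    ggplot2::labs(x = "LOO-CV accuracy (label permutations)", y = "Count",
                  title = sprintf("Observed accuracy = %.3f, p = %.3g",
                                  object$observed_accuracy, object$p_value)) +
    ggplot2::theme_minimal()
}

#' Leave-one-substance-out evaluation
#'
#' Measures how well the model categorizes a substance it has never seen:
#' for each parent substance, all of its replicate samples are withheld, a
#' forest is trained on the remaining samples, and the withheld replicates
#' are predicted. Substances whose removal leaves their class with no
#' training samples cannot be evaluated and are skipped with the reason
#' recorded.
#'
#' @inheritParams tune_and_fit_forest
#' @param labels Label table with `sample`, `category` and `substance`
#'   columns; at least two substances.
#' @param mtry Features tried per split; default `ceiling(sqrt(p))`.
#' @return An object of class `loso_eval` with `overall_accuracy` (over all
#'   predicted replicates), a `predictions` tibble (`sample`, `substance`,
#'   `truth`, `predicted`, `correct`) and a `skipped` tibble (`substance`,
#'   `reason`). [tidy()] returns the predictions, [glance()] the summary
#'   row.
#' @export
leave_one_substance_out <- function(x, labels, mtry = NULL, n_trees = 500,
                                    seed) {
  check_feature_table(x)
  check_no_missing(x, "leave_one_substance_out")
  check_label_table(labels, need_substance = TRUE)
  if (missing(seed) || !is.numeric(seed)) abort("`seed` must be supplied as an integer.")
  m <- canonical_features(feature_matrix(x))
  labs <- align_labels(labels, rownames(m))
  y <- factor(labs$category)
  substances <- unique(labs$substance)
  if (length(substances) < 2L) abort("Need at least two substances.")
  if (is.null(mtry)) mtry <- ceiling(sqrt(ncol(m)))

  out <- withr::with_seed(as.integer(seed), {
    purrr::map(substances, function(s) {
      test <- labs$substance == s
      ytr <- y[!test]
      emptied <- setdiff(levels(y), unique(as.character(ytr)))
      if (length(emptied)) {
        return(list(skipped = tibble(substance = s, reason = "class emptied")))
      }
      fit <- randomForest::randomForest(
        x = m[!test, , drop = FALSE], y = droplevels(ytr),
        mtry = min(mtry, ncol(m)), ntree = n_trees
      )
      pred <- as.character(predict(fit, m[test, , drop = FALSE]))
      list(predictions = tibble(
        sample = rownames(m)[test], substance = s,
        truth = as.character(y[test]), predicted = pred,
        correct = pred == as.character(y[test])
      ))
    })
  })

  predictions <- dplyr::bind_rows(purrr::map(out, "predictions"))
  skipped <- dplyr::bind_rows(purrr::map(out, "skipped"))
  if (nrow(predictions) == 0L) {
    abort("Every substance was skipped; no class retains training samples.")
  }
  structure(
    list(
      overall_accuracy = mean(predictions$correct),
      predictions = predictions,
      skipped = if (nrow(skipped)) skipped else tibble(substance = character(),
                                                       reason = character()),
      mtry = mtry, n_trees = n_trees, seed = as.integer(seed)
    ),
    class = "loso_eval"
  )
}

#' @export
print.loso_eval <- function(x, ...) {
  cat(sprintf(
    "Leave-one-substance-out evaluation: accuracy %.3f over %d replicates (%d substance(s) skipped)\n",
    x$overall_accuracy, nrow(x$predictions), nrow(x$skipped)
  ))
  invisible(x)
}

#' @rdname leave_one_substance_out
#' @param x,object A `loso_eval` object.
#' @param ... Unused.
#' @export
tidy.loso_eval <- function(x, ...) x$predictions

#' @rdname leave_one_substance_out
#' @export
glance.loso_eval <- function(x, ...) {
  tibble(
    overall_accuracy = x$overall_accuracy,
    n_predicted = nrow(x$predictions),
    n_skipped = nrow(x$skipped),
    mtry = x$mtry, n_trees = x$n_trees
  )
}

#' Rank features by mean decrease in accuracy
#'
#' Orders the analytical features of a fitted forest by permutation
#' importance: the mean decrease in out-of-bag accuracy, averaged over
#' trees, when the feature's values are permuted. The top of this ranking
#' feeds the ToxPi profiles.
#'
#' @param fit A `forest_eval` object from [tune_and_fit_forest()].
#' @param top Optionally keep only the `top` highest-ranked features.
#' @return A tibble with columns `rank`, `feature`, `importance`, in
#'   descending importance order.
#' @export
rank_features_importance <- function(fit, top = NULL) {
  if (!inherits(fit, "forest_eval")) {
    abort("`fit` must be a forest_eval object from tune_and_fit_forest().")
  }
  out <- fit$importance
  if (!is.null(top)) out <- dplyr::slice_head(out, n = as.integer(top))
  out
}
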