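# Fowlkes-Mallows pair-counting comparison of two flat groupings, and the
# label-permutation null used to judge whether a dendrogram reflects a
# reference categorization better than chance.

as_partition <- function(x, arg = "partition") {
  if (is.data.frame(x)) {
    if (!all(c("sample", "cluster") %in% names(x))) {
      abort(sprintf("`%s` must have columns `sample` and `cluster`.", arg))
    }
    out <- setNames(x$cluster, x$sample)
  } else if (!is.null(names(x))) {
    out <- x
  } else {
    abort(sprintf("`%s` must be a sample/cluster data frame or a named vector.", arg))
  }
  if (anyDuplicated(names(out))) {
    abort(sprintf("`%s` assigns some sample more than once.", arg))
  }
  as.integer(factor(out)) |> setNames(names(out))
}

# pair counts from integer cluster codes (same sample order in a and b)
fm_counts <- function(a, b) {
  ct <- table(a, b)
  tp_plus_fp <- sum(choose(rowSums(ct), 2))
  tp_plus_fn <- sum(choose(colSums(ct), 2))
  tp <- sum(choose(ct, 2))
  c(tp = tp, fp = tp_plus_fp - tp, fn = tp_plus_fn - tp)
}

fm_from_counts <- function(cnt) {
  if (cnt[["tp"]] == 0) return(0)
  sqrt(cnt[["tp"]] / (cnt[["tp"]] + cnt[["fp"]]) *
         cnt[["tp"]] / (cnt[["tp"]] + cnt[["fn"]]))
}

#' Fowlkes-Mallows index between two partitions
#'
#' Pair-counting agreement between two flat groupings of the same samples:
#' over all unordered sample pairs, `TP` pairs are co-clustered in both
#' partitions, `FP` co-clustered only in `p`, `FN` co-clustered only in `q`,
#' and `FM = sqrt(TP / (TP + FP) * TP / (TP + FN))` - the geometric mean of
#' pairwise precision and recall. `FM` is 1 for identical groupings
#' (up to cluster relabeling), 0 when no pair is co-clustered in both, and
#' is symmetric in its arguments.
#'
#' @param p,q Partitions: data frames with columns `sample` and `cluster`
#'   (as returned by [cut_tree()]) or named cluster vectors, over identical
#'   sample sets.
#' @return A one-row tibble with columns `fm`, `tp`, `fp`, `fn`.
#' @details When `TP + FP` or `TP + FN` is zero (e.g. all-singleton
#'   partitions) the index is defined as 0.
#' @export
#' @examples
#' fm_index(c(a = 1, b = 1, c = 2, d = 2), c(a = 1, b = 2, c = 2, d = 2))
fm_index <- function(p, q) {
  p <- as_partition(p, "p")
  q <- as_partition(q, "q")
  if (length(p) != length(q) || !setequal(names(p), names(q))) {
    abort("`p` and `q` must be partitions of the same sample set.")
  }
  q <- q[names(p)]
  cnt <- fm_counts(p, q)
  tibble(fm = fm_from_counts(cnt),
         tp = as.integer(cnt[["tp"]]), fp = as.integer(cnt[["fp"]]),
         fn = as.integer(cnt[["fn"]]))
}

#' Permutation test of dendrogram-categorization agreement
#'
#' Cuts a data-driven dendrogram into as many clusters as there are
#' reference categories, computes the Fowlkes-Mallows index between the cut
#' and the categorization, and compares it to a null distribution obtained
#' by shuffling the category labels over samples (class sizes preserved)
#' and recomputing the index against the same tree cut. The empirical
#' p-value is the proportion of permuted index values at least as large as
#' the observed one.
#'
#' @param tree An [stats::hclust] dendrogram of the samples (e.g. from
#'   [average_linkage_tree()] on a correlation distance matrix).
#' @param labels Label table with `sample` and `category` covering the tree
#'   leaves; at least two categories.
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed making the null distribution reproducible.
#' @param alpha Significance level for the `significant` flag (default 0.05).
#' @param ties `"ge"` (default) counts permuted values equal to the observed
#'   index as extreme; `"gt"` requires strict exceedance.
#' @return An object of class `fm_test` with fields `fm_observed`, `tp`,
#'   `fp`, `fn`, `null_values`, `p_value`, `n_perm`, `alpha`, `significant`,
#'   `k`, `seed`, and the cut `partition`. [tidy()]/[glance()] return a
#'   one-row summary; [autoplot()] draws the null distribution with the
#'   observed value marked.
#' @export
#' @examples
#' sim <- generate_profiles(seed = 7)
#' tree <- sim$profiles |>
#'   standardize_rows_z() |>
#'   correlation_distance_matrix() |>
#'   average_linkage_tree()
#' fm_permutation_test(tree, sim$labels, n_perm = 200, seed = 7)
fm_permutation_test <- function(tree, labels, n_perm = 1000, seed,
                                alpha = 0.05, ties = c("ge", "gt")) {
  ties <- match.arg(ties)
  if (!inherits(tree, "hclust")) abort("`tree` must be an hclust object.")
  check_label_table(labels)
  if (!is.numeric(n_perm) || length(n_perm) != 1L || n_perm < 1) {
    abort("`n_perm` must be a positive integer.")
  }
  n_perm <- as.integer(n_perm)
  if (missing(seed) || !is.numeric(seed)) abort("`seed` must be supplied as an integer.")
  labels <- align_labels(labels, tree$labels)
  k <- length(unique(labels$category))
  if (k < 2L) abort("Need at least two categories.")

  part <- as_partition(cut_tree(tree, k))
  lab <- as.integer(factor(labels$category))
  cnt <- fm_counts(part, lab)
  fm_obs <- fm_from_counts(cnt)

  null_values <- withr::with_seed(as.integer(seed), {
    vapply(seq_len(n_perm), function(i) {
      fm_from_counts(fm_counts(part, sample(lab)))
    }, numeric(1))
  })
  hits <- if (ties == "ge") sum(null_values >= fm_obs) else sum(null_values > fm_obs)
  p_value <- hits / n_perm

  structure(
    list(
      fm_observed = fm_obs,
      tp = as.integer(cnt[["tp"]]), fp = as.integer(cnt[["fp"]]),
      fn = as.integer(cnt[["fn"]]),
      null_values = null_values,
      p_value = p_value,
      n_perm = n_perm,
      alpha = alpha,
      significant = p_value <= alpha,
      k = k,
      seed = as.integer(seed),
      ties = ties,
      partition = tibble(sample = names(part), cluster = unname(part),
                         category = labels$category)
    ),
    class = "fm_test"
  )
}

#' @export
print.fm_test <- function(x, ...) {
  cat(sprintf("Fowlkes-Mallows dendrogram-categorization test (k = %d)\n", x$k))
  cat(sprintf("  FM observed: %.4f   (TP %d, FP %d, FN %d)\n",
              x$fm_observed, x$tp, x$fp, x$fn))
  cat(sprintf("  Null: %d label permutations, mean %.4f, sd %.4f\n",
              x$n_perm, mean(x$null_values), sd(x$null_values)))
  cat(sprintf("  p = %.4g (%ssignificant at alpha = %g)\n",
              x$p_value, if (x$significant) "" else "not ", x$alpha))
  invisible(x)
}

#' @rdname fm_permutation_test
#' @param x,object An `fm_test` object.
#' @param ... Unused.
#' @export
tidy.fm_test <- function(x, ...) {
  tibble(
    fm = x$fm_observed, tp = x$tp, fp = x$fp, fn = x$fn,
    p_value = x$p_value, null_mean = mean(x$null_values),
    null_sd = sd(x$null_values), n_perm = x$n_perm,
    k = x$k, alpha = x$alpha, significant = x$significant
  )
}

#' @rdname fm_permutation_test
#' @export
glance.fm_test <- function(x, ...) tidy(x)

#' @rdname fm_permutation_test
#' @export
autoplot.fm_test <- function(object, ...) {
  d <- tibble(fm = object$null_values)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fm)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey75", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$fm_observed,
                        colour = "#b2182b", linewidth = 1) +
    ggplot2::labs(
      x = "Fowlkes-Mallows index (label permutations)", y = "Count",
      title = sprintf("Observed FM = %.3f, p = %.3g",
                      object$fm_observed, object$p_value)
    ) +
    ggplot2::theme_minimal()
}
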