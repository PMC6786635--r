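# ToxPi weight-of-evidence integration of the top-ranked analytical
# features: per-sample slice values, weighted overall scores, and a PCA map
# of the slice matrix.

#' ToxPi slice values for selected features
#'
#' Extracts the selected feature columns (typically the top-ranked features
#' from [rank_features_importance()]) and min-max scales each one to
#' \[0, 1\] over the included samples, giving the per-sample slice values of
#' a ToxPi profile. Constant features yield all-zero slices.
#'
#' @param x A feature table with at least two samples.
#' @param features Character vector of feature IDs to use as slices, a
#'   subset of the table's features; slice order follows `features`.
#' @return A tibble with `sample` plus one \[0, 1\] column per slice.
#' @export
toxpi_slices <- function(x, features) {
  check_feature_table(x)
  check_no_missing(x, "toxpi_slices")
  if (nrow(x) < 2L) abort("Need at least two samples.")
  features <- as.character(features)
  if (length(features) == 0L) abort("`features` must name at least one feature.")
  unknown <- setdiff(features, names(x)[-1L])
  if (length(unknown)) {
    abort(sprintf("Unknown feature ID(s): %s", paste(unknown, collapse = ", ")))
  }
  x[, c("sample", features)] |>
    dplyr::mutate(dplyr::across(-"sample", minmax_vec))
}

#' Overall ToxPi scores
#'
#' Collapses a slice matrix into one weight-of-evidence score per sample:
#' the weighted mean of its slice values, in \[0, 1\]. Scores are invariant
#' to uniform rescaling of the weights.
#'
#' @param slices A slice tibble from [toxpi_slices()] (`sample` plus
#'   numeric slice columns).
#' @param weights Positive slice weights: a named vector over the slice
#'   columns, an unnamed vector in column order, or `NULL` (default) for
#'   equal weights.
#' @return A tibble with columns `sample` and `score`, sorted by
#'   decreasing score.
#' @export
#' @examples
#' slices <- tibble::tibble(sample = c("a", "b"), s1 = c(1, 0), s2 = c(0, 0))
#' toxpi_overall_scores(slices)
toxpi_overall_scores <- function(slices, weights = NULL) {
  check_feature_table(slices)
  check_no_missing(slices, "toxpi_overall_scores")
  slice_ids <- names(slices)[-1L]
  if (is.null(weights)) {
    weights <- setNames(rep(1, length(slice_ids)), slice_ids)
  } else {
    if (is.null(names(weights))) {
      if (length(weights) != length(slice_ids)) {
        abort("Unnamed `weights` must have one value per slice.")
      }
      names(weights) <- slice_ids
    }
    missing_w <- setdiff(slice_ids, names(weights))
    if (length(missing_w)) {
      abort(sprintf("No weight given for slice(s): %s", paste(missing_w, collapse = ", ")))
    }
    weights <- weights[slice_ids]
  }
  if (any(!is.finite(weights)) || any(weights <= 0)) {
    abort("All slice weights must be positive.")
  }
  m <- feature_matrix(slices)
  score <- as.numeric(m %*% weights) / sum(weights)
  tibble(sample = slices$sample, score = score) |>
    dplyr::arrange(dplyr::desc(.data$score))
}

#' PCA map of ToxPi slice profiles
#'
#' Column-centered principal component analysis of the slice matrix,
#' mapping samples into two dimensions to depict how the most informative
#' analytical features separate the substances.
#'
#' @param slices A slice tibble from [toxpi_slices()], at least three
#'   samples and two non-degenerate (non-constant) slice dimensions.
#' @return An object of class `scores_pca`: `coordinates` (tibble `sample`,
#'   `PC1`, `PC2`) and `explained_variance` (all component variance
#'   fractions, non-increasing). [tidy()] returns the coordinates,
#'   [glance()] the variance shares, [autoplot()] the scatter map.
#' @details Component signs follow the convention that the
#'   largest-magnitude loading of each component is positive, so
#'   coordinates do not depend on sample order.
#' @export
pca_of_scores <- function(slices) {
  check_feature_table(slices)
  check_no_missing(slices, "pca_of_scores")
  if (nrow(slices) < 3L) abort("PCA of scores needs at least three samples.")
  m <- feature_matrix(slices)
  centered <- scale(m, center = TRUE, scale = FALSE)
  if (sum(apply(centered, 2L, sd) > 0) < 2L) {
    abort("Fewer than two non-degenerate slice dimensions; PCA map is undefined.")
  }
  pc <- prcomp(m, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(ncol(pc$rotation)), function(j) {
    v <- pc$rotation[, j]
    s <- sign(v[which.max(abs(v))])
    if (s == 0) 1 else s
  }, numeric(1))
  coords <- sweep(pc$x, 2L, flip, `*`)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(
      coordinates = tibble(sample = slices$sample,
                           PC1 = coords[, 1], PC2 = coords[, 2]),
      explained_variance = ev
    ),
    class = "scores_pca"
  )
}

#' @export
print.scores_pca <- function(x, ...) {
  cat(sprintf("PCA of ToxPi slice profiles (PC1 %.1f%%, PC2 %.1f%% of variance)\n",
              100 * x$explained_variance[1], 100 * x$explained_variance[2]))
  print(x$coordinates, ...)
  invisible(x)
}

#' @rdname pca_of_scores
#' @param x,object A `scores_pca` object.
#' @param ... Unused.
#' @export
tidy.scores_pca <- function(x, ...) x$coordinates

#' @rdname pca_of_scores
#' @export
glance.scores_pca <- function(x, ...) {
  tibble(pc1_variance = x$explained_variance[1],
         pc2_variance = x$explained_variance[2],
         n_components = length(x$explained_variance))
}

#' @rdname pca_of_scores
#' @export
autoplot.scores_pca <- function(object, ...) {
  ggplot2::ggplot(object$coordinates,
                  ggplot2::aes(x = .data$PC1, y = .data$PC2,
                               label = .data$sample)) +
    ggplot2::geom_point(colour = "#2166ac", size = 2) +
    ggplot2::geom_text(vjust = -0.7, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance[2]),
      title = "PCA of ToxPi slice profiles"
    ) +
    ggplot2::theme_minimal()
}

#' Radial ToxPi profile plot
#'
#' Draws the classic radial "pie" representation: one pie per sample, one
#' slice per feature, slice radius proportional to the \[0, 1\] slice value
#' and slice angle proportional to its weight.
#'
#' @param slices A slice tibble from [toxpi_slices()].
#' @param weights Positive slice weights as in [toxpi_overall_scores()].
#' @return A ggplot object, faceted by sample.
#' @export
plot_toxpi <- function(slices, weights = NULL) {
  check_feature_table(slices)
  slice_ids <- names(slices)[-1L]
  if (is.null(weights)) weights <- setNames(rep(1, length(slice_ids)), slice_ids)
  long <- slices |>
    tidyr::pivot_longer(-"sample", names_to = "slice", values_to = "value") |>
    dplyr::mutate(weight = unname(weights[.data$slice]))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$slice, y = .data$value,
                                     width = .data$weight / max(.data$weight),
                                     fill = .data$slice)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, 1) +
    ggplot2::facet_wrap(~sample) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Feature") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
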