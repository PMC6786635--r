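#' Reduced-rank (de-noised) sample scores via SVD
#'
#' Decomposes the row-standardized profile matrix by singular value
#' decomposition and keeps the smallest number of leading components whose
#' cumulative share of the total variation (squared singular values) reaches
#' `threshold`. The retained sample scores - the data projected onto the
#' leading right singular vectors - replace the raw features in the
#' unsupervised workflow, discarding redundant, noisy directions.
#'
#' @param x A feature table, normally row-z-scored (see
#'   [standardize_rows_z()]); a warning is issued otherwise. At least two
#'   samples and two features.
#' @param threshold Cumulative variance fraction to retain, in (0, 1].
#'   Default 0.85.
#' @return An object of class `chemgroup_reduced` with elements
#'   \describe{
#'     \item{scores}{tibble: `sample` plus one column per retained component
#'       (`C1`, `C2`, ...); column `i` has Euclidean norm equal to the
#'       `i`-th singular value.}
#'     \item{rank}{number of retained components, the minimal rank reaching
#'       `threshold`.}
#'     \item{variance_fractions}{per-component variance fractions for all
#'       components (non-increasing, summing to 1).}
#'     \item{rotation}{feature loadings (right singular vectors) of the
#'       retained components.}
#'     \item{threshold, singular_values}{as supplied / computed.}
#'   }
#'   [tidy()] returns the per-component variance table, [glance()] a
#'   one-row summary, and [autoplot()] a scree plot.
#' @details For reproducibility across platforms each right singular vector
#'   is oriented so that its largest-magnitude loading is positive.
#' @export
#' @examples
#' sim <- generate_profiles(seed = 1)
#' sim$profiles |> standardize_rows_z() |> reduced_rank_scores(0.85)
reduced_rank_scores <- function(x, threshold = 0.85) {
  check_feature_table(x)
  check_no_missing(x, "reduced_rank_scores")
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold > 1) {
    abort("`threshold` must be a single number in (0, 1].")
  }
  if (nrow(x) < 2L || ncol(x) < 3L) {
    abort("Rank reduction needs at least 2 samples and 2 features.")
  }
  if (scaling_state(x) != "row_zscore") {
    warn("Input is not marked row-z-scored; the decomposition is applied to the values as given.")
  }
  m <- feature_matrix(x)
  if (all(m == 0)) abort("Cannot decompose an all-zero matrix.")

  dec <- svd(m)
  # orient each right singular vector: largest-|loading| entry positive
  flip <- vapply(seq_len(ncol(dec$v)), function(j) {
    v <- dec$v[, j]
    sign(v[which.max(abs(v))])
  }, numeric(1))
  flip[flip == 0] <- 1
  dec$v <- sweep(dec$v, 2L, flip, `*`)
  dec$u <- sweep(dec$u, 2L, flip, `*`)

  energy <- dec$d^2
  fractions <- energy / sum(energy)
  r <- which(cumsum(fractions) >= threshold - 1e-12)[1L]

  scores <- dec$u[, seq_len(r), drop = FALSE] %*% diag(dec$d[seq_len(r)], r, r)
  colnames(scores) <- paste0("C", seq_len(r))
  rotation <- dec$v[, seq_len(r), drop = FALSE]
  dimnames(rotation) <- list(colnames(m), paste0("C", seq_len(r)))

  structure(
    list(
      scores = dplyr::bind_cols(tibble(sample = rownames(m)),
                                tibble::as_tibble(as.data.frame(scores))),
      rank = r,
      variance_fractions = fractions,
      rotation = rotation,
      threshold = threshold,
      singular_values = dec$d
    ),
    class = "chemgroup_reduced"
  )
}

#' @export
print.chemgroup_reduced <- function(x, ...) {
  cat(sprintf(
    "Reduced-rank profile scores: %d of %d components (%.1f%% of variation, threshold %.0f%%)\n",
    x$rank, length(x$variance_fractions),
    100 * sum(x$variance_fractions[seq_len(x$rank)]), 100 * x$threshold
  ))
  print(x$scores, ...)
  invisible(x)
}

#' @rdname reduced_rank_scores
#' @param x,object A `chemgroup_reduced` object.
#' @param ... Unused.
#' @export
tidy.chemgroup_reduced <- function(x, ...) {
  tibble(
    component = seq_along(x$variance_fractions),
    singular_value = x$singular_values,
    variance_fraction = x$variance_fractions,
    cumulative_fraction = cumsum(x$variance_fractions),
    retained = seq_along(x$variance_fractions) <= x$rank
  )
}

#' @rdname reduced_rank_scores
#' @export
glance.chemgroup_reduced <- function(x, ...) {
  tibble(
    rank = x$rank,
    n_components = length(x$variance_fractions),
    threshold = x$threshold,
    variance_retained = sum(x$variance_fractions[seq_len(x$rank)])
  )
}

#' @rdname reduced_rank_scores
#' @export
autoplot.chemgroup_reduced <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$component, y = .data$cumulative_fraction)) +
    ggplot2::geom_line(colour = "grey60") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$retained), size = 2) +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "#2166ac", `FALSE` = "grey70"),
                                 name = "retained") +
    ggplot2::labs(x = "Component", y = "Cumulative variance fraction",
                  title = sprintf("Reduced rank r = %d at %.0f%% variation",
                                  object$rank, 100 * object$threshold)) +
    ggplot2::theme_minimal()
}
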