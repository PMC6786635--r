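#' Unfold a long 3D profile into a samples-by-features table
#'
#' Concatenates the two within-sample axes of a three-way profile
#' (sample x axis1 x axis2) into a single feature axis, producing the wide
#' matrix used throughout the grouping workflows. Feature columns are the
#' Cartesian product of the observed `axis1` and `axis2` keys, named
#' `"axis1|axis2"` and ordered axis1-major; combinations never observed for
#' a sample are `NA` (undetected composition, imputed to zero later).
#'
#' @param records Long records: a data frame with columns `sample`, `axis1`,
#'   `axis2`, `value` and unique (sample, axis1, axis2) triples.
#' @return A feature table with one row per sample and
#'   `n_axis1 * n_axis2` feature columns, `scaling_state` `"raw"`.
#' @details Axis keys that all parse as numbers are ordered numerically
#'   (carbon numbers), otherwise lexicographically; samples keep their order
#'   of first appearance.
#' @seealso [collapse_elution_axis()] for summing out `axis1` instead.
#' @export
unfold_long_profile <- function(records) {
  check_long_records(records)
  a1 <- axis_order(records$axis1)
  a2 <- axis_order(records$axis2)
  keys <- as.vector(t(outer(a1, a2, paste, sep = "|")))  # axis1-major
  wide <- records |>
    dplyr::mutate(feature = paste(.data$axis1, .data$axis2, sep = "|")) |>
    dplyr::select("sample", "feature", "value") |>
    tidyr::pivot_wider(names_from = "feature", values_from = "value")
  for (k in setdiff(keys, names(wide))) wide[[k]] <- NA_real_
  out <- wide[, c("sample", keys)]
  check_feature_table(out)
  set_scaling_state(out, "raw")
}

axis_order <- function(v) {
  u <- unique(v)
  num <- suppressWarnings(as.numeric(u))
  if (!anyNA(num)) u[order(num)] else sort(u)
}

#' Collapse the elution axis of a long profile
#'
#' Reduces a three-way profile to one feature per analyte by summing each
#' (sample, analyte) trace over the whole `axis1` (elution-time) dimension,
#' keeping only a selected analyte panel - e.g. restricting a GC-MS run to
#' m/z channels corresponding to polycyclic aromatic hydrocarbons before
#' grouping analysis.
#'
#' @inheritParams unfold_long_profile
#' @param keep_analytes Character vector of `axis2` keys to keep; must be
#'   non-empty and a subset of the observed analytes.
#' @return A feature table with one column per kept analyte (in
#'   `keep_analytes` order), each cell the sum over `axis1`.
#' @export
collapse_elution_axis <- function(records, keep_analytes) {
  check_long_records(records)
  if (length(keep_analytes) == 0L) abort("`keep_analytes` must name at least one analyte.")
  keep_analytes <- as.character(keep_analytes)
  unknown <- setdiff(keep_analytes, unique(records$axis2))
  if (length(unknown)) {
    abort(sprintf("Analytes not present in the profile: %s", paste(unknown, collapse = ", ")))
  }
  out <- records |>
    dplyr::filter(.data$axis2 %in% keep_analytes) |>
    dplyr::summarise(value = sum(.data$value), .by = c("sample", "axis2")) |>
    tidyr::pivot_wider(names_from = "axis2", values_from = "value")
  miss <- setdiff(keep_analytes, names(out))
  for (k in miss) out[[k]] <- NA_real_
  out <- out[, c("sample", keep_analytes)]
  check_feature_table(out)
  set_scaling_state(out, "raw")
}

#' Impute missing measurements as zero
#'
#' Missing entries in analytical chemistry profiles indicate composition
#' that was not detected for a sample, so they are replaced by exact zeros
#' rather than estimated.
#'
#' @param x A feature table.
#' @return The table with every `NA` replaced by 0; all other values are
#'   untouched.
#' @export
impute_missing_zero <- function(x) {
  check_feature_table(x)
  state <- scaling_state(x)
  out <- dplyr::mutate(x, dplyr::across(-"sample", \(v) dplyr::coalesce(v, 0)))
  set_scaling_state(out, state)
}

#' Remove features with negligible variation
#'
#' Drops feature columns whose sample standard deviation (denominator
#' `n - 1`) is zero or strictly below `sd_threshold`. Constant columns carry
#' no grouping information; near-constant ones mostly noise. A threshold of
#' 0.05 is appropriate for small row-scaled data sets; the default 0 removes
#' only exactly constant features.
#'
#' @param x A complete feature table (no missing entries).
#' @param sd_threshold Non-negative removal threshold on the sample SD.
#' @return The filtered table; the IDs of removed features are stored in
#'   attribute `removed_features` (see [removed_features()]).
#' @export
#' @examples
#' x <- tibble::tibble(sample = c("a", "b", "c"),
#'                     flat = c(1, 1, 1), steep = c(0, 1, 2))
#' removed_features(filter_low_variance(x))
filter_low_variance <- function(x, sd_threshold = 0) {
  check_feature_table(x)
  check_no_missing(x, "filter_low_variance")
  if (!is.numeric(sd_threshold) || length(sd_threshold) != 1L || sd_threshold < 0) {
    abort("`sd_threshold` must be a single non-negative number.")
  }
  state <- scaling_state(x)
  sds <- vapply(x[-1L], sd, numeric(1))
  drop <- sds == 0 | sds < sd_threshold
  if (all(drop)) abort("no features survive filtering")
  out <- x[, c(TRUE, !drop)]
  attr(out, "removed_features") <- names(x)[-1L][drop]
  set_scaling_state(out, state)
}

#' @rdname filter_low_variance
#' @export
removed_features <- function(x) {
  attr(x, "removed_features", exact = TRUE) %||% character()
}

#' Row-wise min-max scaling
#'
#' Scales each sample's profile to \[0, 1\] by subtracting the row minimum
#' and dividing by the row range, removing between-sample differences in
#' overall intensity. Constant rows (zero range) map to all zeros.
#'
#' @param x A complete feature table.
#' @return The scaled table, `scaling_state` `"row_minmax"`.
#' @export
scale_rows_minmax <- function(x) {
  check_feature_table(x)
  check_no_missing(x, "scale_rows_minmax")
  m <- feature_matrix(x)
  m <- t(apply(m, 1L, minmax_vec))
  dimnames(m) <- list(x$sample, names(x)[-1L])
  new_feature_table(m, "row_minmax")
}

#' Column-wise min-max scaling
#'
#' Scales each feature to \[0, 1\] across samples, so that every measurement
#' carries approximately equal weight when training classifiers. Usually
#' applied after [scale_rows_minmax()]. Constant columns map to zeros.
#'
#' @param x A complete feature table.
#' @return The scaled table; `scaling_state` becomes
#'   `"row_minmax+col_minmax"` when the input was row-scaled.
#' @export
scale_cols_minmax <- function(x) {
  check_feature_table(x)
  check_no_missing(x, "scale_cols_minmax")
  state <- if (scaling_state(x) %in% c("row_minmax", "row_minmax+col_minmax")) {
    "row_minmax+col_minmax"
  } else {
    "raw"
  }
  out <- dplyr::mutate(x, dplyr::across(-"sample", minmax_vec))
  set_scaling_state(out, state)
}

#' Row-wise z-score standardization
#'
#' Centers and scales each sample's profile to mean 0 and sample standard
#' deviation 1 (denominator `n - 1`), the normalization applied before
#' singular value decomposition in the unsupervised workflow. Constant rows
#' map to all zeros.
#'
#' @param x A complete feature table with at least two features.
#' @return The standardized table, `scaling_state` `"row_zscore"`.
#' @export
standardize_rows_z <- function(x) {
  check_feature_table(x)
  check_no_missing(x, "standardize_rows_z")
  if (ncol(x) < 3L) abort("Row z-scoring needs at least two features.")
  m <- feature_matrix(x)
  zrow <- function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  m <- t(apply(m, 1L, zrow))
  dimnames(m) <- list(x$sample, names(x)[-1L])
  new_feature_table(m, "row_zscore")
}
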