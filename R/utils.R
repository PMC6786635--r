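# Internal helpers shared across the package. A "feature table" is a tibble
# whose first column (`sample`) holds unique sample IDs and whose remaining
# columns are numeric analytical features; the optional `scaling_state`
# attribute tracks which scalings have been applied.

SCALING_STATES <- c("raw", "row_minmax", "row_minmax+col_minmax", "row_zscore")

new_feature_table <- function(mat, scaling_state = "raw") {
  out <- tibble::as_tibble(as.data.frame(mat), .name_repair = "minimal")
  out <- dplyr::bind_cols(tibble(sample = rownames(mat)), out)
  set_scaling_state(out, scaling_state)
}

#' Scaling state of a feature table
#'
#' Feature tables carry a `scaling_state` attribute (`"raw"`,
#' `"row_minmax"`, `"row_minmax+col_minmax"` or `"row_zscore"`) recording
#' which scaling steps have been applied. Tables without the attribute are
#' treated as `"raw"`.
#'
#' @param x A feature table (tibble with a `sample` column).
#' @return A length-one character vector.
#' @export
scaling_state <- function(x) {
  attr(x, "scaling_state", exact = TRUE) %||% "raw"
}

set_scaling_state <- function(x, state) {
  stopifnot(state %in% SCALING_STATES)
  attr(x, "scaling_state") <- state
  x
}

check_feature_table <- function(x, arg = "x") {
  if (!is.data.frame(x) || ncol(x) < 2L) {
    abort(sprintf("`%s` must be a data frame with a `sample` column and at least one feature column.", arg))
  }
  if (names(x)[1L] != "sample") {
    abort(sprintf("The first column of `%s` must be named `sample`.", arg))
  }
  dup <- unique(x$sample[duplicated(x$sample)])
  if (length(dup)) {
    abort(sprintf("Duplicate sample IDs: %s", paste(dup, collapse = ", ")))
  }
  dupf <- unique(names(x)[-1L][duplicated(names(x)[-1L])])
  if (length(dupf)) {
    abort(sprintf("Duplicate feature IDs: %s", paste(dupf, collapse = ", ")))
  }
  bad <- names(x)[-1L][!vapply(x[-1L], is.numeric, logical(1))]
  if (length(bad)) {
    abort(sprintf("Non-numeric feature columns: %s", paste(bad, collapse = ", ")))
  }
  invisible(x)
}

check_no_missing <- function(x, op) {
  if (anyNA(x[-1L])) {
    abort(sprintf(
      "`%s` requires a complete table; impute missing values first (see `impute_missing_zero()`).",
      op
    ))
  }
  invisible(x)
}

# samples-by-features numeric matrix with sample IDs as rownames
feature_matrix <- function(x) {
  check_feature_table(x)
  m <- as.matrix(x[-1L])
  rownames(m) <- x$sample
  storage.mode(m) <- "double"
  m
}

check_label_table <- function(labels, need_substance = FALSE) {
  if (!is.data.frame(labels) || !all(c("sample", "category") %in% names(labels))) {
    abort("`labels` must be a data frame with columns `sample` and `category`.")
  }
  dup <- unique(labels$sample[duplicated(labels$sample)])
  if (length(dup)) {
    abort(sprintf("Duplicate sample IDs in labels: %s", paste(dup, collapse = ", ")))
  }
  if (need_substance && !"substance" %in% names(labels)) {
    abort("`labels` must contain a `substance` column identifying replicate parents.")
  }
  invisible(labels)
}

# align a label table to a vector of sample IDs, erroring on mismatch
align_labels <- function(labels, sample_ids) {
  missing <- setdiff(sample_ids, labels$sample)
  if (length(missing)) {
    abort(sprintf("Labels missing for samples: %s", paste(missing, collapse = ", ")))
  }
  labels[match(sample_ids, labels$sample), , drop = FALSE]
}

minmax_vec <- function(v) {
  r <- range(v)
  if (r[1] == r[2]) rep(0, length(v)) else (v - r[1]) / (r[2] - r[1])
}
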