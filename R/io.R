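#' Read a wide analytical feature table
#'
#' Reads a samples-by-features matrix from delimited text. The first column
#' holds sample IDs and the header row holds feature IDs, the layout produced
#' by typical GC-MS / GCxGC-FID / IM-MS post-processing exports. Missing
#' measurements (empty cells or a declared missing token) are kept as `NA` so
#' that downstream imputation is an explicit step.
#'
#' @param path Path to the file.
#' @param fmt `"csv"` or `"tsv"`.
#' @param missing Character vector of tokens read as missing, besides the
#'   empty cell. Default `"NA"`.
#' @return A feature table: a tibble with a `sample` column followed by
#'   numeric feature columns, `scaling_state` `"raw"`.
#' @details Duplicate sample or feature IDs and non-numeric cells (other than
#'   the missing tokens) are errors that name the offending entry. Negative
#'   values are accepted with a warning: raw analytical intensities are
#'   non-negative, but previously scaled exports need not be.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeLines(c("sample,f1,f2", "s1,1,2", "s2,3,"), tf)
#' read_feature_table(tf)
read_feature_table <- function(path, fmt = c("csv", "tsv"), missing = "NA") {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  delim <- if (fmt == "csv") "," else "\t"
  raw <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = character(), trim_ws = TRUE, show_col_types = FALSE,
    name_repair = "minimal"
  )
  if (ncol(raw) < 2L) abort("Expected a sample-ID column plus at least one feature column.")
  names(raw)[1L] <- "sample"
  dup <- unique(raw$sample[duplicated(raw$sample)])
  if (length(dup)) abort(sprintf("Duplicate sample IDs: %s", paste(dup, collapse = ", ")))
  dupf <- unique(names(raw)[-1L][duplicated(names(raw)[-1L])])
  if (length(dupf)) abort(sprintf("Duplicate feature IDs: %s", paste(dupf, collapse = ", ")))

  na_tokens <- c("", missing)
  parse_col <- function(col, name) {
    col[col %in% na_tokens] <- NA_character_
    num <- suppressWarnings(as.numeric(col))
    bad <- which(!is.na(col) & is.na(num))
    if (length(bad)) {
      abort(sprintf(
        "Non-numeric value %s in feature %s, sample %s",
        dQuote(col[bad[1]]), dQuote(name), dQuote(raw$sample[bad[1]])
      ))
    }
    num
  }
  vals <- purrr::imap(raw[-1L], parse_col)
  out <- dplyr::bind_cols(raw[1L], tibble::as_tibble(vals))
  if (any(unlist(vals, use.names = FALSE) < 0, na.rm = TRUE)) {
    warn("Feature table contains negative values; expected non-negative raw intensities.")
  }
  check_feature_table(out)
  set_scaling_state(out, "raw")
}

#' Write a feature table to delimited text
#'
#' Inverse of [read_feature_table()]: writes the `sample` column first and
#' one column per feature, with `NA` for missing entries.
#'
#' @param x A feature table.
#' @param path Output path.
#' @param fmt `"csv"` or `"tsv"`.
#' @return `x`, invisibly.
#' @export
write_feature_table <- function(x, path, fmt = c("csv", "tsv")) {
  fmt <- match.arg(fmt)
  check_feature_table(x)
  if (fmt == "csv") readr::write_csv(x, path) else readr::write_tsv(x, path)
  invisible(x)
}

#' Read a sample label table
#'
#' Reads per-sample metadata: the grouping category (e.g. a manufacturing
#' class at the 3-, 9- or 16-class level) and optionally the parent substance
#' ID encoding the replicate structure (all replicate runs of one substance
#' share a substance ID).
#'
#' @param path Path to a delimited file with columns `sample`, `category`
#'   and optionally `substance`.
#' @param fmt `"csv"` or `"tsv"`.
#' @return A tibble with columns `sample`, `category` and, when present,
#'   `substance`.
#' @export
read_label_table <- function(path, fmt = c("csv", "tsv")) {
  fmt <- match.arg(fmt)
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  reader <- if (fmt == "csv") readr::read_csv else readr::read_tsv
  out <- reader(path, col_types = readr::cols(.default = readr::col_character()),
                show_col_types = FALSE)
  check_label_table(out)
  out
}

#' Read a long-format 3D profile
#'
#' Reads long records of a three-way profile (sample x elution-axis x
#' analyte), one measurement per row, as columns `sample`, `axis1`, `axis2`,
#' `value`. `axis1` is the ordered axis (elution time index or carbon
#' number); `axis2` the categorical analyte key (m/z channel or molecular
#' class).
#'
#' @param path Path to a CSV file with columns `sample,axis1,axis2,value`.
#' @return A tibble of long records.
#' @export
read_long_profile <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  out <- readr::read_csv(path, col_types = readr::cols(
    sample = readr::col_character(),
    axis1 = readr::col_character(),
    axis2 = readr::col_character(),
    value = readr::col_double()
  ), show_col_types = FALSE)
  check_long_records(out)
  out
}

check_long_records <- function(records) {
  need <- c("sample", "axis1", "axis2", "value")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    abort("Long records need columns `sample`, `axis1`, `axis2`, `value`.")
  }
  if (nrow(records) == 0L) abort("Long records are empty.")
  key <- paste(records$sample, records$axis1, records$axis2, sep = "\r")
  dup <- key[duplicated(key)]
  if (length(dup)) {
    parts <- strsplit(dup[1], "\r", fixed = TRUE)[[1]]
    abort(sprintf(
      "Duplicate (sample, axis1, axis2) record: (%s, %s, %s)",
      parts[1], parts[2], parts[3]
    ))
  }
  invisible(records)
}
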