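test_that("read_feature_table parses wide CSV/TSV with missing entries", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,f1,f2", "a,1,2", "b,3,", "c,NA,6.5"), tf)
  x <- read_feature_table(tf)
  expect_s3_class(x, "tbl_df")
  expect_equal(dim(x), c(3L, 3L))
  expect_equal(scaling_state(x), "raw")
  expect_equal(x$f1, c(1, 3, NA))
  expect_equal(x$f2, c(2, NA, 6.5))
  expect_equal(sum(is.na(x[-1])), 2L)

  tt <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample\tf1", "a\t1", "b\t2"), tt)
  expect_equal(read_feature_table(tt, fmt = "tsv")$f1, c(1, 2))
})

test_that("read_feature_table rejects duplicates and names non-numeric cells", {
  tf <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,f1", "a,1", "a,2"), tf)
  expect_error(read_feature_table(tf), "Duplicate sample IDs.*a")

  tf2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,f1,f1", "a,1,2"), tf2)
  expect_error(read_feature_table(tf2), "Duplicate feature IDs.*f1")

  tf3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,f1,f2", "a,1,2", "b,oops,4"), tf3)
  expect_error(read_feature_table(tf3), "oops.*f1.*b")

  tf4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("sample,f1", "a,-1", "b,2"), tf4)
  expect_warning(read_feature_table(tf4), "negative")
})

test_that("feature tables round-trip through CSV bit-identically", {
  x <- toy_table(matrix(c(1.5, 0.25, -2.75, 1e6, 0.125, 3), 2, 3))
  tf <- withr::local_tempfile(fileext = ".csv")
  suppressWarnings({
    write_feature_table(x, tf)
    y <- read_feature_table(tf)
  })
  expect_identical(as.matrix(y[-1]), as.matrix(x[-1]))
  expect_identical(y$sample, x$sample)
})

test_that("unfold_long_profile builds the axis1-major Cartesian grid", {
  rec <- tidyr::expand_grid(sample = c("A", "B"),
                            axis1 = c("C10", "C11"),
                            axis2 = c("alkane", "aromatic"))
  rec$value <- seq_len(8)
  x <- unfold_long_profile(rec)
  expect_equal(names(x), c("sample", "C10|alkane", "C10|aromatic",
                           "C11|alkane", "C11|aromatic"))
  expect_equal(dim(x), c(2L, 5L))
  expect_equal(x[["C10|alkane"]], c(1, 5))

  # absent combination stays missing for that sample only
  x2 <- unfold_long_profile(rec[-4, ])  # drop A's (C11, aromatic)
  expect_true(is.na(x2[["C11|aromatic"]][x2$sample == "A"]))
  expect_false(is.na(x2[["C11|aromatic"]][x2$sample == "B"]))

  x3 <- unfold_long_profile(tibble::tibble(sample = "A", axis1 = "t1",
                                           axis2 = "m1", value = 2))
  expect_equal(dim(x3), c(1L, 2L))

  expect_error(unfold_long_profile(rec[c(1, 1, 2), ]), "Duplicate")
})

test_that("numeric axis keys are ordered numerically, not lexically", {
  rec <- tidyr::expand_grid(sample = "A", axis1 = c("9", "10"), axis2 = "m")
  rec$value <- c(1, 2)
  expect_equal(names(unfold_long_profile(rec))[-1], c("9|m", "10|m"))
})

test_that("collapse_elution_axis sums traces and validates the analyte panel", {
  rec <- tibble::tibble(
    sample = "A", axis1 = c("t1", "t2", "t3"), axis2 = "m1",
    value = c(1, 2, 3)
  )
  x <- collapse_elution_axis(rec, "m1")
  expect_equal(x$m1, 6)

  expect_error(collapse_elution_axis(rec, c("m1", "mX")), "mX")
  expect_error(collapse_elution_axis(rec, character()), "at least one")
})

test_that("collapsing a 60-sample x 301-analyte profile to a 55-analyte panel", {
  rec <- tidyr::expand_grid(sample = sprintf("s%02d", 1:60),
                            axis1 = sprintf("t%d", 1:3),
                            axis2 = sprintf("m%03d", 1:301))
  rec$value <- seq_len(nrow(rec)) %% 7
  x <- collapse_elution_axis(rec, sprintf("m%03d", 1:55))
  expect_equal(dim(x), c(60L, 56L))
})

test_that("unfold-then-sum agrees with collapse on the same records", {
  withr::local_seed(11)
  rec <- tidyr::expand_grid(sample = paste0("s", 1:5),
                            axis1 = paste0("t", 1:4),
                            axis2 = paste0("m", 1:3))
  rec$value <- round(stats::runif(nrow(rec)), 3)
  wide <- unfold_long_profile(rec)
  collapsed <- collapse_elution_axis(rec, paste0("m", 1:3))
  for (an in paste0("m", 1:3)) {
    cols <- grep(paste0("\\|", an, "$"), names(wide), value = TRUE)
    expect_equal(rowSums(wide[cols]), collapsed[[an]], ignore_attr = TRUE)
  }
})

test_that("impute_missing_zero zeroes exactly the missing cells", {
  x <- toy_table(rbind(c(1, NA, 3), c(4, 5, NA)))
  y <- impute_missing_zero(x)
  expect_equal(unname(as.matrix(y[-1])), rbind(c(1, 0, 3), c(4, 5, 0)))

  z <- toy_table(rbind(c(1, 2), c(3, 4)))
  expect_identical(as.matrix(impute_missing_zero(z)[-1]), as.matrix(z[-1]))

  w <- impute_missing_zero(toy_table(cbind(c(1, 2), c(NA_real_, NA_real_))))
  expect_equal(w$f2, c(0, 0))
})

test_that("filter_low_variance removes zero- and sub-threshold-SD features", {
  x <- toy_table(cbind(flat = c(1, 1, 1), tiny = c(0, 0.01, 0.02),
                       steep = c(0, 1, 2)))
  y <- filter_low_variance(x, sd_threshold = 0.05)
  expect_equal(names(y)[-1], "steep")           # sd(tiny) = 0.01 < 0.05
  expect_equal(removed_features(y), c("flat", "tiny"))

  y0 <- filter_low_variance(x, sd_threshold = 0)
  expect_equal(removed_features(y0), "flat")    # only the zero-SD column

  expect_error(filter_low_variance(toy_table(cbind(c(2, 2), c(7, 7)))),
               "no features survive")
  expect_error(filter_low_variance(toy_table(rbind(c(1, NA)))), "impute")
})

test_that("threshold 0 removes exactly the zero-SD columns on random tables", {
  withr::local_seed(21)
  for (i in 1:20) {
    m <- matrix(stats::rnorm(8 * 6), 8, 6)
    const <- sample.int(6, 2)
    m[, const] <- rep(stats::runif(2), each = 8)
    x <- toy_table(m)
    y <- filter_low_variance(x, 0)
    expect_setequal(removed_features(y), paste0("f", sort(const)))
  }
})

test_that("row min-max scaling maps rows to [0,1] with extremes attained", {
  x <- toy_table(rbind(c(2, 4, 6), c(5, 5, 5), c(-1, 0, 3)))
  y <- scale_rows_minmax(x)
  m <- as.matrix(y[-1])
  expect_equal(unname(m[1, ]), c(0, 0.5, 1))
  expect_equal(unname(m[2, ]), c(0, 0, 0))      # constant row convention
  expect_equal(unname(m[3, ]), c(0, 0.25, 1))
  expect_equal(scaling_state(y), "row_minmax")

  withr::local_seed(5)
  z <- scale_rows_minmax(toy_table(matrix(stats::rnorm(40), 5, 8)))
  mz <- as.matrix(z[-1])
  expect_true(all(mz >= 0 & mz <= 1))
  expect_equal(unname(apply(mz, 1, min)), rep(0, 5))
  expect_equal(unname(apply(mz, 1, max)), rep(1, 5))
})

test_that("column min-max scaling is idempotent and handles degenerate input", {
  x <- toy_table(cbind(c(2, 4, 6), c(1, 1, 1)))
  y <- scale_cols_minmax(x)
  expect_equal(y$f1, c(0, 0.5, 1))
  expect_equal(y$f2, c(0, 0, 0))
  expect_equal(as.matrix(scale_cols_minmax(y)[-1]), as.matrix(y[-1]))

  one <- scale_cols_minmax(toy_table(matrix(c(3, 7), 1)))
  expect_equal(unname(as.matrix(one[-1])[1, ]), c(0, 0))

  st <- scale_cols_minmax(scale_rows_minmax(toy_table(matrix(1:6, 2))))
  expect_equal(scaling_state(st), "row_minmax+col_minmax")
})

test_that("row z-scoring gives mean 0 and sample SD 1 per row", {
  x <- toy_table(rbind(c(1, 2, 3), c(4, 4, 4)))
  y <- standardize_rows_z(x)
  m <- as.matrix(y[-1])
  expect_equal(unname(m[1, ]), c(-1, 0, 1))     # mean 2, sample SD 1
  expect_equal(unname(m[2, ]), c(0, 0, 0))
  expect_equal(scaling_state(y), "row_zscore")

  withr::local_seed(6)
  z <- standardize_rows_z(toy_table(matrix(stats::rexp(60), 6, 10)))
  mz <- as.matrix(z[-1])
  expect_true(all(abs(rowMeans(mz)) < 1e-12))
  expect_equal(unname(apply(mz, 1, stats::sd)), rep(1, 6))
})
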