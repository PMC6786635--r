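#' Generate class- and replicate-structured synthetic profiles
#'
#' Simulates an analytical-chemistry-like feature table with known ground
#' truth, emulating the structure of certified reference materials and
#' petroleum UVCB data sets: substances nested in manufacturing classes,
#' each substance measured as several replicate runs. Informative features
#' carry class-specific mean levels; the remaining features are pure noise
#' with respect to class. Every module of the package can be exercised
#' against the emitted ground-truth labels.
#'
#' @param n_classes Number of classes (default 3).
#' @param substances_per_class Substances nested in each class (default 3).
#' @param replicates_per_substance Replicate runs per substance (default 3).
#' @param n_features Total number of analytical features (default 55).
#' @param n_informative Number of class-informative features (default 10);
#'   these are the first `n_informative` feature columns.
#' @param class_effect Standard deviation of the spread of class means on
#'   the informative features (default 5); larger values separate the
#'   classes more strongly relative to the unit-scale feature noise.
#' @param substance_sd SD of per-substance offsets shared by all replicates
#'   of a substance (default 0.5).
#' @param replicate_sd SD of independent replicate-level noise
#'   (default 0.5).
#' @param missing_rate Fraction of cells set missing (default 0); exactly
#'   `round(missing_rate * n_cells)` cells are blanked.
#' @param seed Integer seed; the output is bit-identical for a given seed.
#' @return A list with elements
#'   \describe{
#'     \item{profiles}{feature table of
#'       `n_classes * substances_per_class * replicates_per_substance`
#'       samples by `n_features` non-negative features
#'       (`NA` where missing was injected), `scaling_state` `"raw"`.}
#'     \item{labels}{label table with `sample`, `category`, `substance`.}
#'     \item{informative_features}{IDs of the class-informative features.}
#'   }
#' @details The value of sample `s` on feature `f` is
#'   `baseline_f + class_mean + substance_offset + replicate_noise`, with
#'   the class term present only on informative features; the matrix is
#'   then shifted by its global minimum so all intensities are
#'   non-negative, mimicking abundance data.
#' @export
#' @examples
#' sim <- generate_profiles(seed = 1)
#' dim(sim$profiles)
generate_profiles <- function(n_classes = 3, substances_per_class = 3,
                              replicates_per_substance = 3,
                              n_features = 55, n_informative = 10,
                              class_effect = 5, substance_sd = 0.5,
                              replicate_sd = 0.5, missing_rate = 0,
                              seed) {
  stopifnot(n_classes >= 2, substances_per_class >= 1,
            replicates_per_substance >= 1, n_features >= 1)
  if (n_informative > n_features) {
    abort("`n_informative` cannot exceed `n_features`.")
  }
  if (class_effect < 0 || substance_sd < 0 || replicate_sd < 0) {
    abort("Effect and noise SDs must be non-negative.")
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    abort("`missing_rate` must lie in [0, 1).")
  }
  if (missing(seed) || !is.numeric(seed)) abort("`seed` must be supplied as an integer.")

  n_sub <- n_classes * substances_per_class
  n <- n_sub * replicates_per_substance
  fwidth <- max(2L, nchar(as.character(n_features)))
  feat_ids <- sprintf(paste0("F%0", fwidth, "d"), seq_len(n_features))

  class_of_sub <- rep(seq_len(n_classes), each = substances_per_class)
  sub_of_sample <- rep(seq_len(n_sub), each = replicates_per_substance)
  class_of_sample <- class_of_sub[sub_of_sample]
  rep_idx <- rep(seq_len(replicates_per_substance), times = n_sub)

  sample_ids <- sprintf("c%d_s%02d_r%d", class_of_sample, sub_of_sample, rep_idx)

  m <- withr::with_seed(as.integer(seed), {
    baseline <- stats::rnorm(n_features)  # common feature-level scale
    class_means <- matrix(0, n_classes, n_features)
    if (n_informative > 0) {
      class_means[, seq_len(n_informative)] <-
        stats::rnorm(n_classes * n_informative, sd = class_effect)
    }
    sub_offsets <- matrix(stats::rnorm(n_sub * n_features, sd = substance_sd),
                          n_sub, n_features)
    noise <- matrix(stats::rnorm(n * n_features, sd = replicate_sd),
                    n, n_features)
    vals <- matrix(baseline, n, n_features, byrow = TRUE) +
      class_means[class_of_sample, , drop = FALSE] +
      sub_offsets[sub_of_sample, , drop = FALSE] +
      noise
    vals <- vals - min(vals)          # shift to non-negative intensities
    vals[vals < 0] <- 0
    n_miss <- round(missing_rate * length(vals))
    if (n_miss > 0) {
      vals[sample.int(length(vals), n_miss)] <- NA_real_
    }
    vals
  })
  dimnames(m) <- list(sample_ids, feat_ids)

  list(
    profiles = new_feature_table(m, "raw"),
    labels = tibble(
      sample = sample_ids,
      category = sprintf("class%d", class_of_sample),
      substance = sprintf("sub%02d", sub_of_sample)
    ),
    informative_features = feat_ids[seq_len(n_informative)]
  )
}
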