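#' Correlation distance between sample profiles
#'
#' Converts pairwise Pearson correlation between sample rows into the
#' distance `d = 1 - r` used for hierarchical clustering of chemical
#' fingerprints: identical profiles are at distance 0, anti-correlated
#' profiles at distance 2.
#'
#' @param x A feature table, or a `chemgroup_reduced` object (its component
#'   scores are used). At least two samples; every row must be non-constant.
#' @return A [stats::dist] object labelled by sample IDs.
#' @export
correlation_distance_matrix <- function(x) {
  if (inherits(x, "chemgroup_reduced")) x <- x$scores
  check_feature_table(x)
  check_no_missing(x, "correlation_distance_matrix")
  if (nrow(x) < 2L) abort("Need at least two samples.")
  m <- feature_matrix(x)
  flat <- rownames(m)[apply(m, 1L, sd) == 0]
  if (length(flat)) {
    abort(sprintf("Constant profile (correlation undefined) for sample(s): %s",
                  paste(flat, collapse = ", ")))
  }
  d <- 1 - cor(t(m))
  stats::as.dist(d)
}

#' Reference distances from a fixed categorization
#'
#' Builds the "gold standard" side of a dendrogram-vs-categorization
#' comparison: samples are one-hot encoded over their categories and
#' Euclidean distances taken between the indicator vectors, so replicate
#' pairs within a category are at distance 0 and all between-category pairs
#' at `sqrt(2)`. Clustering this matrix yields the artificial reference
#' dendrogram whose cut at the number of categories reproduces the
#' categorization exactly.
#'
#' @param labels A label table with columns `sample` and `category`;
#'   at least two samples and two categories.
#' @return A [stats::dist] object labelled by sample IDs.
#' @export
label_reference_distances <- function(labels) {
  check_label_table(labels)
  if (nrow(labels) < 2L) abort("Need at least two samples.")
  cats <- unique(labels$category)
  if (length(cats) < 2L) {
    abort("Reference categorization is degenerate: only one category.")
  }
  onehot <- outer(labels$category, cats, `==`) * 1
  rownames(onehot) <- labels$sample
  dist(onehot)
}

#' Average-linkage (UPGMA) dendrogram
#'
#' Agglomerative hierarchical clustering where the distance between two
#' clusters is the unweighted mean of all cross-pair distances.
#'
#' @param d A [stats::dist] object or a symmetric, non-negative,
#'   zero-diagonal distance matrix.
#' @return An [stats::hclust] tree.
#' @export
average_linkage_tree <- function(d) {
  if (is.matrix(d)) {
    if (nrow(d) != ncol(d) || !isSymmetric(unname(d), tol = 1e-8)) {
      abort("Distance matrix must be square and symmetric.")
    }
    if (any(diag(d) != 0)) abort("Distance matrix must have a zero diagonal.")
    if (any(d < 0)) abort("Distances must be non-negative.")
    d <- stats::as.dist(d)
  } else if (!inherits(d, "dist")) {
    abort("`d` must be a dist object or a symmetric matrix.")
  }
  hclust(d, method = "average")
}

#' Cut a dendrogram into k flat clusters
#'
#' Removes the `k - 1` highest merges of the tree, e.g. cutting at the known
#' number of manufacturing classes before a pair-counting comparison.
#'
#' @param tree An [stats::hclust] tree.
#' @param k Number of clusters, between 1 and the number of leaves.
#' @return A partition: tibble with columns `sample` and integer `cluster`
#'   (1..k, numbered in leaf order of first appearance).
#' @export
cut_tree <- function(tree, k) {
  if (!inherits(tree, "hclust")) abort("`tree` must be an hclust object.")
  n <- length(tree$labels %||% tree$order)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k < 1 || k > n) {
    abort(sprintf("`k` must be an integer between 1 and %d.", n))
  }
  assign <- cutree(tree, k = k)
  tibble(sample = names(assign) %||% as.character(seq_len(n)),
         cluster = as.integer(assign))
}

#' Export a dendrogram as Newick text
#'
#' Writes an [stats::hclust] tree in Newick format with merge heights
#' converted to branch lengths, for use in external tree viewers.
#'
#' @param tree An [stats::hclust] tree.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(tree, path) {
  if (!inherits(tree, "hclust")) abort("`tree` must be an hclust object.")
  if (!requireNamespace("ape", quietly = TRUE)) {
    abort("Newick export requires the `ape` package.")
  }
  ape::write.tree(ape::as.phylo(tree), file = path)
  invisible(path)
}
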