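# Independent brute-force oracles and fixture builders used across tests.

# Pair-enumeration Fowlkes-Mallows oracle: loops over every unordered
# sample pair, independent of the contingency-table implementation.
fm_oracle <- function(p, q) {
  stopifnot(identical(sort(names(p)), sort(names(q))))
  q <- q[names(p)]
  n <- length(p)
  tp <- fp <- fn <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      in_p <- p[i] == p[j]
      in_q <- q[i] == q[j]
      if (in_p && in_q) tp <- tp + 1L
      else if (in_p) fp <- fp + 1L
      else if (in_q) fn <- fn + 1L
    }
  }
  fm <- if (tp == 0L) 0 else sqrt(tp / (tp + fp) * tp / (tp + fn))
  list(fm = fm, tp = tp, fp = fp, fn = fn)
}

random_partition <- function(n, max_k = n) {
  k <- sample.int(max_k, 1)
  stats::setNames(sample.int(k, n, replace = TRUE), paste0("s", seq_len(n)))
}

# tiny wide table fixture
toy_table <- function(values, sample_ids = NULL, feature_ids = NULL) {
  m <- as.matrix(values)
  rownames(m) <- sample_ids %||% rownames(m) %||% paste0("s", seq_len(nrow(m)))
  colnames(m) <- feature_ids %||% colnames(m) %||% paste0("f", seq_len(ncol(m)))
  out <- tibble::as_tibble(as.data.frame(m))
  dplyr::bind_cols(tibble::tibble(sample = rownames(m)), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# four well-separated samples whose correlation tree splits (s1,s2)|(s3,s4)
separated_quartet <- function() {
  toy_table(rbind(
    c(10, 9, 1, 1, 2),
    c(9, 10, 2, 1, 1),
    c(1, 1, 10, 9, 8),
    c(1, 2, 9, 10, 9)
  ))
}
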