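# Internal helpers shared across modules.

.datatable.aware <- TRUE

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Adjusted Rand index between two partitions
#'
#' Measures agreement between two clusterings, corrected for chance; 1 for
#' identical partitions, ~0 for independent ones.
#'
#' @param a,b Vectors of cluster labels of equal length.
#' @return A single numeric value.
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  # degenerate partitions (all singletons / single cluster in both): agreement
  # is perfect iff the contingency structure is, by convention
  if (max_idx == expected) return(as.numeric(sum_ij == max_idx))
  (sum_ij - expected) / (max_idx - expected)
}

#' Best-match Jaccard agreement between two collections of gene sets
#'
#' For each set in `truth` finds the maximally Jaccard-overlapping set in
#' `inferred`; returns the per-truth-set maxima and their mean.
#'
#' @param inferred,truth Named lists of character vectors.
#' @return List with `per_set` (named numeric) and `mean`.
#' @export
best_match_jaccard <- function(inferred, truth) {
  jac <- function(x, y) length(intersect(x, y)) / length(union(x, y))
  per <- vapply(truth, function(tr) {
    if (length(inferred) == 0) return(0)
    max(vapply(inferred, jac, numeric(1), y = tr))
  }, numeric(1))
  list(per_set = per, mean = mean(per))
}

# Hypergeometric over-representation p-value: P(X >= k) with k successes in a
# draw of size n from a universe of N containing K successes.
hyper_p <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

# Centered moving average within a single vector; shrinking window at the
# edges so the output has the same length.
moving_average <- function(x, window) {
  stopifnot(window %% 2 == 1)
  n <- length(x)
  half <- (window - 1) / 2
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - half, 1)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
}

# Entropy (nats) of a discrete label composition.
label_entropy <- function(labels) {
  p <- table(labels) / length(labels)
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Mean local batch-mixing entropy
#'
#' For each cell, the entropy of batch labels among its k nearest neighbours
#' in the given coordinate space; averaged over cells. Higher values mean
#' better mixing.
#'
#' @param coords Numeric matrix, cells x dims.
#' @param batch Batch label per cell.
#' @param k Neighbourhood size.
#' @return A single numeric value.
#' @export
batch_mixing_entropy <- function(coords, batch, k = 20) {
  d <- as.matrix(dist(coords))
  diag(d) <- Inf
  ent <- vapply(seq_len(nrow(d)), function(i) {
    nn <- order(d[i, ])[seq_len(min(k, ncol(d) - 1))]
    label_entropy(batch[nn])
  }, numeric(1))
  mean(ent)
}

# Standardize matrix rows to zero mean / unit variance across columns.
# Zero-variance rows are returned as all-zero with an attribute listing them.
standardize_rows <- function(m) {
  mu <- rowMeans(m)
  z <- m - mu
  s <- sqrt(rowSums(z^2) / (ncol(m) - 1))
  zero <- s == 0 | !is.finite(s)
  s[zero] <- 1
  out <- z / s
  attr(out, "zero_variance") <- which(zero)
  out
}
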