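# Eigengene activity: per regulon, the first right-singular-vector score of
# the standardized member-gene submatrix, with lambda1 (PC1 variance
# fraction) as the co-regulation statistic and a permutation null over
# size-matched random gene sets.

# First singular triplet of a standardized genes x cells matrix via the small
# g x g cross-product. Returns per-cell PC1 scores (sigma1 * v1), lambda1,
# and the total variance split.
eigengene_of <- function(z) {
  cp <- tcrossprod(z)                 # g x g
  ei <- eigen(cp, symmetric = TRUE)
  evals <- pmax(ei$values, 0)
  sigma1 <- sqrt(evals[1])
  u1 <- ei$vectors[, 1]
  scores <- as.vector(crossprod(z, u1))   # = sigma1 * v1
  # Orientation: positive correlation with the mean standardized member row.
  mean_row <- colMeans(z)
  if (sum(scores * mean_row) < 0) scores <- -scores
  list(scores = scores, lambda1 = evals[1] / sum(evals), sigma1 = sigma1)
}

# lambda1 only (cheap path used by permutation nulls).
lambda1_of <- function(z) {
  evals <- eigen(tcrossprod(z), symmetric = TRUE, only.values = TRUE)$values
  evals <- pmax(evals, 0)
  evals[1] / sum(evals)
}

#' Per-cell regulon activity (eigengene scores)
#'
#' For each regulon, member-gene rows of the normalized matrix are
#' standardized (zero mean, unit variance across cells) and the first
#' singular triplet taken; activity is the per-cell PC1 score (sigma1 * v1),
#' sign-oriented to correlate positively with the mean standardized member
#' expression. lambda1 = sigma1^2 / sum(sigma^2) is the fraction of member
#' variance on PC1.
#'
#' @param em `ExpressionMatrix` with normalized layer.
#' @param regulons List of regulons (each with `genes`); from
#'   [infer_regulons()] or constructed.
#' @return An `ActivityMatrix` list: `activity` (regulons x cells),
#'   `zscores` (row-zscored layer), `lambda1`, `dropped_genes`.
#' @export
regulon_activity <- function(em, regulons) {
  norm <- normalized_dense(em)
  genes <- colnames(norm)
  ids <- names(regulons) %||% vapply(regulons, `[[`, character(1), "id")
  act <- matrix(NA_real_, length(regulons), nrow(norm),
                dimnames = list(ids, rownames(norm)))
  lambda1 <- setNames(numeric(length(regulons)), ids)
  dropped <- list()
  for (i in seq_along(regulons)) {
    gs <- regulons[[i]]$genes
    missing <- setdiff(gs, genes)
    if (length(missing) > 0)
      stop("regulon ", ids[i], " has genes absent from the matrix: ",
           paste(head(missing, 5), collapse = ", "))
    z <- standardize_rows(t(norm[, gs, drop = FALSE]))
    zv <- attr(z, "zero_variance")
    if (length(zv) > 0) {
      warning("regulon ", ids[i], ": dropping ", length(zv),
              " zero-variance gene(s)")
      dropped[[ids[i]]] <- gs[zv]
      if (length(zv) == length(gs))
        stop("regulon ", ids[i], ": all member genes have zero variance")
      z <- z[-zv, , drop = FALSE]
    }
    eg <- eigengene_of(z)
    act[i, ] <- eg$scores
    lambda1[i] <- eg$lambda1
  }
  zs <- standardize_rows(act)
  attr(zs, "zero_variance") <- NULL
  structure(list(activity = act, zscores = zs, lambda1 = lambda1,
                 dropped_genes = dropped),
            class = "ActivityMatrix")
}

#' @export
print.ActivityMatrix <- function(x, ...) {
  cat(sprintf("ActivityMatrix: %d regulons x %d cells; lambda1 in [%.2f, %.2f]\n",
              nrow(x$activity), ncol(x$activity),
              min(x$lambda1), max(x$lambda1)))
  invisible(x)
}

#' Permutation significance of regulon co-regulation
#'
#' For each regulon, draws `n_perm` size-matched random gene sets from the
#' matrix's gene pool and computes each set's lambda1 on the standardized
#' submatrix; the regulon is significant when its own lambda1 exceeds the
#' `percentile`-th percentile of its null.
#'
#' @param em `ExpressionMatrix` with normalized layer.
#' @param regulons Regulon list.
#' @param activity Optional precomputed `ActivityMatrix` (recomputed if NULL).
#' @param n_perm Number of permutations (default 1000; < 100 warns).
#' @param percentile Null percentile for the cutoff (default 95).
#' @param seed Seed.
#' @return A `PermutationNull` list: `null_lambda1` (regulons x n_perm),
#'   `threshold`, `lambda1`, `significant`.
#' @export
permutation_significance <- function(em, regulons, activity = NULL,
                                     n_perm = 1000, percentile = 95, seed = 1) {
  if (n_perm < 100)
    warning("n_perm < 100 gives an unstable null percentile")
  if (is.null(activity)) activity <- regulon_activity(em, regulons)
  norm <- normalized_dense(em)
  z_all <- standardize_rows(t(norm))   # genes x cells, standardized once
  usable <- setdiff(seq_len(nrow(z_all)), attr(z_all, "zero_variance"))
  sizes <- vapply(regulons, function(r) length(r$genes), integer(1))
  if (max(sizes) > length(usable)) stop("gene pool smaller than largest regulon")
  set.seed(seed)
  ids <- rownames(activity$activity)
  null <- matrix(NA_real_, length(regulons), n_perm,
                 dimnames = list(ids, NULL))
  for (i in seq_along(regulons)) {
    for (b in seq_len(n_perm)) {
      idx <- usable[sample.int(length(usable), sizes[i])]
      null[i, b] <- lambda1_of(z_all[idx, , drop = FALSE])
    }
  }
  thr <- apply(null, 1, quantile, probs = percentile / 100)
  structure(list(null_lambda1 = null, threshold = thr,
                 lambda1 = activity$lambda1,
                 significant = activity$lambda1 > thr,
                 n_perm = n_perm, percentile = percentile, seed = seed),
            class = "PermutationNull")
}
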