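# Cell-to-cell cosine similarity on program genes, hierarchical clustering,
# and the cross-set vs within-reference similarity test.

#' Cosine similarity of cells on program genes, with cluster tests
#'
#' Computes pairwise cosine similarity between all cells of two sets (the
#' reference set A and a comparison set B) on the normalized expression of
#' the program genes, average-linkage clusters the pooled cells into
#' `k_clusters`, and tests per cluster (one-sided Wilcoxon, BH FDR) whether
#' its cross-set pairwise similarities are higher than the pairwise
#' similarities among all reference cells.
#'
#' @param em_a,em_b `ExpressionMatrix` objects with normalized layers.
#' @param program_genes Gene set defining the comparison space.
#' @param k_clusters Clusters to cut (default 5).
#' @return List: `similarity` (full symmetric matrix, unit diagonal),
#'   `clusters`, `source` ("A"/"B" per cell), `cluster_tests` (data.frame
#'   with p, fdr per cluster).
#' @export
cosine_state_similarity <- function(em_a, em_b, program_genes, k_clusters = 5) {
  ga <- intersect(program_genes, colnames(em_a$counts))
  gb <- intersect(program_genes, colnames(em_b$counts))
  genes <- intersect(ga, gb)
  if (length(genes) == 0) stop("program gene list empty in one of the matrices")
  xa <- normalized_dense(em_a)[, genes, drop = FALSE]
  xb <- normalized_dense(em_b)[, genes, drop = FALSE]
  x <- rbind(xa, xb)
  src <- rep(c("A", "B"), c(nrow(xa), nrow(xb)))
  nrm <- sqrt(rowSums(x^2))
  zero <- nrm == 0
  if (any(zero)) {
    warning(sum(zero), " zero-vector cell(s); similarity 0 by convention")
    nrm[zero] <- 1
  }
  xn <- x / nrm
  sim <- tcrossprod(xn)
  sim[zero, ] <- 0; sim[, zero] <- 0
  diag(sim) <- ifelse(zero, 0, 1)
  rownames(sim) <- colnames(sim) <- paste0(src, "_", seq_along(src))

  hc <- hclust(stats::as.dist(1 - sim), method = "average")
  cl <- cutree(hc, k = k_clusters)
  # Baseline: pairwise similarities among ALL reference (A) cells; per
  # cluster, cross-source pairs inside the cluster are tested against it.
  all_a <- which(src == "A")
  baseline <- sim[all_a, all_a][upper.tri(diag(length(all_a)))]
  tests <- lapply(sort(unique(cl)), function(k) {
    idx <- which(cl == k)
    a_idx <- idx[src[idx] == "A"]; b_idx <- idx[src[idx] == "B"]
    cross <- if (length(a_idx) >= 1 && length(b_idx) >= 1)
      as.vector(sim[a_idx, b_idx, drop = FALSE]) else numeric(0)
    p <- if (length(baseline) >= 2 && length(cross) >= 2)
      suppressWarnings(wilcox.test(cross, baseline, alternative = "greater",
                                   exact = FALSE)$p.value) else NA_real_
    data.frame(cluster = k, n_a = length(a_idx), n_b = length(b_idx), p = p)
  })
  tests <- do.call(rbind, tests)
  tests$fdr <- p.adjust(tests$p, "BH")
  list(similarity = sim, clusters = cl, source = src, cluster_tests = tests)
}
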