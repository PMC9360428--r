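# Regulon inference: correlation clustering of genes followed by
# hypergeometric enrichment of TF-target prior sets inside each cluster; a
# regulon is (cluster ∩ prior targets, TF) at BH FDR <= cutoff and minimum
# size.

#' Infer TF-labelled regulons
#'
#' Genes are clustered by average-linkage hierarchical clustering on
#' 1 - Pearson correlation of their normalized expression profiles, cut into
#' `n_clusters` candidate co-expression clusters. For every (cluster, TF)
#' pair the overlap between the cluster and the TF's prior target set is
#' tested hypergeometrically (universe = genes tested); significant overlaps
#' of at least `min_size` genes are emitted as regulons.
#'
#' @param em `ExpressionMatrix` with normalized layer.
#' @param tf_target_prior data.frame with `tf` and `target` columns.
#' @param min_size Minimum member genes per regulon (default 5).
#' @param fdr_cutoff BH FDR cutoff over all (cluster, TF) tests (default 0.05).
#' @param n_clusters Number of candidate clusters; default `n_genes / 10`.
#' @param min_gene_cells Genes detected in fewer cells are excluded.
#' @return List of `Regulon` lists (`id`, `tf`, `genes`,
#'   `tf_enrichment_fdr`, `cluster`), with an attribute `n_tests`.
#' @export
infer_regulons <- function(em, tf_target_prior, min_size = 5,
                           fdr_cutoff = 0.05, n_clusters = NULL,
                           min_gene_cells = 10) {
  if (is.null(tf_target_prior) || nrow(tf_target_prior) == 0)
    stop("empty TF-target prior")
  norm <- normalized_dense(em)
  detected <- colSums(norm > 0)
  norm <- norm[, detected >= min_gene_cells, drop = FALSE]
  genes <- colnames(norm)
  n_clusters <- n_clusters %||% max(2L, round(ncol(norm) / 10))

  cc <- suppressWarnings(cor(norm))
  cc[is.na(cc)] <- 0
  hc <- hclust(stats::as.dist(1 - cc), method = "average")
  cl <- cutree(hc, k = n_clusters)

  prior <- split(tf_target_prior$target, tf_target_prior$tf)
  prior <- lapply(prior, intersect, y = genes)
  prior <- prior[lengths(prior) > 0]
  N <- length(genes)
  cand <- list(); pvals <- numeric(0)
  for (k in sort(unique(cl))) {
    members <- genes[cl == k]
    if (length(members) < min_size) next
    for (tf in names(prior)) {
      ov <- intersect(members, prior[[tf]])
      if (length(ov) < min_size) next
      p <- hyper_p(length(ov), length(prior[[tf]]), length(members), N)
      cand[[length(cand) + 1]] <- list(tf = tf, genes = sort(ov), cluster = k)
      pvals <- c(pvals, p)
    }
  }
  n_tests <- length(prior) * length(unique(cl))
  if (length(cand) == 0) {
    warning("no regulons found")
    return(structure(list(), n_tests = n_tests))
  }
  # BH over the full candidate test family (non-overlapping pairs count as
  # tests with p = 1 implicitly; we correct over performed tests padded to
  # the family size to stay conservative).
  fdr <- p.adjust(c(pvals, rep(1, max(0, n_tests - length(pvals)))),
                  "BH")[seq_along(pvals)]
  keep <- which(fdr <= fdr_cutoff)
  if (length(keep) == 0) {
    warning("no regulons found at FDR <= ", fdr_cutoff)
    return(structure(list(), n_tests = n_tests))
  }
  regs <- lapply(seq_along(keep), function(i) {
    cd <- cand[[keep[i]]]
    structure(list(id = sprintf("R%03d", i), tf = cd$tf, genes = cd$genes,
                   tf_enrichment_fdr = fdr[keep[i]], cluster = cd$cluster),
              class = "Regulon")
  })
  names(regs) <- vapply(regs, `[[`, character(1), "id")
  structure(regs, n_tests = n_tests)
}

#' @export
print.Regulon <- function(x, ...) {
  cat(sprintf("Regulon %s: TF %s, %d genes, FDR %.3g\n",
              x$id, x$tf, length(x$genes), x$tf_enrichment_fdr))
  invisible(x)
}
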