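# Differential expression between cell groups: per-gene two-sided Wilcoxon
# rank-sum on the normalized layer, BH FDR, with fold-change and
# fraction-expressing filters.

#' Differential expression (Wilcoxon rank-sum)
#'
#' Tests every gene between two disjoint cell groups; reports genes passing
#' `|log2FC| >= lfc_min`, in-group expressing fraction `>= pct_min`, and BH
#' FDR `<= fdr_max`. log2FC compares mean de-logged normalized expression
#' (+1 pseudocount).
#'
#' @param em `ExpressionMatrix` with normalized layer.
#' @param group_a,group_b Disjoint barcode or index vectors.
#' @param lfc_min Fold-change cutoff (default `log2(1.25)`).
#' @param pct_min Fraction of group-a cells expressing (default 0.1).
#' @param fdr_max BH FDR cutoff (default 0.1).
#' @param all_genes Return all tested genes without filtering.
#' @return A `DegTable` data.frame: gene, log2fc, pct_a, pct_b, statistic, p,
#'   fdr.
#' @export
differential_expression <- function(em, group_a, group_b,
                                    lfc_min = log2(1.25), pct_min = 0.1,
                                    fdr_max = 0.1, all_genes = FALSE) {
  norm <- normalized_dense(em)
  a <- norm[group_a, , drop = FALSE]
  b <- norm[group_b, , drop = FALSE]
  if (nrow(a) == 0 || nrow(b) == 0) stop("both groups must be non-empty")
  ia <- rownames(a); ib <- rownames(b)
  if (length(intersect(ia, ib)) > 0) stop("groups overlap")
  res <- lapply(seq_len(ncol(norm)), function(g) {
    wt <- suppressWarnings(wilcox.test(a[, g], b[, g]))
    c(statistic = unname(wt$statistic), p = wt$p.value)
  })
  res <- do.call(rbind, res)
  mean_a <- colMeans(expm1(a)); mean_b <- colMeans(expm1(b))
  out <- data.frame(gene = colnames(norm),
                    log2fc = log2(mean_a + 1) - log2(mean_b + 1),
                    pct_a = colMeans(a > 0), pct_b = colMeans(b > 0),
                    statistic = res[, "statistic"], p = res[, "p"],
                    stringsAsFactors = FALSE)
  out$fdr <- p.adjust(out$p, "BH")
  if (!all_genes)
    out <- out[abs(out$log2fc) >= lfc_min & out$pct_a >= pct_min &
                 out$fdr <= fdr_max, , drop = FALSE]
  rownames(out) <- NULL
  out
}
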