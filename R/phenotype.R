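# Phenotypic-state profiling: hypergeometric enrichment of GMT sets per cell
# group, -log10(FDR) conversion, top-N sets by row sum, binary profiles and
# pairwise Jaccard similarity.

#' Phenotypic state profiles and Jaccard similarity between groups
#'
#' For each group's gene list, every GMT set is tested hypergeometrically
#' against the stated gene universe; FDR-adjusted p-values are converted to
#' `-log10(FDR)`, the `top_n` sets with the largest row sum across groups
#' are retained, and each group's binary profile (enriched at FDR <= 0.1)
#' is compared pairwise by Jaccard index.
#'
#' @param group_genes Named list: per group, its DEG or program gene list.
#' @param gmt_sets Named list of gene sets (non-empty).
#' @param universe Character vector, the shared background gene universe.
#' @param top_n Number of sets retained (default 200).
#' @param fdr_max Enrichment cutoff (default 0.1).
#' @return List: `neglog_fdr` (sets x groups), `profiles` (binary),
#'   `jaccard` (groups x groups), `fdr`.
#' @export
phenotype_state_profile <- function(group_genes, gmt_sets, universe,
                                    top_n = 200, fdr_max = 0.1) {
  if (length(gmt_sets) == 0) stop("empty GMT collection")
  gmt_sets <- lapply(gmt_sets, intersect, y = universe)
  group_genes <- lapply(group_genes, intersect, y = universe)
  N <- length(universe)
  p <- matrix(NA_real_, length(gmt_sets), length(group_genes),
              dimnames = list(names(gmt_sets), names(group_genes)))
  for (s in seq_along(gmt_sets)) for (g in seq_along(group_genes)) {
    k <- length(intersect(gmt_sets[[s]], group_genes[[g]]))
    p[s, g] <- if (k == 0) NA_real_ else
      hyper_p(k, length(gmt_sets[[s]]), length(group_genes[[g]]), N)
  }
  fdr <- matrix(p.adjust(p, "BH"), nrow(p), dimnames = dimnames(p))
  neglog <- -log10(fdr)
  neglog[is.na(neglog)] <- 0
  rs <- rowSums(neglog)
  keep <- order(rs, decreasing = TRUE)[seq_len(min(top_n, nrow(neglog)))]
  keep <- keep[rs[keep] > 0]
  neglog <- neglog[keep, , drop = FALSE]
  profiles <- !is.na(fdr[keep, , drop = FALSE]) & fdr[keep, , drop = FALSE] <= fdr_max
  ng <- length(group_genes)
  jac <- matrix(1, ng, ng, dimnames = list(names(group_genes), names(group_genes)))
  for (i in seq_len(ng)) for (j in seq_len(ng)) if (i != j) {
    u <- sum(profiles[, i] | profiles[, j])
    jac[i, j] <- if (u == 0) 0 else sum(profiles[, i] & profiles[, j]) / u
  }
  list(neglog_fdr = neglog, profiles = profiles, jaccard = jac,
       fdr = fdr[keep, , drop = FALSE])
}
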