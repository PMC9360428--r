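# Consensus doublet detection: per run, synthetic doublets are averaged
# random inter-cluster cell pairs; cells assigning (max Pearson) to a
# synthetic-doublet centroid are flagged, with a rescue step for flagged
# groups showing uniquely upregulated genes; flags are aggregated over runs.

#' Consensus doublet detection
#'
#' @param em `ExpressionMatrix` with a normalized layer.
#' @param clusters Cluster label per cell (>= 2 distinct values).
#' @param n_runs Number of randomized runs.
#' @param consensus_fraction Flag a cell when flagged in at least this
#'   fraction of runs.
#' @param n_synthetic Synthetic doublets per cluster pair per run.
#' @param rescue_min Minimum uniquely upregulated genes (rank-sum FDR < 0.05
#'   vs both constituent clusters) for a flagged group to be rescued.
#' @param seed Seed; run r uses seed + r.
#' @return A `DoubletCallSet` list: `n_flagged_runs` per cell, `consensus`
#'   logical, `n_runs`, `params`.
#' @export
detect_doublets_consensus <- function(em, clusters, n_runs = 50,
                                      consensus_fraction = 0.5,
                                      n_synthetic = 30, rescue_min = 4,
                                      seed = 1) {
  norm <- normalized_dense(em)
  clusters <- as.character(clusters)
  ids <- sort(unique(clusters))
  if (length(ids) < 2) stop("need >= 2 clusters to synthesize inter-cluster doublets")
  n_cells <- nrow(norm)
  pairs <- combn(ids, 2, simplify = FALSE)
  flags <- integer(n_cells)

  for (run in seq_len(n_runs)) {
    set.seed(seed + run)
    cl_centroids <- rowsum(norm, clusters) / as.vector(table(clusters))
    doub_centroids <- t(vapply(pairs, function(pr) {
      i <- sample(which(clusters == pr[1]), n_synthetic, replace = TRUE)
      j <- sample(which(clusters == pr[2]), n_synthetic, replace = TRUE)
      colMeans((norm[i, , drop = FALSE] + norm[j, , drop = FALSE]) / 2)
    }, numeric(ncol(norm))))
    rownames(doub_centroids) <- vapply(pairs, paste, character(1), collapse = "|")
    cents <- rbind(cl_centroids, doub_centroids)
    cors <- cor(t(norm), t(cents))
    best <- rownames(cents)[max.col(cors, ties.method = "first")]
    flagged <- !(best %in% ids)
    # Rescue: flagged cells sharing a doublet centroid are rescued when they
    # show >= rescue_min genes uniquely upregulated vs both constituents.
    for (dc in unique(best[flagged])) {
      cells_dc <- which(best == dc)
      if (length(cells_dc) < 3) next
      pr <- strsplit(dc, "|", fixed = TRUE)[[1]]
      n_up <- uniquely_upregulated_genes(norm, cells_dc,
                                         which(clusters == pr[1]),
                                         which(clusters == pr[2]))
      if (n_up >= rescue_min) flagged[cells_dc] <- FALSE
    }
    flags <- flags + as.integer(flagged)
  }
  structure(list(n_flagged_runs = flags, consensus = flags >= consensus_fraction * n_runs,
                 n_runs = n_runs,
                 params = list(consensus_fraction = consensus_fraction,
                               n_synthetic = n_synthetic,
                               rescue_min = rescue_min, seed = seed)),
            class = "DoubletCallSet")
}

# Count genes upregulated (one-sided rank-sum, BH FDR < 0.05) in `group`
# versus BOTH reference cell sets. Genes are pre-screened by mean difference
# to keep the test count modest.
uniquely_upregulated_genes <- function(norm, group, ref_a, ref_b, fdr = 0.05) {
  gm <- colMeans(norm[group, , drop = FALSE])
  am <- colMeans(norm[ref_a, , drop = FALSE])
  bm <- colMeans(norm[ref_b, , drop = FALSE])
  cand <- which(gm > am & gm > bm)
  cand <- cand[order(pmin(gm - am, gm - bm)[cand], decreasing = TRUE)]
  cand <- head(cand, 50)
  if (length(cand) == 0) return(0)
  p <- vapply(cand, function(g) {
    pa <- wilcox.test(norm[group, g], norm[ref_a, g],
                      alternative = "greater", exact = FALSE)$p.value
    pb <- wilcox.test(norm[group, g], norm[ref_b, g],
                      alternative = "greater", exact = FALSE)$p.value
    max(pa, pb)
  }, numeric(1))
  sum(p.adjust(p, "BH") < fdr)
}
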