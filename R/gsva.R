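# Single-sample gene-set enrichment: weighted Kolmogorov-Smirnov running-sum
# statistic per cell (hit weight proportional to the absolute centred rank
# statistic, miss weight 1/(N - |G|)), with a per-cell permutation null in
# which the gene ranking is randomized.

# ES for hit positions `pos` (sorted, 1-based) in a ranking of length N with
# positional weights `w_all`; signed maximum deviation of the running sum.
ks_running_es <- function(pos, N, w_all) {
  k <- length(pos)
  w <- w_all[pos]
  tot <- sum(w)
  if (tot == 0) w <- rep(1 / k, k) else w <- w / tot
  cumw <- cumsum(w)
  miss <- 1 / (N - k)
  after <- cumw - (pos - seq_len(k)) * miss
  before <- c(0, cumw[-k]) - (pos - seq_len(k)) * miss
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' Per-cell gene-set enrichment with permutation nulls
#'
#' For each cell, genes are ranked by normalized expression (descending);
#' the enrichment score of a set is the signed maximum deviation of a
#' weighted KS running sum (hit weight proportional to |N/2 - rank + 1/2|,
#' miss weight 1/(N - |G|)). The per-cell null randomizes the set's rank
#' positions `n_perm` times; a set is enriched in a cell when its ES exceeds
#' the `percentile`-th percentile of that null. Group-level enrichment of
#' flagged cells is reported with a BH-corrected hypergeometric test.
#'
#' @param em `ExpressionMatrix` with normalized layer.
#' @param gene_sets Named list of character vectors.
#' @param n_perm Permutations per cell and set size (default 1000).
#' @param percentile Null percentile (default 95).
#' @param groups Optional group label per cell.
#' @param seed Seed.
#' @return An `EnrichmentResult` list: `es` (cells x sets), `enriched`
#'   (logical, same shape), `null_threshold` (cells x set sizes used),
#'   `group_enrichment` (data.frame with BH FDR and `significant` at 0.1).
#' @export
gsva_enrichment <- function(em, gene_sets, n_perm = 1000, percentile = 95,
                            groups = NULL, seed = 1) {
  norm <- normalized_dense(em)
  genes <- colnames(norm)
  sets <- lapply(gene_sets, intersect, y = genes)
  empty <- lengths(sets) == 0
  if (any(empty)) {
    warning("skipping gene sets with no genes in the matrix: ",
            paste(names(sets)[empty], collapse = ", "))
    sets <- sets[!empty]
  }
  if (length(sets) == 0) stop("no usable gene sets")
  N <- length(genes)
  w_all <- abs(N / 2 - seq_len(N) + 0.5)
  n_cells <- nrow(norm)
  set.seed(seed)
  es <- matrix(NA_real_, n_cells, length(sets),
               dimnames = list(rownames(norm), names(sets)))
  enriched <- es
  sizes <- sort(unique(lengths(sets)))
  thr_by_size <- matrix(NA_real_, n_cells, length(sizes),
                        dimnames = list(rownames(norm), as.character(sizes)))
  set_idx <- lapply(sets, match, table = genes)
  for (c_i in seq_len(n_cells)) {
    ord <- order(norm[c_i, ], decreasing = TRUE)
    pos_of <- integer(N); pos_of[ord] <- seq_len(N)
    # Null thresholds per set size: random position draws emulate a
    # randomized gene ranking.
    for (s_i in seq_along(sizes)) {
      k <- sizes[s_i]
      null_es <- vapply(seq_len(n_perm), function(b)
        ks_running_es(sort(sample.int(N, k)), N, w_all), numeric(1))
      thr_by_size[c_i, s_i] <- quantile(null_es, percentile / 100)
    }
    for (s in seq_along(sets)) {
      pos <- sort(pos_of[set_idx[[s]]])
      es[c_i, s] <- ks_running_es(pos, N, w_all)
      enriched[c_i, s] <- es[c_i, s] > thr_by_size[c_i, as.character(length(pos))]
    }
  }
  enriched <- enriched > 0
  group_enrichment <- NULL
  if (!is.null(groups)) {
    rows <- list()
    for (s in colnames(es)) for (g in sort(unique(as.character(groups)))) {
      in_g <- groups == g
      k <- sum(enriched[in_g, s]); K <- sum(enriched[, s]); n <- sum(in_g)
      rows[[length(rows) + 1]] <- data.frame(
        set = s, group = g, k = k, n = n, K = K, N = n_cells,
        p = hyper_p(k, K, n, n_cells), stringsAsFactors = FALSE)
    }
    group_enrichment <- do.call(rbind, rows)
    group_enrichment$fdr <- p.adjust(group_enrichment$p, "BH")
    group_enrichment$significant <- group_enrichment$fdr <= 0.1
  }
  structure(list(es = es, enriched = enriched, null_threshold = thr_by_size,
                 group_enrichment = group_enrichment,
                 n_perm = n_perm, percentile = percentile, seed = seed),
            class = "EnrichmentResult")
}
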