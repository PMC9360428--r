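# Consensus TF calling: correlate each TF's motif deviation z-scores with
# the gene score of its own gene across cells, filter on correlation, FDR
# and inter-group deviation difference, and intersect with the regulon TF
# set.

#' Correlate motif deviations with TF gene scores
#'
#' Pearson correlation across cells between a TF motif's deviation z-scores
#' and the distance-weighted gene score of the TF's own gene, BH-corrected
#' over TFs; also reports each TF's maximum inter-group mean-z difference.
#'
#' @param deviations `MotifDeviationResult`.
#' @param gene_scores Sparse cells x genes gene-score matrix.
#' @param tf_gene_map data.frame with `tf`, `motif_id`, `tf_gene`.
#' @param groups Group label per cell (e.g. network states).
#' @return data.frame per TF: `tf`, `corr`, `p`, `fdr`, `max_group_diff`.
#' @export
correlate_deviation_genescore <- function(deviations, gene_scores, tf_gene_map,
                                          groups) {
  cells <- colnames(deviations$z)
  stopifnot(all(cells %in% rownames(gene_scores)),
            length(groups) == length(cells))
  rows <- list()
  for (i in seq_len(nrow(tf_gene_map))) {
    tf <- tf_gene_map$tf[i]; mo <- tf_gene_map$motif_id[i]
    g <- tf_gene_map$tf_gene[i]
    if (!mo %in% rownames(deviations$z)) next
    if (!g %in% colnames(gene_scores)) {
      warning("TF gene absent from gene scores, skipping TF: ", tf)
      next
    }
    zv <- deviations$z[mo, ]
    gv <- as.numeric(gene_scores[cells, g])
    ok <- is.finite(zv)
    ct <- suppressWarnings(cor.test(zv[ok], gv[ok]))
    gm <- tapply(zv[ok], as.character(groups)[ok], mean)
    diffs <- if (length(gm) >= 2) max(dist(gm)) else 0
    rows[[length(rows) + 1]] <- data.frame(
      tf = tf, motif_id = mo, corr = unname(ct$estimate), p = ct$p.value,
      max_group_diff = diffs, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out$fdr <- p.adjust(out$p, "BH")
  out
}

#' Select consensus TFs
#'
#' A TF passes the accessibility filters when its deviation-gene-score
#' correlation is `>= corr_min`, FDR `<= fdr_max`, and its maximum
#' inter-group deviation difference lies in the upper `1 - quantile` tail of
#' all TFs. Consensus TFs are the passing TFs that also drive a regulon.
#'
#' @param tf_stats From [correlate_deviation_genescore()] (>= 2 TFs).
#' @param regulon_tfs Character vector of regulon TF identifiers (non-empty).
#' @param corr_min Correlation threshold (default 0.4).
#' @param fdr_max FDR threshold (default 0.1).
#' @param quantile Quantile cut for the group-difference filter (default 0.5
#'   = upper half).
#' @param deviations Optional `MotifDeviationResult` for the per-TF
#'   positive-deviation state composition.
#' @param groups Optional state label per cell (needed with `deviations`).
#' @return data.frame of `ConsensusTfCall`s: per TF the statistics, the
#'   `passes` flag, `in_regulon_tfs`, `consensus`; attribute
#'   `state_composition` (list per consensus TF).
#' @export
select_consensus_tfs <- function(tf_stats, regulon_tfs, corr_min = 0.4,
                                 fdr_max = 0.1, quantile = 0.5,
                                 deviations = NULL, groups = NULL) {
  if (nrow(tf_stats) < 2) stop("need statistics for >= 2 TFs")
  if (length(regulon_tfs) == 0) stop("empty regulon TF set")
  diff_cut <- stats::quantile(tf_stats$max_group_diff, quantile)
  out <- tf_stats
  out$passes <- out$corr >= corr_min & out$fdr <= fdr_max &
    out$max_group_diff >= diff_cut
  out$in_regulon_tfs <- out$tf %in% regulon_tfs
  out$consensus <- out$passes & out$in_regulon_tfs
  if (!is.null(deviations) && !is.null(groups)) {
    comp <- lapply(out$motif_id[out$consensus], function(mo) {
      zv <- deviations$z[mo, ]
      pos <- is.finite(zv) & zv > 0
      if (!any(pos)) return(table(character(0)))
      prop.table(table(as.character(groups)[pos]))
    })
    names(comp) <- out$tf[out$consensus]
    attr(out, "state_composition") <- comp
  }
  out
}
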