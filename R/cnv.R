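# Moving-average CNV caller: per-cell relative expression against a
# non-tumour reference, smoothed along genome order within chromosomes;
# tumour call = chr7 arm gain AND chr10 arm loss.

#' Infer per-cell CNV profiles and tumour calls
#'
#' Relative expression = normalized expression minus the per-gene mean over
#' reference cells, median-centred per cell, clipped to ±3, smoothed by a
#' centred moving average of
#' `window` genes within each chromosome (genes ordered by position). Arm
#' score = mean smoothed value per chromosome arm. A cell is called tumour
#' when its mean chr7 score exceeds `+arm_threshold` and its mean chr10
#' score is below `-arm_threshold`.
#'
#' @param em `ExpressionMatrix` with normalized layer; `gene_meta` must have
#'   `chrom`, `arm`, and `tss` (position).
#' @param reference_cells Barcodes (or indices) of non-tumour reference cells.
#' @param window Odd moving-average window in genes (default 101).
#' @param arm_threshold Arm-score threshold (default 0.1).
#' @return A `CnvProfile` list: `arm_scores` (cells x arms), `chrom_scores`
#'   (cells x chromosomes), `tumor_call` (logical per cell), `window`,
#'   `gene_order`.
#' @export
infer_cnv_calls <- function(em, reference_cells, window = 101, arm_threshold = 0.1) {
  stopifnot(window %% 2 == 1)
  gm <- em$gene_meta
  if (!all(c("chrom", "arm", "tss") %in% names(gm)))
    stop("gene_meta must provide chrom, arm, tss")
  if (length(reference_cells) == 0) stop("reference cell set is empty")
  norm <- normalized_dense(em)
  ref <- norm[reference_cells, , drop = FALSE]
  rel <- sweep(norm, 2, colMeans(ref))
  rel[rel > 3] <- 3; rel[rel < -3] <- -3

  ord <- order(gm$chrom, gm$tss)
  rel <- rel[, ord, drop = FALSE]
  chrom <- gm$chrom[ord]; arm <- paste0(gm$chrom, gm$arm)[ord]
  min_chrom <- min(table(chrom))
  if (window > min_chrom)
    stop("window (", window, ") exceeds the smallest chromosome's gene count (",
         min_chrom, "); use a smaller window")
  smooth <- rel
  for (ch in unique(chrom)) {
    j <- which(chrom == ch)
    smooth[, j] <- t(apply(rel[, j, drop = FALSE], 1, moving_average,
                           window = window))
  }
  # Median-center each cell's smoothed track: genome-wide compositional
  # shifts between cell populations must not masquerade as CNV, and after
  # smoothing the median sits on the unaltered-chromosome baseline.
  smooth <- smooth - apply(smooth, 1, median)
  arm_scores <- t(rowsum(t(smooth), arm) / as.vector(table(arm)))
  chrom_scores <- t(rowsum(t(smooth), chrom) / as.vector(table(chrom)))
  tumor_call <- chrom_scores[, "chr7"] > arm_threshold &
    chrom_scores[, "chr10"] < -arm_threshold
  structure(list(arm_scores = arm_scores, chrom_scores = chrom_scores,
                 tumor_call = tumor_call, window = window,
                 arm_threshold = arm_threshold, gene_order = ord),
            class = "CnvProfile")
}
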