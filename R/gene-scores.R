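# TSS-proximity gene scores from ATAC fragments: each fragment midpoint
# within ±W of a gene's TSS contributes exp(-|d|/s); per-cell depth
# normalization to 10,000 weighted counts.

#' Distance-weighted gene activity scores from fragments
#'
#' `score(c, g) = sum over fragments of cell c whose midpoint lies within
#' ±W of TSS_g of exp(-|midpoint - TSS|/s)`, then normalized per cell to
#' 10,000 total weighted counts.
#'
#' @param fragments Fragment table (chrom, start, end, barcode, count).
#' @param gene_table data.frame with `symbol`, `chrom`, `tss` (1-based),
#'   `strand`.
#' @param s Exponential decay constant in bp (default 5000).
#' @param W Window half-width in bp (default 100000).
#' @param barcodes Optional barcode universe.
#' @param normalize Per-cell depth normalization (default TRUE).
#' @return A `GeneScoreMatrix`: sparse cells x genes non-negative matrix with
#'   attributes `s`, `W`.
#' @export
compute_gene_scores <- function(fragments, gene_table, s = 5000, W = 100000,
                                barcodes = NULL, normalize = TRUE) {
  miss <- is.na(gene_table$tss)
  if (any(miss)) {
    warning("skipping ", sum(miss), " gene(s) without TSS")
    gene_table <- gene_table[!miss, , drop = FALSE]
  }
  fr <- data.table::as.data.table(fragments)
  if (is.null(barcodes)) barcodes <- sort(unique(fr$barcode))
  fr[, mid := (start + end) %/% 2L]
  gt <- data.table::data.table(symbol = gene_table$symbol,
                               chrom = gene_table$chrom,
                               qs = gene_table$tss - 1L - as.integer(W),
                               qe = gene_table$tss - 1L + as.integer(W),
                               tss0 = gene_table$tss - 1L)
  data.table::setkey(gt, chrom, qs, qe)
  ii <- fr[, .(chrom, qs = mid, qe = mid, barcode, count)]
  ov <- data.table::foverlaps(ii, gt, type = "within", nomatch = NULL)
  scores <- if (nrow(ov) == 0) {
    Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                         dims = c(length(barcodes), nrow(gene_table)),
                         dimnames = list(barcodes, gene_table$symbol))
  } else {
    # foverlaps keeps the query's interval columns as i.qs/i.qe; i.qs is the
    # fragment midpoint
    ov[, w := count * exp(-abs(i.qs - tss0) / s)]
    agg <- ov[barcode %in% barcodes, .(w = sum(w)), by = .(barcode, symbol)]
    Matrix::sparseMatrix(i = match(agg$barcode, barcodes),
                         j = match(agg$symbol, gene_table$symbol),
                         x = agg$w,
                         dims = c(length(barcodes), nrow(gene_table)),
                         dimnames = list(barcodes, gene_table$symbol))
  }
  if (normalize) {
    tot <- Matrix::rowSums(scores)
    tot[tot == 0] <- 1
    scores <- scores / tot * 1e4
  }
  attr(scores, "s") <- s
  attr(scores, "W") <- W
  scores
}
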