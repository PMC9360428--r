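# QC filters for RNA and ATAC cells. RNA thresholds are closed inequalities
# (mito <= 20%, counts and detected genes within closed ranges); ATAC
# thresholds are strict (> min_fragments, > min_tss).

#' QC-filter RNA cells
#'
#' Retains cells whose mitochondrial fraction of detected genes is `<=
#' mito_max`, total counts lie within `count_range` (closed), and detected
#' gene count lies within `gene_range` (closed). The mitochondrial fraction
#' is computed over detected genes (genes with count > 0), not counts.
#'
#' @param em `ExpressionMatrix` with mito flags in `gene_meta$mito`.
#' @param mito_max Maximum mito fraction (default 0.20).
#' @param count_range Closed (low, high) total-count bounds.
#' @param gene_range Closed (low, high) detected-gene bounds.
#' @return Filtered `ExpressionMatrix` with a `qc_report` attribute: per
#'   criterion, cells failing it, plus cells in/out.
#' @export
qc_filter_rna <- function(em, mito_max = 0.20, count_range = c(500, 50000),
                          gene_range = c(500, 10000)) {
  if (is.null(em$gene_meta$mito)) stop("missing mito flags in gene_meta")
  stopifnot(count_range[1] <= count_range[2], gene_range[1] <= gene_range[2])
  counts <- em$counts
  total <- Matrix::rowSums(counts)
  detected_mat <- counts
  detected_mat@x <- rep(1, length(detected_mat@x))
  n_detected <- Matrix::rowSums(detected_mat)
  n_mito_detected <- Matrix::rowSums(detected_mat[, em$gene_meta$mito, drop = FALSE])
  mito_frac <- ifelse(n_detected > 0, n_mito_detected / n_detected, 0)

  fail_mito <- mito_frac > mito_max
  fail_counts <- total < count_range[1] | total > count_range[2]
  fail_genes <- n_detected < gene_range[1] | n_detected > gene_range[2]
  keep <- !(fail_mito | fail_counts | fail_genes)
  if (!any(keep)) warning("no cells pass RNA QC")
  out <- subset_cells(em, cells = keep)
  attr(out, "qc_report") <- list(
    n_in = nrow(counts), n_out = sum(keep),
    failed = list(mito = sum(fail_mito), counts = sum(fail_counts),
                  genes = sum(fail_genes)),
    thresholds = list(mito_max = mito_max, count_range = count_range,
                      gene_range = gene_range))
  out
}

#' Per-cell TSS enrichment score
#'
#' Ratio of mean per-base Tn5 insertion coverage in `±center_halfwidth` of
#' the TSSs to the mean per-base coverage in two `flank_width`-bp windows
#' ending `flank_distance` bp away on either side. Insertions are both
#' fragment ends. The flank mean carries a pseudocount of 0.1 per base so the
#' ratio stays finite; a cell with no insertions anywhere scores 0.
#'
#' @param fragments Fragment table (chrom, start, end, barcode, count;
#'   0-based half-open).
#' @param tss_table data.frame with `chrom` and `tss` (1-based positions).
#' @param center_halfwidth,center Half-width of the TSS-centred window (bp).
#' @param flank_distance Distance from TSS to the outer flank edge (bp).
#' @param flank_width Width of each flank window (bp).
#' @param barcodes Optional barcode universe (cells absent from the
#'   fragments score 0).
#' @return data.frame with `barcode`, `n_fragments` (unique fragment count),
#'   `tss_enrichment`.
#' @export
compute_tss_enrichment <- function(fragments, tss_table, center_halfwidth = 50,
                                   flank_distance = 2000, flank_width = 100,
                                   barcodes = NULL) {
  stopifnot(nrow(tss_table) > 0)
  fr <- data.table::as.data.table(fragments)
  if (is.null(barcodes))
    barcodes <- if (nrow(fr)) sort(unique(fr$barcode)) else character(0)
  if (nrow(fr) == 0) {
    warning("empty fragment file: all TSS metrics zero")
    return(data.frame(barcode = barcodes, n_fragments = 0, tss_enrichment = 0))
  }
  # Insertion sites: both fragment ends (start and end-1, the two cut
  # positions of the half-open interval), weighted by the count column.
  ins <- rbind(fr[, .(chrom, pos = start, barcode, count)],
               fr[, .(chrom, pos = end - 1L, barcode, count)])
  tss <- data.table::as.data.table(tss_table[, c("chrom", "tss")])
  tss0 <- tss$tss - 1L  # 1-based TSS -> 0-based coordinate system

  win <- function(lo_off, hi_off) {
    w <- data.table::data.table(chrom = tss$chrom, qs = tss0 + lo_off,
                                qe = tss0 + hi_off)
    data.table::setkey(w, chrom, qs, qe)
    ii <- ins[, .(chrom, qs = pos, qe = pos, barcode, count)]
    ov <- data.table::foverlaps(ii, w, type = "within", nomatch = NULL)
    ov[, .(n = sum(count)), by = barcode]
  }
  center <- win(-center_halfwidth, center_halfwidth)
  fl_l <- win(-flank_distance, -flank_distance + flank_width - 1L)
  fl_r <- win(flank_distance - flank_width + 1L, flank_distance)

  n_tss <- nrow(tss)
  center_bases <- (2 * center_halfwidth + 1) * n_tss
  flank_bases <- 2 * flank_width * n_tss
  get <- function(tab) {
    v <- setNames(rep(0, length(barcodes)), barcodes)
    hit <- tab$barcode %in% barcodes
    v[tab$barcode[hit]] <- tab$n[hit]
    v
  }
  center_mean <- get(center) / center_bases
  flank_mean <- (get(fl_l) + get(fl_r)) / flank_bases + 0.1
  uniq <- fr[, .(n = .N), by = barcode]
  data.frame(barcode = barcodes,
             n_fragments = as.numeric(get(uniq)),
             tss_enrichment = as.numeric(center_mean / flank_mean),
             row.names = NULL)
}

#' QC-filter ATAC cells
#'
#' Keeps cells with unique fragment count strictly greater than
#' `min_fragments` and TSS enrichment strictly greater than `min_tss`.
#'
#' @param metrics data.frame from [compute_tss_enrichment()].
#' @param min_fragments Fragment threshold (kept if > this).
#' @param min_tss TSS enrichment threshold (kept if > this).
#' @return Character vector of retained barcodes with a `qc_report` attribute.
#' @export
qc_filter_atac <- function(metrics, min_fragments = 1000, min_tss = 4) {
  keep <- metrics$n_fragments > min_fragments & metrics$tss_enrichment > min_tss
  if (!any(keep)) warning("no cells pass ATAC QC")
  out <- metrics$barcode[keep]
  attr(out, "qc_report") <- list(
    n_in = nrow(metrics), n_out = sum(keep),
    failed = list(fragments = sum(metrics$n_fragments <= min_fragments),
                  tss = sum(metrics$tss_enrichment <= min_tss)))
  out
}
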