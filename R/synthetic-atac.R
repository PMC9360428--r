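# Coupled snATAC-seq simulator: per-cell fragment counts in TF-target peaks
# rise with that TF's planted activity; background peaks follow a flat rate.
# One motif per TF, decoy TFs carry motifs and peaks but no activity signal.

#' Simulate snATAC-seq fragments coupled to planted TF activity
#'
#' Builds a peak set (promoter-proximal and distal target peaks per TF, decoy
#' TF peaks, background peaks), a 1:1 peak x motif match table, and a
#' BED-like fragment table. Expected fragment counts in a TF's peaks scale as
#' `exp(atac_gamma * activity)`; every peak carries a synthetic bias
#' covariate for background matching.
#'
#' @param network A `GroundTruthNetwork`.
#' @param config A `SyntheticConfig`.
#' @param cell_truth Truth list from [simulate_expression_counts()] (uses
#'   `cells`, `activity`, `gene_table`).
#' @return List with `fragments` (data.table chrom/start/end/barcode/count,
#'   sorted), `peaks` (chrom, start, end, peak_id, bias), `motif_matches`
#'   (peak_id, motif_id), `tf_motif_map` (tf, motif_id, tf_gene,
#'   differential), `peak_counts` (sparse cells x peaks).
#' @export
simulate_accessibility <- function(network, config, cell_truth) {
  cells <- cell_truth$cells
  activity <- cell_truth$activity
  gene_table <- cell_truth$gene_table
  if (is.null(cells$barcode) || !identical(rownames(activity), cells$barcode))
    stop("validation error: cell_truth barcodes inconsistent with activity matrix")
  set.seed(config$seed + 2L)

  n_decoy <- config$n_decoy_tfs %||% length(network$tfs)
  decoy_tfs <- if (n_decoy > 0) sprintf("DTF%02d", seq_len(n_decoy)) else character(0)
  all_tfs <- c(network$tfs, decoy_tfs)
  missing_gene <- setdiff(all_tfs, gene_table$symbol)
  if (length(missing_gene) > 0)
    stop("validation error: TF genes absent from gene table: ",
         paste(head(missing_gene, 5), collapse = ", "))
  tss_of <- setNames(gene_table$tss, gene_table$symbol)
  chrom_of <- setNames(gene_table$chrom, gene_table$symbol)

  peak_width <- 500L
  peak_list <- list()
  for (tf in all_tfs) {
    # Promoter-proximal peaks within a few kb of the TF's own TSS (drive the
    # TSS-weighted gene score), plus distal target peaks elsewhere.
    offs <- seq_len(config$promoter_peaks_per_tf) * 3000L - 1500L
    prom <- data.frame(chrom = unname(chrom_of[tf]),
                       start = unname(tss_of[tf]) + offs - peak_width %/% 2,
                       tf = tf, kind = "promoter", stringsAsFactors = FALSE)
    dist_chrom <- sample(paste0("chr", 1:10), config$peaks_per_tf, replace = TRUE)
    dist <- data.frame(chrom = dist_chrom,
                       start = sample(5e6:4e7, config$peaks_per_tf),
                       tf = tf, kind = "target", stringsAsFactors = FALSE)
    peak_list[[tf]] <- rbind(prom, dist)
  }
  tf_peaks <- do.call(rbind, peak_list)
  n_bg <- config$n_peaks - nrow(tf_peaks)
  if (n_bg < 0) stop("sizing error: n_peaks too small for TF peak allocation")
  bg <- data.frame(chrom = sample(paste0("chr", 1:10), n_bg, replace = TRUE),
                   start = sample(5e6:4e7, n_bg, replace = TRUE),
                   tf = NA_character_, kind = "background",
                   stringsAsFactors = FALSE)
  peaks <- rbind(tf_peaks, bg)
  peaks$start <- as.integer(peaks$start)
  peaks$end <- peaks$start + peak_width
  peaks$peak_id <- sprintf("PEAK%05d", seq_len(nrow(peaks)))
  peaks$bias <- round(runif(nrow(peaks), 0.3, 0.7), 4)

  motif_of <- setNames(paste0("M_", all_tfs), all_tfs)
  motif_matches <- data.frame(peak_id = peaks$peak_id[!is.na(peaks$tf)],
                              motif_id = motif_of[peaks$tf[!is.na(peaks$tf)]],
                              stringsAsFactors = FALSE)
  rownames(motif_matches) <- NULL

  # Expected per-cell peak weights: baseline lognormal, multiplied by
  # exp(gamma * activity) for the owning TF's peaks (decoys stay flat).
  n_cells <- nrow(cells)
  base_w <- rlnorm(nrow(peaks), 0, 0.25)
  depth <- rlnorm(n_cells, config$atac_depth_meanlog, config$atac_depth_sdlog)
  logw <- matrix(0, n_cells, nrow(peaks))
  owned <- !is.na(peaks$tf) & peaks$tf %in% colnames(activity)
  logw[, owned] <- config$atac_gamma * activity[, peaks$tf[owned], drop = FALSE]
  w <- sweep(exp(logw), 2, base_w, `*`)
  share <- w / rowSums(w)
  lambda <- share * depth
  cnt <- matrix(rpois(length(lambda), as.vector(lambda)), n_cells, nrow(peaks),
                dimnames = list(cells$barcode, peaks$peak_id))
  peak_counts <- Matrix::Matrix(cnt, sparse = TRUE)

  nz <- which(cnt > 0, arr.ind = TRUE)
  frag_pos <- peaks$start[nz[, 2]] +
    as.integer(runif(nrow(nz), 75, peak_width - 75))
  fragments <- data.table::data.table(
    chrom = peaks$chrom[nz[, 2]],
    start = frag_pos - 75L,
    end = frag_pos + 75L,
    barcode = cells$barcode[nz[, 1]],
    count = cnt[nz])
  data.table::setorder(fragments, chrom, start, end, barcode)

  tf_motif_map <- data.frame(
    tf = all_tfs, motif_id = motif_of[all_tfs], tf_gene = all_tfs,
    differential = all_tfs %in% network$tfs, stringsAsFactors = FALSE)
  rownames(tf_motif_map) <- NULL
  list(fragments = fragments, peaks = peaks[, c("chrom", "start", "end",
                                                "peak_id", "bias", "tf", "kind")],
       motif_matches = motif_matches, tf_motif_map = tf_motif_map,
       peak_counts = peak_counts)
}
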