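# chromVAR-style motif accessibility deviations: per cell and motif, the
# relative difference between observed counts in motif-matched peaks and the
# expectation from the population-wide peak usage, bias-corrected against
# size-matched background peak sets drawn from (bias x accessibility) bins
# and z-scored by the background sd.

#' Bias-corrected motif deviation z-scores
#'
#' Expected counts `e_mc = depth_c * f_m` with `f_m` the population fraction
#' of reads in motif-m peaks; raw deviation `y_mc = (obs_mc - e_mc) / e_mc`.
#' `n_background` background peak sets, sampled bin-wise to match each motif
#' peak's bias and mean accessibility, yield the correction (subtract
#' background mean deviation) and the z-score (divide by background sd).
#'
#' @param peak_counts Sparse cells x peaks count matrix.
#' @param motif_matches data.frame with `peak_id`, `motif_id`.
#' @param peak_bias Per-peak bias covariate (e.g. GC content), aligned with
#'   `colnames(peak_counts)`.
#' @param n_background Background sets per motif (default 50).
#' @param n_bins Bins per axis of the (bias, accessibility) grid (default 10).
#' @param seed Seed.
#' @return A `MotifDeviationResult` list: `raw` and `corrected` deviations,
#'   `z` (all motifs x cells), `expected_fraction`, `skipped` motifs.
#' @export
motif_deviation_scores <- function(peak_counts, motif_matches, peak_bias,
                                   n_background = 50, n_bins = 10, seed = 1) {
  m <- peak_counts
  peaks <- colnames(m)
  stopifnot(length(peak_bias) == ncol(m))
  unknown <- setdiff(motif_matches$peak_id, peaks)
  if (length(unknown) > 0)
    stop("motif matches reference unknown peaks: ",
         paste(head(unknown, 5), collapse = ", "))
  depth <- Matrix::rowSums(m)
  total <- sum(depth)
  peak_tot <- Matrix::colSums(m)
  peak_frac <- peak_tot / total
  # Bin peaks on (bias, mean accessibility) for background matching.
  bin_of <- function(v) {
    r <- rank(v, ties.method = "first")
    cut(r, breaks = n_bins, labels = FALSE)
  }
  bins <- paste(bin_of(peak_bias), bin_of(peak_tot))
  bin_members <- split(seq_along(peaks), bins)

  motif_peaks <- split(match(motif_matches$peak_id, peaks), motif_matches$motif_id)
  motifs <- names(motif_peaks)
  set.seed(seed)
  n_cells <- nrow(m)
  raw <- corrected <- z <- matrix(NA_real_, length(motifs), n_cells,
                                  dimnames = list(motifs, rownames(m)))
  exp_frac <- setNames(numeric(length(motifs)), motifs)
  skipped <- character(0)

  dev_for <- function(idx) {
    obs <- Matrix::rowSums(m[, idx, drop = FALSE])
    f <- sum(peak_frac[idx])
    e <- depth * f
    list(y = as.numeric((obs - e) / e), f = f, ok = f > 0)
  }
  for (mo in motifs) {
    idx <- motif_peaks[[mo]]
    d <- dev_for(idx)
    if (!d$ok || sum(peak_tot[idx]) == 0) {
      warning("motif ", mo, " has zero total reads; skipped")
      skipped <- c(skipped, mo)
      next
    }
    exp_frac[mo] <- d$f
    raw[mo, ] <- d$y
    bg <- matrix(NA_real_, n_background, n_cells)
    for (b in seq_len(n_background)) {
      bidx <- vapply(idx, function(p) {
        pool <- bin_members[[bins[p]]]
        pool[sample.int(length(pool), 1)]
      }, integer(1))
      bd <- dev_for(bidx)
      bg[b, ] <- if (bd$ok) bd$y else 0
    }
    mu_bg <- colMeans(bg)
    sd_bg <- apply(bg, 2, sd)
    corrected[mo, ] <- d$y - mu_bg
    z[mo, ] <- ifelse(sd_bg > 0, (d$y - mu_bg) / sd_bg, NA_real_)
  }
  keep <- setdiff(motifs, skipped)
  structure(list(raw = raw[keep, , drop = FALSE],
                 corrected = corrected[keep, , drop = FALSE],
                 z = z[keep, , drop = FALSE],
                 expected_fraction = exp_frac[keep],
                 n_background = n_background, skipped = skipped, seed = seed),
            class = "MotifDeviationResult")
}
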