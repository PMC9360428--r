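# Module scores (set mean minus expression-bin-matched control mean) and the
# label rules built on them: cell typing, meta-modules, the MES-PN axis, and
# cell-cycle phase with per-group enrichment.

#' Per-cell gene-set module score
#'
#' `score(c) = mean(normalized expression of set genes) - mean(control
#' pool)`, where the control pool draws, for each set gene, `n_controls`
#' genes (with replacement) from the same average-expression bin. Genes are
#' binned into `n_bins` by their average normalized expression. A constant
#' expression matrix scores exactly 0; adding a constant to every entry
#' leaves scores unchanged.
#'
#' @param em `ExpressionMatrix` with normalized layer.
#' @param gene_sets Named list of character vectors (or one character vector).
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_controls Control genes sampled per set gene (default 100).
#' @param seed Sampling seed.
#' @return Cells x sets numeric matrix of scores, with control-pool metadata
#'   attributes.
#' @export
module_score <- function(em, gene_sets, n_bins = 25, n_controls = 100, seed = 1) {
  norm <- normalized_dense(em)
  if (is.character(gene_sets)) gene_sets <- list(set = gene_sets)
  if (any(lengths(gene_sets) == 0)) stop("empty gene set")
  genes <- colnames(norm)
  avg <- colMeans(norm)
  n_bins_eff <- min(n_bins, length(unique(avg)))
  bin <- if (n_bins_eff < 2) rep(1L, length(avg)) else
    cut(rank(avg, ties.method = "first"), breaks = n_bins_eff, labels = FALSE)
  names(bin) <- genes
  set.seed(seed)
  scores <- matrix(NA_real_, nrow(norm), length(gene_sets),
                   dimnames = list(rownames(norm), names(gene_sets)))
  for (s in seq_along(gene_sets)) {
    gs <- gene_sets[[s]]
    missing <- setdiff(gs, genes)
    if (length(missing) > 0)
      warning("genes absent from matrix (", names(gene_sets)[s], "): ",
              paste(head(missing, 5), collapse = ", "))
    gs <- intersect(gs, genes)
    if (length(gs) == 0) stop("gene set has no genes in the matrix: ",
                              names(gene_sets)[s])
    ctrl <- unlist(lapply(gs, function(g) {
      pool <- genes[bin == bin[[g]]]
      pool[sample.int(length(pool), n_controls, replace = TRUE)]
    }))
    scores[, s] <- rowMeans(norm[, gs, drop = FALSE]) -
      rowMeans(norm[, ctrl, drop = FALSE])
  }
  attr(scores, "control_meta") <- list(n_bins = n_bins_eff,
                                       n_controls = n_controls, seed = seed)
  scores
}

#' Assign cell types from module scores
#'
#' Label = argmax score when that score exceeds `threshold`, else
#' `"unclassified"`. Exact ties break toward the earlier column with a
#' warning.
#'
#' @param scores Cells x types score matrix.
#' @param threshold Minimum winning score (default 0.05).
#' @return Character vector of labels.
#' @export
assign_cell_type <- function(scores, threshold = 0.05) {
  best <- max.col(scores, ties.method = "first")
  tied <- apply(scores, 1, function(r) sum(r == max(r)) > 1)
  if (any(tied))
    warning(sum(tied), " cell(s) with tied top scores; first set in column order used")
  label <- colnames(scores)[best]
  top <- scores[cbind(seq_len(nrow(scores)), best)]
  label[top <= threshold] <- "unclassified"
  label
}

#' Meta-module classification (MES1/MES2/AC/OPC/NPC1/NPC2)
#'
#' Scores the six meta-module sets and labels each cell by the maximum
#' score; MES1/MES2 collapse to "MES" and NPC1/NPC2 to "NPC"; cells with no
#' score above `threshold` are "unclassified".
#'
#' @param em `ExpressionMatrix` with normalized layer.
#' @param six_module_sets Named list with exactly MES1, MES2, AC, OPC, NPC1,
#'   NPC2.
#' @param threshold Score threshold (default 0.05).
#' @param seed Control-pool seed.
#' @return Character vector of labels in {MES, AC, OPC, NPC, unclassified}.
#' @export
classify_metamodule <- function(em, six_module_sets, threshold = 0.05, seed = 1) {
  need <- c("MES1", "MES2", "AC", "OPC", "NPC1", "NPC2")
  if (!setequal(names(six_module_sets), need))
    stop("six_module_sets must be named exactly: ", paste(need, collapse = ", "))
  scores <- module_score(em, six_module_sets[need], seed = seed)
  lab <- assign_cell_type(scores, threshold)
  lab[lab %in% c("MES1", "MES2")] <- "MES"
  lab[lab %in% c("NPC1", "NPC2")] <- "NPC"
  lab
}

#' MES-PN axis classification from PC1 loadings
#'
#' MES set = genes with the 100 highest loadings, PN = 100 lowest, INT = the
#' remainder; cells labelled by maximum module score over the three sets
#' with the usual threshold.
#'
#' @param em `ExpressionMatrix` with normalized layer.
#' @param pc1_loadings Named numeric vector of PC1 loadings (>= 300 genes,
#'   at least 201 required).
#' @param threshold Score threshold (default 0.05).
#' @param seed Control-pool seed.
#' @return List: `labels` in {MES, PN, INT, unclassified}, `sets`.
#' @export
classify_mes_pn <- function(em, pc1_loadings, threshold = 0.05, seed = 1) {
  if (length(pc1_loadings) < 201)
    stop("need loadings for at least 201 genes (got ", length(pc1_loadings), ")")
  ord <- order(pc1_loadings, decreasing = TRUE)
  genes <- names(pc1_loadings)
  sets <- list(MES = genes[head(ord, 100)],
               PN = genes[utils::tail(ord, 100)],
               INT = genes[ord[101:(length(ord) - 100)]])
  scores <- module_score(em, sets, seed = seed)
  list(labels = assign_cell_type(scores, threshold), sets = sets)
}

#' Cell-cycle phase labels and per-group phase enrichment
#'
#' Phase by larger of the S and G2M module scores; G1 when both are <= 0.
#' Per-group enrichment of each phase by hypergeometric test with BH FDR
#' (significant when FDR < 0.01).
#'
#' @param em `ExpressionMatrix` with normalized layer.
#' @param phase_sets Named list with `S` and `G2M` gene sets.
#' @param groups Group label per cell (e.g. network states); `NULL` skips
#'   enrichment.
#' @param seed Control-pool seed.
#' @return List: `phase` per cell, `enrichment` data.frame (group, phase, k,
#'   n, K, N, p, fdr, significant).
#' @export
cycle_phase_enrichment <- function(em, phase_sets, groups = NULL, seed = 1) {
  stopifnot(all(c("S", "G2M") %in% names(phase_sets)))
  scores <- module_score(em, phase_sets[c("S", "G2M")], seed = seed)
  phase <- ifelse(scores[, "S"] <= 0 & scores[, "G2M"] <= 0, "G1",
                  ifelse(scores[, "S"] >= scores[, "G2M"], "S", "G2M"))
  enr <- NULL
  if (!is.null(groups)) {
    N <- length(phase)
    rows <- list()
    for (g in sort(unique(as.character(groups)))) {
      in_g <- groups == g
      for (ph in c("G1", "S", "G2M")) {
        k <- sum(phase[in_g] == ph); K <- sum(phase == ph); n <- sum(in_g)
        rows[[length(rows) + 1]] <- data.frame(
          group = g, phase = ph, k = k, n = n, K = K, N = N,
          p = hyper_p(k, K, n, N), stringsAsFactors = FALSE)
      }
    }
    enr <- do.call(rbind, rows)
    enr$fdr <- p.adjust(enr$p, "BH")
    enr$significant <- enr$fdr < 0.01
  }
  list(phase = phase, enrichment = enr)
}
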