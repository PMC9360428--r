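# Longitudinal staging: SNN clusters are mapped to stages (PT, IPT, LPT-A,
# LPT-B, REC) via hypergeometric condition enrichment and a rule table;
# regulon trajectories are classified from per-stage one-sided activity
# tests.

#' Assign longitudinal stages to clusters
#'
#' Tests hypergeometric enrichment of each condition within each cluster
#' (BH FDR over all cluster x condition tests). The enriched-condition set
#' then maps to a stage: PDX-tr2 + recurrent-neighbour flag -> REC;
#' PDX-tr1 AND PDX-tr2 -> LPT-A; PDX-tr1 -> IPT; PDX-tr2 -> LPT-B; any of
#' Primary/PDX-1/PDX-2 (and no treated-timepoint enrichment) -> PT;
#' otherwise "unassigned".
#'
#' @param clusters Cluster label per cell.
#' @param conditions Condition label per cell, in {Primary, PDX-1, PDX-2,
#'   PDX-tr1, PDX-tr2, Recurrent}.
#' @param recurrent_neighbor Logical per cluster (named): does a majority of
#'   projected recurrent cells neighbour this cluster? Default all FALSE.
#' @param fdr_max Enrichment FDR cutoff (default 0.1).
#' @return A `StageAssignment` list: `cluster_stage` (named character),
#'   `cell_stage`, `enrichment` (cluster x condition FDR table).
#' @export
assign_stages <- function(clusters, conditions, recurrent_neighbor = NULL,
                          fdr_max = 0.1) {
  conditions <- as.character(conditions)
  bad <- setdiff(unique(conditions), CONDITION_LEVELS)
  if (length(bad) > 0)
    stop("unknown condition label(s): ", paste(bad, collapse = ", "))
  clusters <- as.character(clusters)
  ids <- sort(unique(clusters))
  if (is.null(recurrent_neighbor))
    recurrent_neighbor <- setNames(rep(FALSE, length(ids)), ids)
  N <- length(conditions)
  rows <- list()
  for (cl in ids) for (cond in unique(conditions)) {
    in_cl <- clusters == cl
    k <- sum(conditions[in_cl] == cond)
    rows[[length(rows) + 1]] <- data.frame(
      cluster = cl, condition = cond, k = k, n = sum(in_cl),
      K = sum(conditions == cond), N = N,
      p = hyper_p(k, sum(conditions == cond), sum(in_cl), N),
      stringsAsFactors = FALSE)
  }
  enr <- do.call(rbind, rows)
  enr$fdr <- p.adjust(enr$p, "BH")
  cluster_stage <- setNames(rep("unassigned", length(ids)), ids)
  for (cl in ids) {
    e <- enr$condition[enr$cluster == cl & enr$fdr <= fdr_max]
    tr1 <- "PDX-tr1" %in% e; tr2 <- "PDX-tr2" %in% e
    pre <- any(c("Primary", "PDX-1", "PDX-2") %in% e)
    cluster_stage[cl] <-
      if (tr2 && isTRUE(recurrent_neighbor[[cl]])) "REC"
      else if (tr1 && tr2) "LPT-A"
      else if (tr1) "IPT"
      else if (tr2) "LPT-B"
      else if (pre) "PT"
      else "unassigned"
  }
  if (any(cluster_stage == "unassigned"))
    warning("unassigned cluster(s): ",
            paste(names(cluster_stage)[cluster_stage == "unassigned"],
                  collapse = ", "))
  structure(list(cluster_stage = cluster_stage,
                 cell_stage = unname(cluster_stage[clusters]),
                 enrichment = enr),
            class = "StageAssignment")
}

#' Classify regulon activity trajectories across stages
#'
#' Per regulon and stage, a one-sided Wilcoxon rank-sum test of in-stage vs
#' out-of-stage activity (BH FDR over all regulon x stage tests). Labels:
#' significant-high in PT -> "selected_against"; in REC ->
#' "selected_induced"; in IPT and/or LPT only -> "transient"; none ->
#' "flat". When several rules fire the precedence is selected_against >
#' selected_induced > transient, with a warning.
#'
#' @param activity `ActivityMatrix` (or a regulons x cells matrix).
#' @param stages Stage label per cell (PT, IPT, LPT-A, LPT-B, REC).
#' @param fdr_max FDR cutoff (default 0.01).
#' @param min_stage_cells Stages with fewer cells are skipped with a warning.
#' @return data.frame per regulon: `regulon`, `label`, and one FDR column per
#'   stage.
#' @export
classify_regulon_trajectory <- function(activity, stages, fdr_max = 0.01,
                                        min_stage_cells = 10) {
  act <- if (is.matrix(activity)) activity else activity$activity
  stages <- as.character(stages)
  stopifnot(length(stages) == ncol(act))
  stage_ids <- intersect(STAGE_LEVELS, unique(stages))
  small <- stage_ids[vapply(stage_ids, function(s) sum(stages == s),
                            integer(1)) < min_stage_cells]
  if (length(small) > 0) {
    warning("skipping stage(s) with < ", min_stage_cells, " cells: ",
            paste(small, collapse = ", "))
    stage_ids <- setdiff(stage_ids, small)
  }
  pmat <- matrix(NA_real_, nrow(act), length(stage_ids),
                 dimnames = list(rownames(act), stage_ids))
  for (s in stage_ids) {
    in_s <- stages == s
    for (r in seq_len(nrow(act)))
      pmat[r, s] <- suppressWarnings(
        wilcox.test(act[r, in_s], act[r, !in_s],
                    alternative = "greater", exact = FALSE)$p.value)
  }
  fdr <- matrix(p.adjust(pmat, "BH"), nrow(act),
                dimnames = dimnames(pmat))
  labels <- character(nrow(act))
  for (r in seq_len(nrow(act))) {
    sig <- colnames(fdr)[fdr[r, ] <= fdr_max]
    hi_pt <- "PT" %in% sig
    hi_rec <- "REC" %in% sig
    hi_mid <- any(c("IPT", "LPT-A", "LPT-B") %in% sig)
    fired <- sum(c(hi_pt, hi_rec))
    if (fired > 1)
      warning("regulon ", rownames(act)[r],
              ": multiple trajectory rules fire; precedence applied")
    labels[r] <- if (hi_pt) "selected_against"
      else if (hi_rec) "selected_induced"
      else if (hi_mid) "transient"
      else "flat"
  }
  out <- data.frame(regulon = rownames(act), label = labels,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(fdr))
}
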