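# Program discovery (k-means on regulon-regulon activity correlations) and
# network-state assignment (hierarchical clustering of cells on pairwise
# activity-profile correlations), with k chosen by mean silhouette.

silhouette_for <- function(cl, dmat) {
  if (length(unique(cl)) < 2) return(NA_real_)
  mean(cluster::silhouette(cl, dmatrix = dmat)[, "sil_width"])
}

#' Group regulons into transcriptional programs
#'
#' Computes the regulon x regulon Pearson correlation of activity profiles
#' and k-means-clusters its rows (`nstart = 50`); k is chosen from `k_range`
#' by maximal mean silhouette (on 1 - correlation distance). If silhouettes
#' are uniformly weak (< 0.05) the smallest k is used with a warning.
#'
#' @param activity `ActivityMatrix` (significant regulons only, typically).
#' @param k_range Candidate numbers of programs.
#' @param seed Seed for k-means.
#' @return List: `programs` (regulon -> program id, e.g. "Pr1"), `k`,
#'   `silhouettes` (named by k), `correlation`.
#' @export
detect_programs <- function(activity, k_range = 2:8, seed = 1) {
  act <- activity$activity
  if (nrow(act) < 2) stop("need >= 2 regulons")
  if (max(k_range) > nrow(act) - 1)
    stop("k_range exceeds the number of regulons")
  cc <- cor(t(act))
  dmat <- 1 - cc
  set.seed(seed)
  fits <- lapply(k_range, function(k) kmeans(cc, centers = k, nstart = 50))
  sil <- vapply(seq_along(k_range), function(i)
    silhouette_for(fits[[i]]$cluster, dmat), numeric(1))
  names(sil) <- k_range
  if (all(is.na(sil) | sil < 0.05)) {
    warning("silhouettes uniformly weak; smallest k selected")
    best <- 1L
  } else best <- which.max(sil)
  cl <- fits[[best]]$cluster
  programs <- setNames(sprintf("Pr%d", cl), rownames(act))
  list(programs = programs, k = k_range[best], silhouettes = sil,
       correlation = cc)
}

#' Assign cells to transcriptional network states
#'
#' Cells are clustered on pairwise Pearson correlation of their regulon
#' activity z-score profiles (average-linkage hierarchical clustering on
#' 1 - correlation), cut to the k in `k_range` with maximal mean silhouette.
#'
#' @param activity `ActivityMatrix`.
#' @param k_range Candidate state counts.
#' @param programs Optional regulon -> program map for the per-state program
#'   activity summary.
#' @param seed Unused (the procedure is deterministic) but kept for interface
#'   symmetry.
#' @return List: `states` (cell -> "SG<k>"), `k`, `silhouettes`,
#'   `state_program_activity` (states x programs mean activity, when
#'   `programs` given).
#' @export
assign_network_states <- function(activity, k_range = 2:8, programs = NULL,
                                  seed = 1) {
  zs <- activity$zscores
  n_cells <- ncol(zs)
  if (n_cells < max(k_range)) stop("fewer cells than max k")
  cc <- cor(zs)                      # cells x cells
  dmat <- 1 - cc
  hc <- hclust(stats::as.dist(dmat), method = "average")
  sil <- vapply(k_range, function(k)
    silhouette_for(cutree(hc, k = k), dmat), numeric(1))
  names(sil) <- k_range
  best <- if (all(is.na(sil))) 1L else which.max(sil)
  cl <- cutree(hc, k = k_range[best])
  states <- setNames(sprintf("SG%d", cl), colnames(zs))
  spa <- NULL
  if (!is.null(programs)) {
    pr_act <- rowsum(activity$activity, programs[rownames(activity$activity)])
    pr_act <- pr_act / as.vector(table(programs[rownames(activity$activity)]))
    spa <- t(rowsum(t(pr_act), states) / as.vector(table(states)))
  }
  list(states = states, k = k_range[best], silhouettes = sil,
       state_program_activity = spa)
}
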