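# PCA -> kNN -> shared-nearest-neighbour graph (Jaccard edge weights) ->
# Leiden community detection.

#' SNN graph clustering
#'
#' PCA of the normalized layer to `n_pcs`, kNN graph, SNN edge weights as
#' the Jaccard index of neighbour sets, then Leiden modularity clustering at
#' the given resolution.
#'
#' @param em `ExpressionMatrix` with normalized layer, or a numeric cells x
#'   features matrix to use directly (PCA still applied unless
#'   `n_pcs = NULL`).
#' @param n_pcs PCs to keep; `NULL` uses the matrix as-is.
#' @param k_neighbors kNN size (default 20).
#' @param resolution Leiden resolution (default 0.8).
#' @param seed Seed for the community search.
#' @return Integer cluster labels named by barcode.
#' @export
snn_cluster <- function(em, n_pcs = 30, k_neighbors = 20, resolution = 0.8,
                        seed = 1) {
  x <- if (is.matrix(em)) em else normalized_dense(em)
  if (nrow(x) < k_neighbors + 1) stop("need >= k_neighbors + 1 cells")
  if (!is.null(n_pcs)) {
    if (n_pcs >= min(dim(x))) stop("n_pcs must be < min(dim)")
    x <- prcomp(x, center = TRUE, scale. = FALSE, rank. = n_pcs)$x
  }
  d <- as.matrix(dist(x))
  diag(d) <- Inf
  nn <- t(apply(d, 1, function(r) order(r)[seq_len(k_neighbors)]))
  n <- nrow(x)
  # SNN: Jaccard of neighbour sets for each kNN edge.
  edges <- list(); weights <- numeric(0)
  nn_sets <- lapply(seq_len(n), function(i) c(i, nn[i, ]))
  for (i in seq_len(n)) for (j in nn[i, ]) if (j > i) {
    shared <- length(intersect(nn_sets[[i]], nn_sets[[j]]))
    jac <- shared / (2 * (k_neighbors + 1) - shared)
    if (jac > 1 / 15) {
      edges[[length(edges) + 1]] <- c(i, j)
      weights <- c(weights, jac)
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (length(edges) > 0) {
    g <- igraph::add_edges(g, as.vector(t(do.call(rbind, edges))))
    igraph::E(g)$weight <- weights
  }
  set.seed(seed)
  cl <- igraph::cluster_leiden(g, objective_function = "modularity",
                               resolution = resolution, n_iterations = 5)
  setNames(as.integer(igraph::membership(cl)), rownames(x))
}
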