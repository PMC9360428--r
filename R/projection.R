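# Reference-landscape projection: store gene means/variances, top-PC
# eigenvectors, reference PC scores and a linear PC -> embedding map; project
# query cells through the same transform and report nearest reference
# neighbours in embedding space.

#' Fit a reference projection model
#'
#' Standardizes the reference with per-gene means and variances, computes
#' the top `n_pcs` eigenvectors and PC scores, and fits a least-squares
#' linear map from PC scores to the supplied 2-D embedding coordinates.
#'
#' @param em_ref Reference `ExpressionMatrix` with normalized layer.
#' @param n_pcs Number of PCs (default 30).
#' @param embedding_coords Cells x 2 coordinates for all reference cells
#'   (e.g. a UMAP); defaults to the first two PC scores.
#' @return A `ReferenceProjectionModel` list: `mean`, `var`, `eigenvectors`
#'   (genes x n_pcs, orthonormal), `ref_scores`, `embedding`, `coef`
#'   (PC -> embedding linear map with intercept), `genes`.
#' @export
fit_reference_projection <- function(em_ref, n_pcs = 30,
                                     embedding_coords = NULL) {
  x <- normalized_dense(em_ref)
  v <- apply(x, 2, var)
  keep <- v > 0
  if (any(!keep))
    warning("excluding ", sum(!keep), " zero-variance gene(s)")
  x <- x[, keep, drop = FALSE]
  m_g <- colMeans(x); v_g <- apply(x, 2, var)
  xs <- sweep(sweep(x, 2, m_g), 2, sqrt(v_g), "/")
  n_pcs <- min(n_pcs, dim(xs) - 1)
  pc <- prcomp(xs, center = FALSE, scale. = FALSE, rank. = n_pcs)
  scores <- pc$x
  if (is.null(embedding_coords)) embedding_coords <- scores[, 1:2]
  stopifnot(nrow(embedding_coords) == nrow(x), ncol(embedding_coords) == 2)
  fit <- lm(embedding_coords ~ scores)
  structure(list(mean = m_g, var = v_g, eigenvectors = pc$rotation,
                 ref_scores = scores, embedding = embedding_coords,
                 coef = coef(fit), genes = colnames(x)),
            class = "ReferenceProjectionModel")
}

#' Project query cells onto a reference landscape
#'
#' Standardizes the query with the reference gene means/variances (missing
#' genes imputed at the reference mean, i.e. standardized 0), multiplies by
#' the stored eigenvectors, maps PC scores to the embedding with the stored
#' linear map, and reports each query cell's nearest reference neighbour by
#' Euclidean embedding distance.
#'
#' @param model A `ReferenceProjectionModel`.
#' @param em_query Query `ExpressionMatrix` with normalized layer.
#' @param max_missing_frac Error when more than this fraction of model genes
#'   is absent from the query (default 0.5).
#' @return List: `scores` (query PC scores), `embedding` (query cells x 2),
#'   `nearest_reference` (index), `nearest_distance`.
#' @export
project_cells <- function(model, em_query, max_missing_frac = 0.5) {
  xq <- normalized_dense(em_query)
  missing <- setdiff(model$genes, colnames(xq))
  if (length(missing) / length(model$genes) > max_missing_frac)
    stop("query lacks ", length(missing), " of ", length(model$genes),
         " model genes (> ", max_missing_frac * 100, "%)")
  if (length(missing) > 0)
    message(length(missing), " model gene(s) absent from query; imputed at reference mean")
  xs <- matrix(0, nrow(xq), length(model$genes),
               dimnames = list(rownames(xq), model$genes))
  present <- intersect(model$genes, colnames(xq))
  xs[, present] <- sweep(sweep(xq[, present, drop = FALSE], 2,
                               model$mean[present]),
                         2, sqrt(model$var[present]), "/")
  scores <- xs %*% model$eigenvectors
  emb <- cbind(1, scores) %*% model$coef
  d2 <- outer(rowSums(emb^2), rowSums(model$embedding^2), "+") -
    2 * emb %*% t(model$embedding)
  nn <- max.col(-d2, ties.method = "first")
  list(scores = scores, embedding = emb, nearest_reference = nn,
       nearest_distance = sqrt(pmax(d2[cbind(seq_len(nrow(emb)), nn)], 0)))
}
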