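# Iterative TF-IDF latent semantic indexing for peak-count matrices: term
# frequency = depth-normalized counts, IDF = log(1 + n_cells / (1 + df)),
# truncated SVD on the most accessible peaks, then on the most variable peaks
# across round-1 clusters.

#' Iterative LSI embedding of a peak-count matrix
#'
#' @param peak_counts Cells x peaks non-negative matrix (sparse or dense).
#' @param d Number of components (>= 2).
#' @param n_iterations 1 = plain LSI on the most accessible peaks; 2 adds a
#'   second round on the most cluster-variable peaks.
#' @param top_features Number of peaks used per round.
#' @param n_clusters k-means clusters used to pick variable peaks in round 2.
#' @param seed Seed for k-means.
#' @return An `LsiEmbedding` list: `scores` (cells x d), `singular_values`,
#'   `idf`, `features` (peak indices used in the final round), `iterations`.
#' @export
tfidf_lsi <- function(peak_counts, d = 30, n_iterations = 2,
                      top_features = NULL, n_clusters = 6, seed = 1) {
  m <- Matrix::Matrix(peak_counts, sparse = TRUE)
  n_cells <- nrow(m); n_peaks <- ncol(m)
  if (d > min(n_cells, n_peaks)) stop("d must be <= min(n_cells, n_peaks)")
  top_features <- min(top_features %||% n_peaks, n_peaks)
  set.seed(seed)

  run_lsi <- function(feat_idx) {
    sub <- m[, feat_idx, drop = FALSE]
    depth <- Matrix::rowSums(m)
    depth[depth == 0] <- 1
    tf <- sub / depth
    df <- Matrix::colSums(sub > 0)
    idf <- log(1 + n_cells / (1 + df))
    x <- as.matrix(tf) %*% diag(idf, length(idf))
    sv <- svd(x, nu = d, nv = 0)
    scores <- sv$u %*% diag(sv$d[seq_len(d)], d)
    rownames(scores) <- rownames(m)
    list(scores = scores, singular_values = sv$d[seq_len(d)], idf = idf)
  }

  feat1 <- order(Matrix::colSums(m), decreasing = TRUE)[seq_len(top_features)]
  it1 <- run_lsi(feat1)
  iterations <- list(list(features = feat1))
  res <- it1; feats <- feat1
  if (n_iterations >= 2) {
    cl <- kmeans(it1$scores, centers = min(n_clusters, n_cells - 1),
                 nstart = 10)$cluster
    # Cluster-mean log accessibility; variance across clusters ranks peaks.
    depth <- Matrix::rowSums(m); depth[depth == 0] <- 1
    tf_full <- as.matrix(m / depth)
    cl_means <- rowsum(tf_full, cl) / as.vector(table(cl))
    vscore <- apply(cl_means, 2, var)
    feats <- order(vscore, decreasing = TRUE)[seq_len(top_features)]
    res <- run_lsi(feats)
    iterations <- c(iterations, list(list(features = feats, clusters = cl)))
  }
  structure(list(scores = res$scores, singular_values = res$singular_values,
                 idf = res$idf, features = feats, iterations = iterations),
            class = "LsiEmbedding")
}
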