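# Wang graph-based semantic similarity on a GO-style DAG with best-match
# average aggregation for term sets.

# S-values of term A: S_A(A) = 1; for an ancestor t, S_A(t) = max over edges
# (child -> t) of w_edge * S_A(child), computed over A's ancestor closure.
wang_svalues <- function(term, dag, weights) {
  parents_of <- split(seq_len(nrow(dag)), dag$child)
  sv <- setNames(1, term)
  frontier <- term
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (ch in frontier) {
      for (e in parents_of[[ch]] %||% integer(0)) {
        pa <- dag$parent[e]
        w <- weights[[dag$relation[e]]]
        if (is.null(w)) stop("unknown relation: ", dag$relation[e])
        cand <- w * sv[[ch]]
        if (is.na(sv[pa]) || cand > sv[[pa]]) {
          sv[pa] <- cand
          nxt <- c(nxt, pa)
        }
      }
    }
    frontier <- unique(nxt)
  }
  sv
}

# Pairwise Wang similarity of two terms.
wang_term_sim <- function(a, b, dag, weights) {
  sa <- wang_svalues(a, dag, weights)
  sb <- wang_svalues(b, dag, weights)
  common <- intersect(names(sa), names(sb))
  if (length(common) == 0) return(0)
  sum(sa[common] + sb[common]) / (sum(sa) + sum(sb))
}

#' Wang semantic similarity between term sets (best-match average)
#'
#' Computes the Wang graph-based similarity for every pair of terms across
#' the two sets and aggregates with the best-match average: the mean of the
#' row maxima and column maxima of the pairwise matrix.
#'
#' @param dag data.frame with `child`, `parent`, `relation` columns
#'   (acyclic).
#' @param terms_a,terms_b Character vectors of term ids present in the DAG.
#' @param w_is_a,w_part_of Edge weights (defaults 0.8, 0.6).
#' @return List: `similarity` (BMA scalar), `pairwise` (|A| x |B| matrix).
#' @export
wang_semantic_similarity <- function(dag, terms_a, terms_b,
                                     w_is_a = 0.8, w_part_of = 0.6) {
  g <- igraph::graph_from_data_frame(dag[, c("child", "parent")])
  if (!igraph::is_dag(g)) stop("cyclic DAG")
  known <- unique(c(dag$child, dag$parent))
  unknown <- setdiff(c(terms_a, terms_b), known)
  if (length(unknown) > 0)
    stop("term(s) not in DAG: ", paste(unknown, collapse = ", "))
  weights <- list(is_a = w_is_a, part_of = w_part_of)
  pw <- matrix(NA_real_, length(terms_a), length(terms_b),
               dimnames = list(terms_a, terms_b))
  for (i in seq_along(terms_a)) for (j in seq_along(terms_b))
    pw[i, j] <- wang_term_sim(terms_a[i], terms_b[j], dag, weights)
  bma <- (mean(apply(pw, 1, max)) + mean(apply(pw, 2, max))) / 2
  list(similarity = bma, pairwise = pw)
}
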