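# Shared fixtures, built in code. The small bundle is generated once per test
# run and memoised; tests treat it as read-only.

.fixture_env <- new.env(parent = emptyenv())

# Scaled-down coupled fixture bundle: 10 TFs, 3 programs, 3 states, 500 cells.
small_bundle <- function() {
  if (is.null(.fixture_env$small)) {
    cfg <- synthetic_config(n_cells = 500, n_genes = 800, n_peaks = 800,
                            n_mito_genes = 5, seed = 42)
    .fixture_env$small <- simulate_fixture_bundle(
      cfg, n_tfs = 10, n_programs = 3, n_states = 3,
      condition_design = default_condition_design(3))
  }
  .fixture_env$small
}

small_bundle_norm <- function() {
  if (is.null(.fixture_env$small_norm))
    .fixture_env$small_norm <- lognormalize(small_bundle()$rna)
  .fixture_env$small_norm
}

# Dense toy ExpressionMatrix with Poisson counts, log-normalized.
make_toy_em <- function(n_cells = 20, n_genes = 50, lambda = 5, seed = 1,
                        normalize = TRUE) {
  set.seed(seed)
  cnt <- matrix(rpois(n_cells * n_genes, lambda), n_cells, n_genes,
                dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                                sprintf("g%03d", seq_len(n_genes))))
  cnt[cbind(seq_len(n_cells), 1)] <- cnt[cbind(seq_len(n_cells), 1)] + 1  # no zero-depth
  em <- expression_matrix(cnt)
  if (normalize) em <- lognormalize(em)
  em
}

# Two-cell-state toy with planted marker blocks (for clustering tests).
make_two_state_em <- function(n_cells = 100, n_genes = 300, seed = 1,
                              strength = 6) {
  set.seed(seed)
  st <- rep(c(1L, 2L), length.out = n_cells)
  mu <- t(vapply(st, function(s) {
    m <- rep(1, n_genes)
    if (s == 1) m[1:30] <- strength else m[31:60] <- strength
    m
  }, numeric(n_genes)))
  cnt <- matrix(rpois(n_cells * n_genes, as.vector(mu)), n_cells, n_genes,
                dimnames = list(sprintf("c%03d", seq_len(n_cells)),
                                sprintf("g%03d", seq_len(n_genes))))
  cnt[, 1] <- cnt[, 1] + 1
  list(em = lognormalize(expression_matrix(cnt)), states = st)
}

# Exhaustive Wilcoxon rank-sum p-value by enumeration (two-sided), no ties.
wilcox_enum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  r_obs <- sum(rank(pooled)[seq_len(n)])
  combs <- combn(length(pooled), n)
  stats <- apply(combs, 2, function(idx) sum(rank(pooled)[idx]))
  mu <- n * (length(pooled) + 1) / 2
  mean(abs(stats - mu) >= abs(r_obs - mu) - 1e-12)
}

# Exact hypergeometric upper-tail P(X >= k) by direct summation.
hyper_enum_p <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}
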