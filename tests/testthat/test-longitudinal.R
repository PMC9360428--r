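test_that("integration aligns a globally shifted duplicate batch", {
  ts <- make_two_state_em(n_cells = 120, n_genes = 600, seed = 1)
  em_a <- ts$em
  em_b <- em_a
  set.seed(1)
  gene_shift <- rnorm(ncol(em_a$counts))
  em_b$normalized <- em_a$normalized +
    matrix(gene_shift, nrow(em_a$counts), ncol(em_a$counts), byrow = TRUE)
  out <- integrate_batches(list(em_a, em_b), n_pcs = 10)
  x <- as.matrix(out$normalized)
  a_rows <- out$cell_meta$batch == 1
  expect_lt(max(abs(x[a_rows, ] - x[!a_rows, ])), 1e-6)
  expect_error(integrate_batches(list(em_a)), ">= 2 batches")
  expect_error(integrate_batches(list(em_a, subset_cells(em_b, genes = 1:100))),
               "share only")
})

test_that("integration increases batch mixing of shared planted states", {
  net <- build_ground_truth_network(6, c(8, 12), n_programs = 3, n_states = 3,
                                    seed = 2)
  cfg <- synthetic_config(n_cells = 300, n_genes = 600, doublet_rate = 0,
                          cnv_gain = 1, cnv_loss = 1, batch_effect_sd = 0.6,
                          seed = 3)
  sim <- simulate_expression_counts(net, cfg, default_condition_design(3))
  em <- lognormalize(sim$em)
  batch <- sim$truth$cells$batch
  em_list <- list(subset_cells(em, batch == "patient"),
                  subset_cells(em, batch == "pdx"))
  out <- integrate_batches(em_list, n_pcs = 10)
  corrected <- prcomp(as.matrix(out$normalized), rank. = 10)$x
  raw <- prcomp(as.matrix(em$normalized), rank. = 10)$x
  ent_cor <- batch_mixing_entropy(corrected, out$cell_meta$batch)
  ent_raw <- batch_mixing_entropy(raw, batch)
  expect_gt(ent_cor, ent_raw)
})

test_that("SNN clustering separates planted states and is deterministic", {
  ts <- make_two_state_em(n_cells = 120, seed = 4)
  cl <- snn_cluster(ts$em, n_pcs = 10, seed = 1)
  expect_equal(adjusted_rand_index(cl, ts$states), 1)
  cl2 <- snn_cluster(ts$em, n_pcs = 10, seed = 1)
  expect_identical(cl, cl2)

  # duplicated cell clusters with its twin
  norm <- as.matrix(ts$em$counts)
  norm <- rbind(norm, dup = norm[1, ])
  rownames(norm)[nrow(norm)] <- "dup"
  em2 <- lognormalize(expression_matrix(norm))
  cl3 <- snn_cluster(em2, n_pcs = 10, seed = 1)
  expect_equal(unname(cl3["dup"]), unname(cl3[1]))
  expect_error(snn_cluster(ts$em, n_pcs = 400), "n_pcs")
})

test_that("Wilcoxon DEG p-values equal exhaustive enumeration for tiny groups", {
  set.seed(5)
  norm <- cbind(gX = c(1.3, 2.1, 0.7, 3.5, 4.2, 5.1, 4.8, 6.0),
                gY = rnorm(8))
  rownames(norm) <- sprintf("c%d", 1:8)
  em <- expression_matrix(matrix(1, 8, 2, dimnames = dimnames(norm)))
  em$normalized <- Matrix::Matrix(norm, sparse = FALSE)
  deg <- differential_expression(em, sprintf("c%d", 1:4), sprintf("c%d", 5:8),
                                 all_genes = TRUE)
  for (g in c("gX", "gY")) {
    p_enum <- wilcox_enum_p(norm[1:4, g], norm[5:8, g])
    expect_equal(deg$p[deg$gene == g], p_enum, tolerance = 1e-12)
  }
  expect_error(differential_expression(em, sprintf("c%d", 1:4),
                                       sprintf("c%d", 4:8)), "overlap")
})

test_that("DEG detects a planted fold change and stays quiet under the null", {
  set.seed(6)
  n <- 200
  cnt <- matrix(rpois(2 * n * 100, 10), 2 * n, 100,
                dimnames = list(sprintf("c%03d", seq_len(2 * n)),
                                sprintf("g%03d", 1:100)))
  cnt[seq_len(n), "g001"] <- rpois(n, 20)         # 2-fold up in group A
  em <- lognormalize(expression_matrix(cnt))
  a <- rownames(cnt)[seq_len(n)]; b <- rownames(cnt)[n + seq_len(n)]
  deg <- differential_expression(em, a, b, all_genes = TRUE)
  expect_lt(deg$fdr[deg$gene == "g001"], 0.01)
  filtered <- differential_expression(em, a, b)
  expect_true("g001" %in% filtered$gene)

  # identical distributions: nothing survives the filters
  cnt0 <- matrix(rpois(2 * n * 100, 10), 2 * n, 100, dimnames = dimnames(cnt))
  em0 <- lognormalize(expression_matrix(cnt0))
  deg0 <- differential_expression(em0, a, b)
  expect_lte(nrow(deg0), 2)
})

test_that("stage assignment maps enriched condition sets through the rule table", {
  set.seed(7)
  n <- 1000
  conditions <- sample(c("Primary", "PDX-1", "PDX-2", "PDX-tr1", "PDX-tr2"),
                       n, replace = TRUE, prob = c(0.2, 0.2, 0.2, 0.2, 0.2))
  clusters <- rep("rest", n)
  clusters[which(conditions == "PDX-tr1")[1:100]] <- "pure_tr1"  # 100% PDX-tr1
  clusters[sample(which(clusters == "rest"), 300)] <- "mix"      # uniform draw
  sa <- suppressWarnings(assign_stages(clusters, conditions))
  expect_equal(unname(sa$cluster_stage["pure_tr1"]), "IPT")
  expect_equal(unname(sa$cluster_stage["mix"]), "unassigned")

  # enrichment for both treated timepoints maps to LPT-A
  cl2 <- rep("bulk", n)
  trt <- which(conditions %in% c("PDX-tr1", "PDX-tr2"))
  cl2[trt[1:150]] <- "both_tr"
  sa2 <- suppressWarnings(assign_stages(cl2, conditions))
  expect_equal(unname(sa2$cluster_stage["both_tr"]), "LPT-A")

  # the same cluster with the recurrent-neighbour flag becomes REC
  sa3 <- suppressWarnings(assign_stages(cl2, conditions,
                                        recurrent_neighbor = c(both_tr = TRUE,
                                                               bulk = FALSE)))
  expect_equal(unname(sa3$cluster_stage["both_tr"]), "REC")
  expect_error(assign_stages(clusters, rep("Weird", n)), "unknown condition")
})

test_that("trajectory classification follows the stage decision table", {
  set.seed(8)
  n <- 400
  stages <- sample(c("PT", "IPT", "LPT-A", "LPT-B", "REC"), n, replace = TRUE)
  act <- matrix(rnorm(4 * n), 4, n,
                dimnames = list(c("Ra", "Rb", "Rc", "Rd"), sprintf("c%03d", 1:n)))
  act["Ra", stages == "IPT"] <- act["Ra", stages == "IPT"] + 2     # transient
  act["Rb", stages == "REC"] <- act["Rb", stages == "REC"] + 2     # induced
  act["Rc", stages == "PT"] <- act["Rc", stages == "PT"] + 2       # selected against
  tr <- classify_regulon_trajectory(act, stages)
  expect_equal(tr$label[tr$regulon == "Ra"], "transient")
  expect_equal(tr$label[tr$regulon == "Rb"], "selected_induced")
  expect_equal(tr$label[tr$regulon == "Rc"], "selected_against")
  expect_equal(tr$label[tr$regulon == "Rd"], "flat")

  # constant activity is flat; tiny stages are skipped with a warning
  const <- matrix(1 + rnorm(n, sd = 1e-6), 1, n,
                  dimnames = list("Rk", colnames(act)))
  expect_equal(classify_regulon_trajectory(const, stages)$label, "flat")
  stages2 <- c(rep("PT", n - 5), rep("REC", 5))
  expect_warning(classify_regulon_trajectory(act, stages2), "skipping stage")
})

test_that("cosine similarity has unit diagonal, symmetry, and detects sharing", {
  ts_a <- make_two_state_em(n_cells = 60, seed = 9)
  ts_b <- make_two_state_em(n_cells = 60, seed = 10)
  genes <- colnames(ts_a$em$counts)[1:120]
  res <- cosine_state_similarity(ts_a$em, ts_b$em, genes, k_clusters = 2)
  expect_equal(res$similarity, t(res$similarity))
  expect_true(all(abs(diag(res$similarity) - 1) < 1e-12))
  # same generator states in both sets: clusters mix sources and the
  # cross-vs-within test is significant
  expect_true(any(res$cluster_tests$fdr < 0.05, na.rm = TRUE))
  mixed <- vapply(sort(unique(res$clusters)), function(k)
    length(unique(res$source[res$clusters == k])) == 2, logical(1))
  expect_true(all(mixed))

  # orthogonal cells: similarity 0
  cnt <- rbind(a = c(5, 0, 1), b = c(0, 5, 1))
  colnames(cnt) <- c("g1", "g2", "g3")
  em <- lognormalize(expression_matrix(cnt))
  r2 <- cosine_state_similarity(em, em, c("g1", "g2"), k_clusters = 2)
  expect_equal(unname(r2$similarity[1, 2]), 0)
})

test_that("reference projection is self-consistent and recovers linear embeddings", {
  ts <- make_two_state_em(n_cells = 80, n_genes = 300, seed = 11)
  mod <- fit_reference_projection(ts$em, n_pcs = 20)
  # reference pushed through its own model reproduces its PC scores
  proj <- project_cells(mod, ts$em)
  expect_lt(max(abs(proj$scores - mod$ref_scores)), 1e-8)
  # default embedding is the first two PCs; the linear map must be exact
  expect_lt(max(abs(proj$embedding - mod$ref_scores[, 1:2])), 1e-8)
  expect_equal(proj$nearest_reference, seq_len(80))
  expect_lt(max(proj$nearest_distance), 1e-6)

  # permuted gene order changes nothing
  ord <- sample(ncol(ts$em$counts))
  em_perm <- subset_cells(ts$em, genes = ord)
  proj_perm <- project_cells(mod, em_perm)
  expect_lt(max(abs(proj_perm$scores - proj$scores)), 1e-8)

  # an all-reference-mean query lands at the origin of PC space
  norm <- as.matrix(ts$em$normalized)
  flat <- matrix(rep(colMeans(norm), each = 3), 3, ncol(norm),
                 dimnames = list(c("q1", "q2", "q3"), colnames(norm)))
  emq <- expression_matrix(matrix(1, 3, ncol(norm), dimnames = dimnames(flat)))
  emq$normalized <- Matrix::Matrix(flat, sparse = FALSE)
  pq <- project_cells(mod, emq)
  expect_lt(max(abs(pq$scores)), 1e-8)

  # missing more than half the model genes is an error
  emq_small <- subset_cells(ts$em, genes = seq_len(100))
  expect_error(project_cells(mod, emq_small), "lacks")
})

test_that("projected recurrent-like cells land near their planted state", {
  b <- small_bundle()
  em <- small_bundle_norm()
  cells <- b$truth$cells
  nd <- !cells$doublet & cells$tumor
  ref_idx <- which(nd & cells$condition != "Recurrent")
  q_idx <- which(nd & cells$condition == "Recurrent")
  mod <- fit_reference_projection(subset_cells(em, ref_idx), n_pcs = 20)
  pj <- project_cells(mod, subset_cells(em, q_idx))
  agree <- mean(cells$state[ref_idx][pj$nearest_reference] ==
                  cells$state[q_idx])
  expect_gte(agree, 0.8)
})

test_that("phenotype profiles compare by Jaccard with exact hypergeometric p", {
  universe <- sprintf("g%02d", 1:20)
  gmt <- list(S1 = universe[1:5], S2 = universe[6:10], S3 = universe[11:15])
  groups <- list(A = universe[c(1:4, 20)], B = universe[c(1:4, 19)],
                 C = universe[11:15])
  res <- phenotype_state_profile(groups, gmt, universe, top_n = 3)
  expect_equal(res$jaccard["A", "B"], 1)       # identical enriched profiles
  expect_equal(res$jaccard["A", "C"], 0)       # disjoint
  # exact enumeration for the (A, S1) cell: 4 of 5 set genes among 5 drawn
  p_exp <- hyper_enum_p(4, 5, 5, 20)
  raw_p <- phyper(4 - 1, 5, 15, 5, lower.tail = FALSE)
  expect_equal(raw_p, p_exp, tolerance = 1e-12)
  expect_true(res$profiles["S1", "A"])
  expect_error(phenotype_state_profile(groups, list(), universe), "empty GMT")
})

test_that("Wang similarity reproduces hand-computed S-values and sanity orders", {
  dag <- data.frame(child = c("a", "b"), parent = c("root", "a"),
                    relation = "is_a")
  w <- wang_semantic_similarity(dag, "a", "b")
  expect_equal(w$similarity, 3.24 / 4.24, tolerance = 1e-12)
  expect_equal(wang_semantic_similarity(dag, "b", "b")$similarity, 1)

  # siblings sharing a parent are more similar than terms sharing only root
  dag2 <- data.frame(child = c("p1", "p2", "s1", "s2", "x"),
                     parent = c("root", "root", "p1", "p1", "p2"),
                     relation = "is_a")
  sib <- wang_semantic_similarity(dag2, "s1", "s2")$similarity
  far <- wang_semantic_similarity(dag2, "s1", "x")$similarity
  expect_gt(sib, far)

  cyc <- data.frame(child = c("a", "b"), parent = c("b", "a"), relation = "is_a")
  expect_error(wang_semantic_similarity(cyc, "a", "b"), "cyclic")
  expect_error(wang_semantic_similarity(dag, "a", "zz"), "zz")
})

test_that("drug matching joins cancer-phase rows against regulon members", {
  tab <- data.frame(drug = c("palbociclib", "metformin", "earlydrug"),
                    target = c("CDK4", "CDK4", "CDK4"),
                    indication_class = c("cancer", "metabolic", "cancer"),
                    max_trial_phase = c("III", "IV", "0"))
  regs <- list(list(id = "R1", tf = "IKZF2", genes = c("CDK4", "OTHER")))
  hits <- match_drug_targets(regs, tab,
                             trajectory = c(R1 = "selected_induced"))
  expect_equal(hits$drug, "palbociclib")
  expect_equal(hits$trajectory, "selected_induced")
  none <- match_drug_targets(list(list(id = "R2", tf = "TFX", genes = "GX")), tab)
  expect_equal(nrow(none), 0)
  expect_error(match_drug_targets(regs, tab[, 1:2]), "malformed")
})
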