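test_that("eigengene activity matches an independent SVD oracle", {
  em <- make_toy_em(40, 120, seed = 1)
  norm <- as.matrix(em$normalized)
  set.seed(2)
  regs <- lapply(1:100, function(i) {
    g <- sample(colnames(norm), sample(5:12, 1))
    list(id = sprintf("R%03d", i), tf = "tf", genes = g)
  })
  names(regs) <- vapply(regs, `[[`, character(1), "id")
  act <- regulon_activity(em, regs)
  for (i in seq_along(regs)) {
    z <- t(scale(norm[, regs[[i]]$genes]))       # independent standardization
    sv <- svd(z)                                 # full SVD oracle
    scores <- sv$d[1] * sv$v[, 1]
    if (sum(scores * colMeans(z)) < 0) scores <- -scores
    expect_lt(max(abs(act$activity[i, ] - scores)), 1e-8)
    expect_lt(abs(act$lambda1[i] - sv$d[1]^2 / sum(sv$d^2)), 1e-8)
  }
})

test_that("perfectly correlated and anti-correlated pairs are rank-1", {
  x <- rnorm(30)
  norm <- cbind(g1 = x, g2 = 2 * x + 5, g3 = -x)
  rownames(norm) <- sprintf("c%02d", 1:30)
  em <- expression_matrix(matrix(1, 30, 3, dimnames = dimnames(norm)))
  em$normalized <- Matrix::Matrix(norm, sparse = FALSE)
  act <- regulon_activity(em, list(R1 = list(id = "R1", tf = "t", genes = c("g1", "g2"))))
  expect_equal(unname(act$lambda1), 1)
  zs <- as.numeric(scale(x))
  expect_gt(abs(cor(act$activity[1, ], zs)), 1 - 1e-10)
  expect_gt(cor(act$activity[1, ], zs), 0)       # orientation: positive

  # anti-correlated pair: lambda1 = 1 and the orientation rule breaks the
  # sign symmetry deterministically
  a1 <- regulon_activity(em, list(R1 = list(id = "R1", tf = "t", genes = c("g1", "g3"))))
  a2 <- regulon_activity(em, list(R1 = list(id = "R1", tf = "t", genes = c("g1", "g3"))))
  expect_equal(unname(a1$lambda1), 1)
  expect_identical(a1$activity, a2$activity)
})

test_that("zero-variance member genes are dropped with a warning", {
  norm <- cbind(g1 = rnorm(20), g2 = rnorm(20), g3 = rep(2, 20))
  rownames(norm) <- sprintf("c%02d", 1:20)
  em <- expression_matrix(matrix(1, 20, 3, dimnames = dimnames(norm)))
  em$normalized <- Matrix::Matrix(norm, sparse = FALSE)
  expect_warning(act <- regulon_activity(em, list(R1 = list(id = "R1", tf = "t",
                                                            genes = c("g1", "g2", "g3")))),
                 "zero-variance")
  expect_false(any(is.na(act$activity)))
  flat <- list(R1 = list(id = "R1", tf = "t", genes = "g3"))
  expect_error(suppressWarnings(regulon_activity(em, flat)), "zero variance")
})

test_that("regulon inference recovers a planted cluster exactly from its prior", {
  b <- small_bundle()
  em <- small_bundle_norm()
  tum <- b$truth$cells$tumor & !b$truth$cells$doublet
  emt <- subset_cells(em, tum)
  net <- b$truth$network
  # prior restricted to one TF covering its planted regulon exactly
  reg1 <- net$regulons[[1]]
  prior <- data.frame(tf = reg1$tf, target = reg1$genes)
  regs <- infer_regulons(emt, prior)
  expect_gte(length(regs), 1)
  jac <- max(vapply(regs, function(r)
    length(intersect(r$genes, reg1$genes)) /
      length(union(r$genes, reg1$genes)), numeric(1)))
  expect_equal(jac, 1)
  expect_error(infer_regulons(emt, prior[0, ]), "empty")
})

test_that("no-signal data emits regulons in at most 5% of candidate tests", {
  net <- build_ground_truth_network(8, c(8, 12), n_programs = 2, n_states = 2,
                                    seed = 3)
  cfg <- synthetic_config(n_cells = 150, n_genes = 600, effect_beta = 0,
                          doublet_rate = 0, cnv_gain = 1, cnv_loss = 1, seed = 4)
  sim <- simulate_expression_counts(net, cfg, default_condition_design(2))
  em <- lognormalize(sim$em)
  prior <- do.call(rbind, lapply(names(net$regulons), function(rid)
    data.frame(tf = net$regulons[[rid]]$tf, target = net$regulons[[rid]]$genes)))
  regs <- suppressWarnings(infer_regulons(em, prior))
  expect_lte(length(regs) / attr(regs, "n_tests"), 0.05)
})

test_that("permutation significance flags planted regulons deterministically", {
  b <- small_bundle()
  em <- small_bundle_norm()
  tum <- b$truth$cells$tumor & !b$truth$cells$doublet
  emt <- subset_cells(em, tum)
  net <- b$truth$network
  regs <- lapply(names(net$regulons), function(rid)
    list(id = rid, tf = net$regulons[[rid]]$tf, genes = net$regulons[[rid]]$genes))
  names(regs) <- names(net$regulons)
  act <- regulon_activity(emt, regs)
  sig <- permutation_significance(emt, regs, act, n_perm = 200, seed = 6)
  expect_true(all(sig$significant))
  sig2 <- permutation_significance(emt, regs, act, n_perm = 200, seed = 6)
  expect_identical(sig$null_lambda1, sig2$null_lambda1)
  expect_warning(permutation_significance(emt, regs[1], act = NULL,
                                          n_perm = 50, seed = 1), "unstable")
})

test_that("program detection recovers correlation blocks and planted programs", {
  # two blocks of correlated activity, independent across blocks
  set.seed(8)
  base1 <- rnorm(200); base2 <- rnorm(200)
  act_mat <- rbind(
    t(replicate(4, base1 + rnorm(200, sd = 0.3))),
    t(replicate(4, base2 + rnorm(200, sd = 0.3))))
  rownames(act_mat) <- sprintf("R%02d", 1:8)
  fake <- list(activity = act_mat, zscores = act_mat, lambda1 = rep(0.5, 8))
  pr <- detect_programs(fake, k_range = 2:4, seed = 1)
  expect_equal(pr$k, 2)
  expect_equal(adjusted_rand_index(pr$programs, rep(1:2, each = 4)), 1)

  # mutually uncorrelated regulons: weak silhouettes, smallest k, warning
  act0 <- matrix(rnorm(8 * 2000), 8, 2000,
                 dimnames = list(sprintf("R%02d", 1:8), NULL))
  fake0 <- list(activity = act0, zscores = act0, lambda1 = rep(0.2, 8))
  expect_warning(pr0 <- detect_programs(fake0, k_range = 2:4, seed = 1),
                 "weak")
  expect_equal(pr0$k, 2)
  expect_error(detect_programs(fake, k_range = 2:20), "exceeds")
})

test_that("network states recover planted structure; duplicates co-cluster", {
  b <- small_bundle()
  em <- small_bundle_norm()
  tum <- which(b$truth$cells$tumor & !b$truth$cells$doublet)
  emt <- subset_cells(em, tum)
  net <- b$truth$network
  regs <- lapply(names(net$regulons), function(rid)
    list(id = rid, tf = net$regulons[[rid]]$tf, genes = net$regulons[[rid]]$genes))
  names(regs) <- names(net$regulons)
  act <- regulon_activity(emt, regs)
  st <- assign_network_states(act, k_range = 2:6)
  expect_gte(adjusted_rand_index(st$states, b$truth$cells$state[tum]), 0.8)

  # duplicated cell lands in the same state as its twin
  act_dup <- act
  act_dup$activity <- cbind(act$activity, dup = act$activity[, 1])
  act_dup$zscores <- cbind(act$zscores, dup = act$zscores[, 1])
  colnames(act_dup$activity)[ncol(act_dup$activity)] <- "dup"
  colnames(act_dup$zscores)[ncol(act_dup$zscores)] <- "dup"
  st2 <- assign_network_states(act_dup, k_range = 2:6)
  expect_equal(unname(st2$states["dup"]), unname(st2$states[1]))

  small <- act
  small$zscores <- act$zscores[, 1:4]
  expect_error(assign_network_states(small, k_range = 2:6), "fewer cells")
})

test_that("beta = 0 states are unrecoverable (ARI near zero)", {
  net <- build_ground_truth_network(6, c(8, 12), n_programs = 3, n_states = 3,
                                    seed = 9)
  cfg <- synthetic_config(n_cells = 200, n_genes = 600, effect_beta = 0,
                          doublet_rate = 0, cnv_gain = 1, cnv_loss = 1, seed = 5)
  sim <- simulate_expression_counts(net, cfg, default_condition_design(3))
  em <- lognormalize(sim$em)
  tum <- which(sim$truth$cells$tumor)
  emt <- subset_cells(em, tum)
  regs <- lapply(names(net$regulons), function(rid)
    list(id = rid, tf = net$regulons[[rid]]$tf, genes = net$regulons[[rid]]$genes))
  names(regs) <- names(net$regulons)
  act <- regulon_activity(emt, regs)
  st <- suppressWarnings(assign_network_states(act, k_range = 2:6))
  expect_lt(abs(adjusted_rand_index(st$states, sim$truth$cells$state[tum])), 0.05)
})

test_that("GSVA running-sum ES matches hand arithmetic on a toy ranking", {
  # 6 genes; cell ranks g1 > g2 > ... > g6; set = {g1, g4}.
  # Positional weights |N/2 - i + 1/2| = (2.5, 1.5, 0.5, 0.5, 1.5, 2.5);
  # hit weights at positions 1 and 4: 2.5/3 and 0.5/3; miss = 1/4.
  # Running sum: after g1 +2.5/3; before g4 2.5/3 - 2/4; after g4 2.5/3+0.5/3-2/4
  # = 1 - 0.5 = 0.5; max deviation = 2.5/3 = 0.8333...
  norm <- matrix(c(6, 5, 4, 3, 2, 1), 1, 6,
                 dimnames = list("cell", sprintf("g%d", 1:6)))
  em <- expression_matrix(norm + 1)
  em$normalized <- Matrix::Matrix(norm, sparse = FALSE)
  res <- gsva_enrichment(em, list(s = c("g1", "g4")), n_perm = 50, seed = 1)
  expect_equal(unname(res$es["cell", "s"]), 2.5 / 3)
})

test_that("a gene set occupying the top ranks maximizes ES among its size class", {
  em <- make_toy_em(5, 40, seed = 10)
  norm <- as.matrix(em$normalized)
  top_sets <- lapply(seq_len(nrow(norm)), function(c_i)
    colnames(norm)[order(norm[c_i, ], decreasing = TRUE)[1:5]])
  # ES of the top-5 set per cell vs 30 random sets of size 5
  set.seed(3)
  rand_sets <- lapply(1:30, function(i) sample(colnames(norm), 5))
  for (c_i in 1:5) {
    sets <- c(list(top = top_sets[[c_i]]), setNames(rand_sets, paste0("r", 1:30)))
    res <- gsva_enrichment(subset_cells(em, c_i), sets, n_perm = 10, seed = 1)
    expect_equal(which.max(res$es[1, ]), c(top = 1))
  }
  expect_warning(gsva_enrichment(em, list(bad = c("nope"), ok = colnames(norm)[1:4]),
                                 n_perm = 10, seed = 1), "skipping")
})
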