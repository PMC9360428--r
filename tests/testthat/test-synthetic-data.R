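test_that("ground-truth network has the requested shape and invariants", {
  net <- build_ground_truth_network(10, c(8, 15), n_programs = 5,
                                    n_states = 5, seed = 1)
  expect_length(net$regulons, 10)
  expect_setequal(unique(net$regulon_program), sprintf("Pr%d", 1:5))
  expect_true(all(lengths(lapply(net$regulons, `[[`, "genes")) >= 5))
  genes <- unlist(lapply(net$regulons, `[[`, "genes"))
  expect_false(anyDuplicated(genes) > 0)            # gene-disjoint regulons
  expect_false(anyDuplicated(as.data.frame(net$state_activity)) > 0)
  expect_true(all(net$state_activity >= -2 & net$state_activity <= 2.1))
  expect_true(all(net$trajectory %in% c("selected_against", "selected_induced",
                                        "transient", "flat")))
})

test_that("infeasible network sizes raise sizing errors", {
  expect_error(build_ground_truth_network(2, n_programs = 5), "sizing")
  expect_error(build_ground_truth_network(5, n_programs = 1), "sizing")
  expect_error(build_ground_truth_network(5, c(3, 4), n_programs = 2), "sizing")
})

test_that("network construction is deterministic given the seed", {
  a <- build_ground_truth_network(8, seed = 99)
  b <- build_ground_truth_network(8, seed = 99)
  expect_identical(a, b)
  c <- build_ground_truth_network(8, seed = 100)
  expect_false(identical(a$trajectory, c$trajectory) &&
                 identical(a$state_activity, c$state_activity))
})

test_that("expression counts carry the planted activity signal, increasing in beta", {
  net <- build_ground_truth_network(6, c(8, 12), n_programs = 3, n_states = 3,
                                    seed = 5)
  cors <- vapply(c(0, 0.5, 1), function(beta) {
    cfg <- synthetic_config(n_cells = 300, n_genes = 600, effect_beta = beta,
                            doublet_rate = 0, seed = 11)
    sim <- simulate_expression_counts(net, cfg, default_condition_design(3))
    em <- lognormalize(sim$em)
    norm <- as.matrix(em$normalized)
    mean(vapply(names(net$regulons), function(rid) {
      reg <- net$regulons[[rid]]
      cor(sim$truth$activity[, reg$tf], rowMeans(norm[, reg$genes]))
    }, numeric(1)))
  }, numeric(1))
  expect_lt(abs(cors[1]), 0.1)          # beta = 0: no signal
  expect_gt(cors[2], 0.3)
  expect_gt(cors[3], cors[2])           # monotone in beta
})

test_that("condition design shifts planted state proportions as configured", {
  net <- build_ground_truth_network(6, c(8, 12), n_programs = 3, n_states = 3,
                                    seed = 5)
  cd <- default_condition_design(3)
  cd[["Primary"]]$state_props <- c(0, 0.5, 0.5)       # state 1 absent pre
  cd[["Recurrent"]]$state_props <- c(0.6, 0.2, 0.2)   # state 1 dominant at REC
  cfg <- synthetic_config(n_cells = 600, n_genes = 600, doublet_rate = 0,
                          seed = 3)
  sim <- simulate_expression_counts(net, cfg, cd)
  cells <- sim$truth$cells
  tum <- cells[cells$tumor, ]
  p_pri <- mean(tum$state[tum$condition == "Primary"] == "SG1")
  p_rec <- mean(tum$state[tum$condition == "Recurrent"] == "SG1")
  expect_equal(p_pri, 0)
  expect_gt(p_rec, 0.4)
})

test_that("bad condition designs are rejected", {
  net <- build_ground_truth_network(4, n_programs = 2, n_states = 2, seed = 1)
  cd <- default_condition_design(2)
  cd[["Primary"]]$state_props <- c(0.5, 0.6)
  cfg <- synthetic_config(n_cells = 100, n_genes = 500, seed = 1)
  expect_error(simulate_expression_counts(net, cfg, cd), "sum to 1")
})

test_that("the written fixture bundle is byte-identical under a fixed seed", {
  cfg <- synthetic_config(n_cells = 120, n_genes = 500, n_peaks = 400,
                          seed = 21)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_fixture_bundle(simulate_fixture_bundle(cfg, n_tfs = 6, n_programs = 2,
                                               n_states = 2,
                                               condition_design = default_condition_design(2)), d1)
  write_fixture_bundle(simulate_fixture_bundle(cfg, n_tfs = 6, n_programs = 2,
                                               n_states = 2,
                                               condition_design = default_condition_design(2)), d2)
  for (f in c("rna/matrix.mtx", "fragments.tsv", "peaks.tsv", "truth_cells.tsv"))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
})

test_that("CNV injection is the identity at neutral factors and plants shifts otherwise", {
  b <- small_bundle()
  net <- b$truth$network
  cfg0 <- synthetic_config(n_cells = 200, n_genes = 600, cnv_gain = 1,
                           cnv_loss = 1, doublet_rate = 0, seed = 13)
  sim <- simulate_expression_counts(net, cfg0, default_condition_design(3))
  out <- inject_cnv_and_doublets(sim$em, sim$truth, cfg0)
  expect_equal(as.matrix(out$em$counts), as.matrix(sim$em$counts))

  cfg1 <- synthetic_config(n_cells = 500, n_genes = 600, cnv_gain = 1.5,
                           cnv_loss = 0.5, doublet_rate = 0, seed = 13)
  sim1 <- simulate_expression_counts(net, cfg1, default_condition_design(3))
  out1 <- inject_cnv_and_doublets(sim1$em, sim1$truth, cfg1)
  cnt <- as.matrix(out1$em$counts)
  tum <- out1$truth$cells$tumor
  j7 <- out1$em$gene_meta$chrom == "chr7"
  j10 <- out1$em$gene_meta$chrom == "chr10"
  p7 <- wilcox.test(rowMeans(cnt[tum, j7]), rowMeans(cnt[!tum, j7]),
                    alternative = "greater")$p.value
  p10 <- wilcox.test(rowMeans(cnt[tum, j10]), rowMeans(cnt[!tum, j10]),
                     alternative = "less")$p.value
  expect_lt(p7, 0.01)
  expect_lt(p10, 0.01)
})

test_that("doublet injection flags exactly rate x n cells, summed across states", {
  net <- build_ground_truth_network(4, n_programs = 2, n_states = 2, seed = 2)
  cfg <- synthetic_config(n_cells = 200, n_genes = 500, doublet_rate = 0.1,
                          cnv_gain = 1, cnv_loss = 1, seed = 8)
  sim <- simulate_expression_counts(net, cfg, default_condition_design(2))
  out <- inject_cnv_and_doublets(sim$em, sim$truth, cfg)
  expect_equal(sum(out$truth$cells$doublet), 20)
  # flagged cells gained counts (sum of two cells)
  d <- which(out$truth$cells$doublet)
  expect_true(all(Matrix::rowSums(out$em$counts[d, ]) >
                    Matrix::rowSums(sim$em$counts[d, ])))
})

test_that("accessibility simulation validates barcodes and is seed-deterministic", {
  b <- small_bundle()
  bad <- b$truth
  bad$activity <- bad$activity[-1, , drop = FALSE]
  expect_error(simulate_accessibility(b$truth$network, b$truth$config, bad),
               "barcodes")
  a1 <- simulate_accessibility(b$truth$network, b$truth$config, b$truth)
  a2 <- simulate_accessibility(b$truth$network, b$truth$config, b$truth)
  expect_identical(a1$fragments, a2$fragments)
})

test_that("the adjusted Rand index agrees with an independent implementation", {
  set.seed(12)
  for (i in 1:10) {
    a <- sample(1:4, 60, replace = TRUE)
    b <- sample(1:3, 60, replace = TRUE)
    expect_equal(adjusted_rand_index(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-12)
  }
  expect_equal(adjusted_rand_index(1:10, 1:10), 1)
})

test_that("fixture bundle cross-references resolve", {
  b <- small_bundle()
  reg_genes <- unlist(lapply(b$truth$network$regulons, `[[`, "genes"))
  expect_true(all(reg_genes %in% b$annotations$gene_table$symbol))
  expect_true(all(b$atac$motif_matches$peak_id %in% b$atac$peaks$peak_id))
  expect_true(all(b$annotations$tf_targets$target %in%
                    b$annotations$gene_table$symbol))
})
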