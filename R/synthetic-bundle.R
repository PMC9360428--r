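# Full fixture bundle: coupled RNA + ATAC simulations plus the annotation
# side-cars (TF-target prior, GMT collections, GO-style DAG subset,
# drug-target table) and planted truth.

#' Simulate a complete multi-omic fixture bundle
#'
#' Runs the planted-network, RNA, CNV/doublet, and ATAC simulators and
#' assembles annotations: a TF -> target prior (exact planted membership plus
#' random targets for decoy TFs), GMT gene sets (regulon sets plus random
#' background sets), a small GO-style DAG, and a drug-target table covering a
#' subset of TFs and member genes.
#'
#' @param config A `SyntheticConfig`.
#' @param n_tfs,n_programs,n_states Planted hierarchy sizes.
#' @param genes_per_regulon_range Member-gene count range per regulon.
#' @param condition_design As from [default_condition_design()].
#' @return A `FixtureBundle` list: `rna` (ExpressionMatrix), `atac`
#'   (accessibility list), `annotations` (gene_table, tf_targets, gmt, go_dag,
#'   drug_targets), `truth`.
#' @export
simulate_fixture_bundle <- function(config = synthetic_config(),
                                    n_tfs = 30L,
                                    n_programs = 5L, n_states = 5L,
                                    genes_per_regulon_range = c(8L, 15L),
                                    condition_design = default_condition_design(n_states)) {
  network <- build_ground_truth_network(n_tfs, genes_per_regulon_range,
                                        n_programs, n_states,
                                        seed = config$seed)
  sim <- simulate_expression_counts(network, config, condition_design)
  sim <- inject_cnv_and_doublets(sim$em, sim$truth, config)
  atac <- simulate_accessibility(network, config, sim$truth)

  set.seed(config$seed + 3L)
  gene_table <- sim$truth$gene_table
  # TF-target prior: exact planted membership; decoys get random background
  # targets so the prior contains negatives.
  prior <- do.call(rbind, lapply(names(network$regulons), function(rid) {
    reg <- network$regulons[[rid]]
    data.frame(tf = reg$tf, target = reg$genes, stringsAsFactors = FALSE)
  }))
  decoys <- atac$tf_motif_map$tf[!atac$tf_motif_map$differential]
  bg_genes <- gene_table$symbol[startsWith(gene_table$symbol, "BG")]
  if (length(decoys) > 0) {
    decoy_prior <- do.call(rbind, lapply(decoys, function(tf)
      data.frame(tf = tf, target = sample(bg_genes, 10), stringsAsFactors = FALSE)))
    prior <- rbind(prior, decoy_prior)
  }

  gmt <- lapply(network$regulons, `[[`, "genes")
  names(gmt) <- paste0("REGULON_", names(network$regulons))
  for (i in 1:10)
    gmt[[sprintf("RANDOM_SET_%02d", i)]] <- sample(gene_table$symbol, 25)

  go_dag <- toy_go_dag()
  drug_targets <- toy_drug_table(network, gene_table)

  list(rna = sim$em, atac = atac,
       annotations = list(gene_table = gene_table, tf_targets = prior,
                          gmt = gmt, go_dag = go_dag,
                          drug_targets = drug_targets),
       truth = sim$truth)
}

# Small acyclic GO-style term DAG (child, parent, relation).
toy_go_dag <- function() {
  edges <- rbind(
    c("GO:BP1", "GO:ROOT", "is_a"), c("GO:BP2", "GO:ROOT", "is_a"),
    c("GO:CYCLE", "GO:BP1", "is_a"), c("GO:DIV", "GO:CYCLE", "is_a"),
    c("GO:MITOSIS", "GO:DIV", "is_a"), c("GO:HYPOXIA", "GO:BP2", "is_a"),
    c("GO:ANGIO", "GO:BP2", "is_a"), c("GO:VEGF", "GO:ANGIO", "is_a"),
    c("GO:IMMUNE", "GO:BP1", "is_a"), c("GO:CYTOKINE", "GO:IMMUNE", "is_a"),
    c("GO:SPINDLE", "GO:MITOSIS", "part_of"), c("GO:EMT", "GO:BP2", "is_a"))
  data.frame(child = edges[, 1], parent = edges[, 2], relation = edges[, 3],
             stringsAsFactors = FALSE)
}

# Drug-target rows covering a subset of TFs/member genes; includes non-cancer
# and early-phase rows so the trial filter has work to do.
toy_drug_table <- function(network, gene_table) {
  tf_targets <- network$tfs[seq_len(min(8, length(network$tfs)))]
  member_targets <- unlist(lapply(network$regulons[1:4], function(r) r$genes[1]),
                           use.names = FALSE)
  targets <- c(tf_targets, member_targets)
  n <- length(targets)
  data.frame(
    drug = sprintf("drug%02d", seq_len(n + 2)),
    target = c(targets, "BG0001", targets[1]),
    indication_class = c(rep("cancer", n), "metabolic", "cancer"),
    max_trial_phase = c(rep(c("II", "III", "IV", "I"), length.out = n), "III", "0"),
    stringsAsFactors = FALSE)
}

#' Write a fixture bundle to disk in standard formats
#'
#' MTX triplet for RNA counts, fragments TSV, peaks/motif/gene/prior/drug
#' TSVs, GMT, DAG TSV, and truth tables.
#'
#' @param bundle From [simulate_fixture_bundle()].
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_counts_bundle(bundle$rna, file.path(dir, "rna"))
  write_fragments(bundle$atac$fragments, file.path(dir, "fragments.tsv"))
  write_peaks(bundle$atac$peaks, file.path(dir, "peaks.tsv"))
  tsv <- function(x, f) write.table(x, file.path(dir, f), sep = "\t",
                                    quote = FALSE, row.names = FALSE)
  tsv(bundle$atac$motif_matches, "motif_matches.tsv")
  tsv(bundle$atac$tf_motif_map, "tf_motif_map.tsv")
  tsv(bundle$annotations$gene_table, "gene_table.tsv")
  tsv(bundle$annotations$tf_targets, "tf_targets.tsv")
  tsv(bundle$annotations$go_dag, "go_dag.tsv")
  tsv(bundle$annotations$drug_targets, "drug_targets.tsv")
  tsv(bundle$truth$cells, "truth_cells.tsv")
  write_gmt(bundle$annotations$gmt, file.path(dir, "gene_sets.gmt"))
  invisible(dir)
}
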