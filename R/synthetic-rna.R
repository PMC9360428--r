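# Coupled snRNA-seq simulator: negative-binomial counts whose gene-level
# means respond multiplicatively to planted TF activity, with log-normal
# library sizes, chr7-gain/chr10-loss CNV signatures and summed-profile
# doublets.

STAGE_LEVELS <- c("PT", "IPT", "LPT-A", "LPT-B", "REC")
CONDITION_LEVELS <- c("Primary", "PDX-1", "PDX-2", "PDX-tr1", "PDX-tr2", "Recurrent")

#' Synthetic data generator configuration
#'
#' Holds every tunable of the coupled RNA/ATAC simulator. Defaults define the
#' package's reference study conditions: 2000 cells across six longitudinal
#' conditions, 63.7% tumour cells, negative-binomial counts with dispersion
#' 0.3, effect size beta = 1 (a unit of TF activity doubles member-gene
#' expression), chr7 gain 1.5 / chr10 loss 0.5, 5% doublets.
#'
#' @param n_cells Total cells across all conditions.
#' @param n_genes Total genes (background + planted; must exceed the planted
#'   gene count).
#' @param n_peaks Total ATAC peaks.
#' @param lib_size_meanlog,lib_size_sdlog Log-normal RNA library-size model.
#' @param dispersion NB dispersion (size = 1/dispersion).
#' @param effect_beta Fold-change per unit TF activity is (1 + effect_beta).
#' @param cnv_gain chr7 multiplier for tumour cells (>= 1).
#' @param cnv_loss chr10 multiplier for tumour cells (<= 1).
#' @param doublet_rate Fraction of cells replaced by doublets, in \[0, 0.2\].
#' @param tumor_fraction Fraction of cells that are tumour cells.
#' @param activity_noise_sd Per-cell, per-TF activity noise (sd).
#' @param trajectory_boost Activity added in the stages named by a regulon's
#'   trajectory pattern.
#' @param batch_effect_sd sd of the per-batch multiplicative log-gene factor
#'   (0 disables batch effects).
#' @param n_mito_genes Number of `MT-` genes carried for QC exercises.
#' @param atac_depth_meanlog,atac_depth_sdlog Log-normal ATAC fragment-depth model.
#' @param atac_gamma Accessibility log-fold per unit TF activity.
#' @param peaks_per_tf Distal target peaks per TF.
#' @param promoter_peaks_per_tf Activity-coupled peaks near each TF's own TSS.
#' @param n_decoy_tfs Decoy TFs with motifs/peaks/prior entries but flat
#'   activity; `NULL` means one per planted TF.
#' @param seed Integer seed governing all generator randomness.
#' @return A `SyntheticConfig` list.
#' @export
synthetic_config <- function(n_cells = 2000L, n_genes = 2000L, n_peaks = 2000L,
                             lib_size_meanlog = log(4000), lib_size_sdlog = 0.3,
                             dispersion = 0.3, effect_beta = 1,
                             cnv_gain = 1.5, cnv_loss = 0.5,
                             doublet_rate = 0.05, tumor_fraction = 0.637,
                             activity_noise_sd = 0.3, trajectory_boost = 0.75,
                             batch_effect_sd = 0, n_mito_genes = 10L,
                             atac_depth_meanlog = log(2000), atac_depth_sdlog = 0.3,
                             atac_gamma = 1.0, peaks_per_tf = 12L,
                             promoter_peaks_per_tf = 4L, n_decoy_tfs = NULL,
                             seed = 7L) {
  cfg <- list(n_cells = as.integer(n_cells), n_genes = as.integer(n_genes),
              n_peaks = as.integer(n_peaks),
              lib_size_meanlog = lib_size_meanlog, lib_size_sdlog = lib_size_sdlog,
              dispersion = dispersion, effect_beta = effect_beta,
              cnv_gain = cnv_gain, cnv_loss = cnv_loss,
              doublet_rate = doublet_rate, tumor_fraction = tumor_fraction,
              activity_noise_sd = activity_noise_sd,
              trajectory_boost = trajectory_boost,
              batch_effect_sd = batch_effect_sd,
              n_mito_genes = as.integer(n_mito_genes),
              atac_depth_meanlog = atac_depth_meanlog,
              atac_depth_sdlog = atac_depth_sdlog,
              atac_gamma = atac_gamma, peaks_per_tf = as.integer(peaks_per_tf),
              promoter_peaks_per_tf = as.integer(promoter_peaks_per_tf),
              n_decoy_tfs = n_decoy_tfs, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_cells > 0, n_genes > 0, n_peaks > 0, dispersion > 0,
              effect_beta >= 0, cnv_gain >= 1, cnv_loss <= 1, cnv_loss > 0,
              doublet_rate >= 0, doublet_rate <= 0.2,
              tumor_fraction > 0, tumor_fraction <= 1)
  })
  structure(cfg, class = "SyntheticConfig")
}

#' Default longitudinal condition design
#'
#' Maps each of the six study conditions to its cell share, its distribution
#' over longitudinal stages, and its network-state proportions (uniform by
#' default; shift them to emulate timepoint-selected states).
#'
#' @param n_states Number of planted network states.
#' @return Named list (one element per condition) with `frac`, `stage_probs`,
#'   `state_props`.
#' @export
default_condition_design <- function(n_states = 5L) {
  uni <- rep(1 / n_states, n_states)
  stage0 <- setNames(numeric(5), STAGE_LEVELS)
  sp <- function(...) { s <- stage0; v <- c(...); s[names(v)] <- v; s }
  list(
    "Primary"   = list(frac = 0.25,  stage_probs = sp(PT = 1), state_props = uni),
    "PDX-1"     = list(frac = 0.125, stage_probs = sp(PT = 1), state_props = uni),
    "PDX-2"     = list(frac = 0.125, stage_probs = sp(PT = 1), state_props = uni),
    "PDX-tr1"   = list(frac = 0.175, stage_probs = sp(IPT = 0.5, `LPT-A` = 0.5),
                       state_props = uni),
    "PDX-tr2"   = list(frac = 0.175, stage_probs = sp(`LPT-A` = 0.3, `LPT-B` = 0.5,
                                                      REC = 0.2),
                       state_props = uni),
    "Recurrent" = list(frac = 0.15,  stage_probs = sp(REC = 1), state_props = uni))
}

# Stages a trajectory pattern boosts.
boost_stages_for <- function(label) {
  switch(label,
         selected_against = "PT",
         selected_induced = "REC",
         transient = c("IPT", "LPT-A", "LPT-B"),
         flat = character(0))
}

# Gene universe: planted regulon genes + TF genes + decoy TF genes + MT genes
# + background, laid out on 10 chromosomes with arms and TSS positions.
build_gene_table <- function(network, config) {
  planted <- network_genes(network)
  n_decoy <- config$n_decoy_tfs %||% length(network$tfs)
  decoy_tfs <- if (n_decoy > 0) sprintf("DTF%02d", seq_len(n_decoy)) else character(0)
  mito <- if (config$n_mito_genes > 0)
    sprintf("MT-G%02d", seq_len(config$n_mito_genes)) else character(0)
  n_named <- length(planted) + length(network$tfs) + length(decoy_tfs) + length(mito)
  if (config$n_genes < n_named + 100)
    stop("sizing error: n_genes (", config$n_genes,
         ") too small for planted network (needs > ", n_named + 100, ")")
  bg <- sprintf("BG%04d", seq_len(config$n_genes - n_named))
  symbols <- c(planted, network$tfs, decoy_tfs, mito, bg)
  # Deterministic shuffle so planted genes are spread across the genome.
  ord <- sample(length(symbols))
  symbols <- symbols[ord]
  chroms <- paste0("chr", 1:10)
  chrom <- chroms[(seq_along(symbols) - 1) %% 10 + 1]
  idx_on_chrom <- stats::ave(seq_along(symbols), chrom, FUN = seq_along)
  tss <- 100000L + (idx_on_chrom - 1L) * 20000L
  n_on_chrom <- stats::ave(seq_along(symbols), chrom, FUN = length)
  arm <- ifelse(idx_on_chrom <= n_on_chrom / 2, "p", "q")
  data.frame(symbol = symbols, chrom = chrom, arm = arm, tss = tss,
             strand = ifelse(seq_along(symbols) %% 2 == 0, "+", "-"),
             stringsAsFactors = FALSE)
}

#' Simulate snRNA-seq counts from a planted network
#'
#' Counts are `NB(mu = depth_c * share_gc, size = 1/dispersion)` where a
#' gene's per-cell expression share responds multiplicatively to its TF's
#' planted activity: `share_gc` is proportional to
#' `base_g * (1 + beta)^(a_tc * m_gt)`. TF activity combines the cell's
#' network-state program activity, the regulon's trajectory boost in the
#' cell's longitudinal stage, and Gaussian noise. Non-tumour cells carry zero
#' activity for every TF.
#'
#' @param network A `GroundTruthNetwork`.
#' @param config A `SyntheticConfig`.
#' @param condition_design As from [default_condition_design()]; per-condition
#'   `state_props` must sum to 1.
#' @return List with `em` (an `ExpressionMatrix`, counts only) and `truth`
#'   (list: `cells` data.frame with barcode/condition/batch/stage/state/tumor/
#'   doublet, `activity` cells x TF matrix of planted activities,
#'   `gene_table`, `network`, `config`).
#' @export
simulate_expression_counts <- function(network, config,
                                       condition_design = default_condition_design(nrow(network$state_activity))) {
  set.seed(config$seed)
  n_states <- nrow(network$state_activity)
  for (cd in condition_design) {
    if (abs(sum(cd$state_props) - 1) > 1e-8)
      stop("validation error: condition state_props must sum to 1")
    if (abs(sum(cd$stage_probs) - 1) > 1e-8)
      stop("validation error: condition stage_probs must sum to 1")
  }
  fracs <- vapply(condition_design, `[[`, numeric(1), "frac")
  n_per <- floor(fracs / sum(fracs) * config$n_cells)
  n_per[1] <- n_per[1] + config$n_cells - sum(n_per)

  gene_table <- build_gene_table(network, config)
  n_genes <- nrow(gene_table)
  conditions <- rep(names(condition_design), times = n_per)
  n_cells <- length(conditions)
  barcodes <- sprintf("CELL%05d", seq_len(n_cells))

  tumor <- logical(n_cells); stage <- character(n_cells); state <- character(n_cells)
  state_ids <- rownames(network$state_activity)
  for (cond in names(condition_design)) {
    idx <- which(conditions == cond)
    cd <- condition_design[[cond]]
    n_tum <- round(length(idx) * config$tumor_fraction)
    tumor[idx[seq_len(n_tum)]] <- TRUE
    stage[idx] <- sample(STAGE_LEVELS, length(idx), replace = TRUE,
                         prob = cd$stage_probs)
    state[idx] <- ifelse(tumor[idx],
                         sample(state_ids, length(idx), replace = TRUE,
                                prob = cd$state_props),
                         "normal")
  }

  # Planted per-cell TF activity.
  tfs <- network$tfs
  activity <- matrix(0, n_cells, length(tfs), dimnames = list(barcodes, tfs))
  reg_ids <- names(network$regulons)
  for (r in seq_along(reg_ids)) {
    rid <- reg_ids[r]
    tf <- network$regulons[[rid]]$tf
    prog <- network$regulon_program[[rid]]
    base_act <- numeric(n_cells)
    base_act[tumor] <- network$state_activity[state[tumor], prog]
    bs <- boost_stages_for(network$trajectory[[rid]])
    boost <- ifelse(tumor & stage %in% bs, config$trajectory_boost, 0)
    noise <- rnorm(n_cells, sd = config$activity_noise_sd)
    noise[!tumor] <- 0
    activity[, tf] <- base_act + boost + noise
  }

  # Gene-to-TF membership (regulon members + the TF's own gene).
  gene_tf <- setNames(rep(NA_character_, n_genes), gene_table$symbol)
  for (rid in reg_ids) {
    reg <- network$regulons[[rid]]
    gene_tf[reg$genes] <- reg$tf
    gene_tf[reg$tf] <- reg$tf
  }

  base_g <- rlnorm(n_genes, meanlog = 0, sdlog = 0.5)
  names(base_g) <- gene_table$symbol
  batch <- c("Primary" = "patient", "PDX-1" = "pdx", "PDX-2" = "pdx",
             "PDX-tr1" = "pdx", "PDX-tr2" = "pdx", "Recurrent" = "patient")[conditions]
  batch_factor <- matrix(1, 2, n_genes,
                         dimnames = list(c("patient", "pdx"), gene_table$symbol))
  if (config$batch_effect_sd > 0)
    batch_factor["pdx", ] <- exp(rnorm(n_genes, sd = config$batch_effect_sd))

  depth <- rlnorm(n_cells, config$lib_size_meanlog, config$lib_size_sdlog)
  log_fold <- matrix(0, n_cells, n_genes)
  has_tf <- !is.na(gene_tf)
  lf_cols <- which(has_tf)
  log_fold[, lf_cols] <- activity[, gene_tf[lf_cols], drop = FALSE] *
    log1p(config$effect_beta)
  weights <- exp(log_fold)
  weights <- sweep(weights, 2, base_g, `*`)
  weights <- weights * batch_factor[batch, , drop = FALSE]
  share <- weights / rowSums(weights)
  mu <- share * depth

  counts <- matrix(rnbinom(length(mu), mu = as.vector(mu),
                           size = 1 / config$dispersion),
                   n_cells, n_genes, dimnames = list(barcodes, gene_table$symbol))
  em <- expression_matrix(counts,
                          cell_meta = data.frame(barcode = barcodes,
                                                 condition = conditions,
                                                 batch = batch,
                                                 stringsAsFactors = FALSE),
                          gene_meta = gene_table)
  cells <- data.frame(barcode = barcodes, condition = conditions, batch = batch,
                      stage = stage, state = state, tumor = tumor,
                      doublet = FALSE, stringsAsFactors = FALSE)
  list(em = em,
       truth = list(cells = cells, activity = activity, gene_table = gene_table,
                    network = network, config = config))
}

#' Inject CNV signatures and doublets
#'
#' Multiplies tumour-cell chr7 counts by `cnv_gain` (extra Poisson counts)
#' and thins chr10 counts binomially to `cnv_loss`; then replaces a
#' `doublet_rate` fraction of cells by the sum of their own counts and a
#' random cell from a different planted state, flagging them in the truth.
#'
#' @param em `ExpressionMatrix` from [simulate_expression_counts()].
#' @param truth Matching truth list.
#' @param config The `SyntheticConfig`.
#' @return List `em`, `truth` with updated counts and doublet flags.
#' @export
inject_cnv_and_doublets <- function(em, truth, config) {
  if (!all(c("chrom") %in% names(em$gene_meta)))
    stop("validation error: gene table lacks chromosome annotation")
  if (!"tumor" %in% names(truth$cells))
    stop("validation error: truth lacks tumor labels")
  set.seed(config$seed + 1L)
  counts <- as.matrix(em$counts)
  tum <- truth$cells$tumor
  if (config$cnv_gain > 1) {
    j <- em$gene_meta$chrom == "chr7"
    block <- counts[tum, j, drop = FALSE]
    counts[tum, j] <- block + rpois(length(block), block * (config$cnv_gain - 1))
  }
  if (config$cnv_loss < 1) {
    j <- em$gene_meta$chrom == "chr10"
    block <- counts[tum, j, drop = FALSE]
    counts[tum, j] <- rbinom(length(block), block, config$cnv_loss)
  }
  n_cells <- nrow(counts)
  n_doub <- round(config$doublet_rate * n_cells)
  if (n_doub > 0) {
    targets <- sample(n_cells, n_doub)
    states <- truth$cells$state
    for (i in targets) {
      partners <- which(states != states[i])
      j <- partners[sample.int(length(partners), 1)]
      counts[i, ] <- counts[i, ] + counts[j, ]
    }
    truth$cells$doublet[targets] <- TRUE
  }
  em2 <- expression_matrix(counts, cell_meta = em$cell_meta,
                           gene_meta = em$gene_meta)
  list(em = em2, truth = truth)
}
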