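# Planted ground-truth regulatory hierarchy: TFs -> regulons -> programs ->
# network states, plus a longitudinal trajectory pattern per regulon.

TRAJECTORY_LABELS <- c("selected_against", "selected_induced", "transient", "flat")

#' Build a planted ground-truth regulatory network
#'
#' Constructs a TF -> regulon -> program -> state hierarchy with known
#' membership, per-state program activity levels in \[-2, 2\], and a
#' longitudinal trajectory pattern per regulon. Regulons are gene-disjoint
#' (one TF per regulon, one regulon per TF).
#'
#' @param n_tfs Number of TFs (= number of regulons).
#' @param genes_per_regulon_range Integer range (lo, hi) of member genes per
#'   regulon; lo must be >= 5.
#' @param n_programs Number of transcriptional programs (2 <= n_programs <=
#'   n_tfs).
#' @param n_states Number of network states (>= 2).
#' @param seed Integer seed; identical arguments + seed give an identical
#'   network.
#' @param trajectory_props Named proportions over the four trajectory labels.
#' @return A `GroundTruthNetwork` list with elements `tfs`, `regulons`
#'   (list of `(tf, genes)`), `programs` (program -> regulon ids),
#'   `regulon_program` (regulon -> program id), `state_activity`
#'   (states x programs matrix), `trajectory` (regulon -> label).
#' @export
build_ground_truth_network <- function(n_tfs, genes_per_regulon_range = c(8L, 15L),
                                       n_programs = 5L, n_states = 5L, seed = 1L,
                                       trajectory_props = c(selected_against = 0.2,
                                                            selected_induced = 0.2,
                                                            transient = 0.2,
                                                            flat = 0.4)) {
  if (n_programs < 2) stop("sizing error: n_programs must be >= 2")
  if (n_tfs < n_programs)
    stop("sizing error: n_tfs (", n_tfs, ") must be >= n_programs (", n_programs, ")")
  if (n_states < 2) stop("sizing error: n_states must be >= 2")
  rng <- as.integer(genes_per_regulon_range)
  if (length(rng) != 2 || rng[1] < 5 || rng[2] < rng[1])
    stop("sizing error: genes_per_regulon_range must be (lo, hi) with lo >= 5")
  stopifnot(abs(sum(trajectory_props) - 1) < 1e-8,
            setequal(names(trajectory_props), TRAJECTORY_LABELS))
  set.seed(seed)

  tfs <- sprintf("TF%02d", seq_len(n_tfs))
  sizes <- sample(seq(rng[1], rng[2]), n_tfs, replace = TRUE)
  gene_pool <- sprintf("G%04d", seq_len(sum(sizes)))
  splits <- split(gene_pool, rep(seq_len(n_tfs), times = sizes))
  regulon_ids <- sprintf("R%02d", seq_len(n_tfs))
  regulons <- lapply(seq_len(n_tfs), function(i)
    list(tf = tfs[i], genes = splits[[i]]))
  names(regulons) <- regulon_ids

  # Programs: round-robin so every program gets at least one regulon.
  program_ids <- sprintf("Pr%d", seq_len(n_programs))
  regulon_program <- setNames(program_ids[(seq_len(n_tfs) - 1) %% n_programs + 1],
                              regulon_ids)
  programs <- split(regulon_ids, regulon_program)[program_ids]

  # Per-state program activity in [-2, 2]: each state strongly activates one
  # program (round-robin) against a random mild background, which keeps state
  # rows distinguishable.
  state_ids <- sprintf("SG%d", seq_len(n_states))
  state_activity <- matrix(round(runif(n_states * n_programs, -1, 1), 2),
                           nrow = n_states,
                           dimnames = list(state_ids, program_ids))
  for (s in seq_len(n_states))
    state_activity[s, (s - 1) %% n_programs + 1] <- 2
  if (anyDuplicated(as.data.frame(state_activity)))
    state_activity <- state_activity + matrix(round(runif(length(state_activity), -0.05, 0.05), 3),
                                              nrow = n_states)

  counts <- floor(trajectory_props * n_tfs)
  rem <- n_tfs - sum(counts)
  if (rem > 0) counts[order(trajectory_props, decreasing = TRUE)[seq_len(rem)]] <-
      counts[order(trajectory_props, decreasing = TRUE)[seq_len(rem)]] + 1
  trajectory <- setNames(sample(rep(TRAJECTORY_LABELS, times = counts)), regulon_ids)

  structure(list(tfs = tfs, regulons = regulons, programs = programs,
                 regulon_program = regulon_program,
                 state_activity = state_activity, trajectory = trajectory),
            class = "GroundTruthNetwork")
}

#' @export
print.GroundTruthNetwork <- function(x, ...) {
  cat(sprintf("GroundTruthNetwork: %d TFs/regulons, %d programs, %d states\n",
              length(x$tfs), length(x$programs), nrow(x$state_activity)))
  invisible(x)
}

# All planted regulon member genes.
network_genes <- function(network)
  unlist(lapply(network$regulons, `[[`, "genes"), use.names = FALSE)
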