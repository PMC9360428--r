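# screvolve

Single-cell regulatory-network states and treatment-response trajectories.

`screvolve` is an R package for analysts studying how a tumour's cell-state
composition evolves under therapy using coupled single-nucleus RNA-seq and
ATAC-seq. It was built around the analysis of glioblastoma evolution across a
primary biopsy, treated patient-derived xenografts, and a recurrent autopsy
sample, and implements that workflow as reusable, tested components:

* **Regulon inference and eigengene activity.** Genes are clustered by
  expression correlation and intersected with a TF→target prior
  (hypergeometric enrichment, BH FDR ≤ 0.05). A regulon's per-cell activity
  is its *eigengene*: with Z the standardized member-gene × cell submatrix
  and Z = UΣVᵀ, activity is σ₁v₁ (the PC1 cell score), sign-oriented to
  correlate positively with mean member expression. Significance compares
  λ₁ = σ₁²/Σσᵢ² with the 95th percentile of λ₁ over 1000 size-matched
  random gene sets.
* **Programs and network states.** k-means on the regulon–regulon activity
  correlation matrix (programs) and average-linkage clustering of cells on
  their activity-profile correlations (states), with k chosen by mean
  silhouette.
* **Accessibility consensus.** chromVAR-style bias-corrected motif deviation
  z-scores, exponential TSS-distance gene scores
  (w = e^(−|d|/5000), |d| ≤ 100 kb), and consensus TFs: deviation–gene-score
  correlation ≥ 0.4 at FDR ≤ 0.1, inter-state deviation difference in the
  upper half, intersected with the regulon TF set.
* **Longitudinal staging and trajectories.** Hypergeometric condition
  enrichment maps SNN clusters onto PT / IPT / LPT-A / LPT-B / REC stages;
  one-sided rank tests per stage (FDR ≤ 0.01) classify each regulon as
  selected-against, selected/induced, transient, or flat.
* **Supporting steps.** QC filters for both modalities, log-normalization,
  iterative TF-IDF LSI, consensus doublet detection, a moving-average CNV
  caller (chr7 gain AND chr10 loss ⇒ tumour), MNN batch integration,
  reference-landscape projection, per-cell gene-set enrichment with
  permutation nulls, Wang/BMA semantic similarity, and drug–target matching.
* **A synthetic multi-omic generator** that plants a known
  TF → regulon → program → state hierarchy (negative-binomial counts,
  activity-coupled accessibility, CNV signatures, doublets, stage-dependent
  activity boosts) so every stage of the pipeline can be validated against
  ground truth.

## Worked example

```r
library(screvolve)

cfg <- synthetic_config(n_cells = 500, n_genes = 800, n_peaks = 800, seed = 42)
bundle <- simulate_fixture_bundle(cfg, n_tfs = 10, n_programs = 3, n_states = 3,
                                  condition_design = default_condition_design(3))

em  <- lognormalize(bundle$rna)
tum <- bundle$truth$cells$tumor & !bundle$truth$cells$doublet
emt <- subset_cells(em, tum)

regs     <- infer_regulons(emt, bundle$annotations$tf_targets)
act      <- regulon_activity(emt, regs)
sig      <- permutation_significance(emt, regs, act, n_perm = 1000, seed = 1)
programs <- detect_programs(act, k_range = 2:6, seed = 1)
states   <- assign_network_states(act, k_range = 2:6, programs = programs$programs)
traj     <- classify_regulon_trajectory(act, bundle$truth$cells$stage[tum])
```

Printed results from this run:

```
ActivityMatrix: 10 regulons x 301 cells; lambda1 in [0.35, 0.58]
significant regulons: 10 of 10
programs chosen k = 2 ; state k = 3
state ARI vs planted truth: 0.99

            flat selected_against selected_induced        transient
               4                2                2                2
```

All 10 planted regulons are recovered and pass the permutation filter
(λ₁ between 0.35 and 0.58, far above random gene sets); the three planted
network states are recovered almost perfectly (adjusted Rand index 0.99
against the generator's labels), and the planted trajectory labels
(4 flat / 2 selected-against / 2 selected-induced / 2 transient) are
reproduced exactly. At this small scale the silhouette criterion merges two
correlated programs (k = 2); at the reference scale (2000 cells, 30
regulons) program recovery is exact — see below.

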