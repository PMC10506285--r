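# spotlink

Reconstruction of ligand–receptor–TF-module signaling networks from
Visium-style spatial transcriptomics, with the full analysis chain around
it and a planted-truth simulator to validate every stage.

## The problem

Spatial transcriptomics of treated tumors poses a chain of questions that
single-cell workflows cannot answer without losing tissue context: how is
the section partitioned into tumor / immune / cancer-associated-fibroblast
(CAF) compartments; which genes and pathways separate responders from
non-responders; which transcription-factor (TF) programs are active in
which spots; and — the step that needs space explicitly — which signals
flow between *adjacent* tissue regions. spotlink implements that chain for
spot-level count matrices with array coordinates, two-group sample
cohorts, and user-supplied cluster annotations.

## What it computes

* **Compartments and composition** — clusters merge into
  tumor/immune/CAF/other; per-sample spot fractions.
* **Pseudo-bulk differential expression** — spot counts summed per patient
  within a compartment; a negative-binomial Wald test per gene with
  median-of-ratios size factors `s_j`, moment dispersions shrunk to a
  mean–dispersion trend, model `K_gj ~ NB(s_j q_{g,group(j)}, alpha_g)`,
  and calls at `|log2FC| >= 2`, BH-adjusted `p <= 0.01`.
* **Preranked enrichment** — the weighted Kolmogorov–Smirnov running-sum
  enrichment score over genes ranked by log2FC, gene-label permutation
  null, NES/p/FDR per signed pool.
* **TF regulatory modules** — per TF, targets with co-expression
  importance strictly above the TF's 95th percentile (optional
  prior-table pruning; modules under 20 genes dropped). Per-spot activity
  is the AUC of the module's gene-recovery curve within the top 5% of each
  spot's ranked genes, normalized to [0, 1].
* **Signaling networks** — for each patient and each ordered pair of
  clusters in direct contact (≥ 10 boundary edges on the hex lattice):
  Pearson correlation of z-scaled receptor expression with module
  activity over the region's spots, zeroed when the module targets the
  receptor, thresholded at `r > 0.3`, and kept only with a cognate ligand
  detected in ≥ 5% of sender spots.
* **Signature scores** — mean normalized expression per spot (a published
  cancer-stem-cell signature ships in `inst/extdata`), Wilcoxon region
  contrasts, and Spearman correlation of signature genes against
  cell-type proportion tables.
* **Synthetic tissues** — `generate_tissue()` draws multi-sample hex-grid
  cohorts with contiguous domains, NB counts, planted regulons driven by
  smooth latent fields, planted signaling links with decoy
  receptors/ligands/TFs, planted fold changes and localized signatures —
  and returns the ground truth to score recovery.

## Worked example

```r
library(spotlink)

# simulate a two-sample cohort with planted signaling ground truth
sim <- generate_tissue(sim_params(), seed = 7)
ds  <- annotate_from_truth(sim$dataset, sim$truth)
ds
#> spot_dataset: 1500 genes x 4050 spots, 2 sample(s)
#>   clusters: CAF, immune, other, tumor_A, tumor_B
#>   compartments: CAF, immune, other, tumor

cfg <- spotlink_config(rng_seed = 7)
ds   <- filter_rare_genes(filter_low_quality_spots(ds, cfg$min_counts),
                          cfg$min_spot_fraction)
norm <- normalize_logcpm(ds)

# regulons from co-expression, pruned by the (truth-derived) prior
tfs  <- names(sim$truth$planted_regulons)
imps <- coexpression_importance(norm, tfs, sample_id = ds$spots$sample_id)
regs <- build_modules(imps, prior = truth_prior(sim$truth))
act  <- aucell_scores(norm, regs, cfg$aucell_top_fraction, seed = 7)

net <- run_interaction_analysis(ds, act, regs,
                                truth_lr_reference(sim$truth), cfg)
head(net$edges[, c("sender_cluster", "receiver_cluster", "ligand",
                   "receptor", "tf_module", "correlation")])
#>   sender_cluster receiver_cluster ligand receptor tf_module correlation
#> 1        tumor_A              CAF LIG002   REC002     TF002   0.3909607
#> 2        tumor_A              CAF LIG004   REC004     TF004   0.3892434
#> 3        tumor_A              CAF LIG006   REC006     TF006   0.3961249
#> 4        tumor_A              CAF LIG008   REC008     TF008   0.3791576
#> 5        tumor_A           immune LIG001   REC001     TF001   0.4956626
#> 6        tumor_A           immune LIG003   REC003     TF003   0.3631259

unlist(score_network_recovery(net, sim$truth))
#>   precision      recall n_recovered   n_planted  n_reported
#>           1           1           8           8           8
```

Each edge reads: spots of the sender cluster express the ligand, the
receiver cluster's spots express its receptor, and that receptor's
z-scaled expression tracks the named TF module's activity at the printed
Pearson r. Here all 8 planted links are recovered with no false edge among
the 40 decoy receptors.

`run_pipeline(config, out_dir)` executes the same chain end to end
(simulated or from a 10x-style triplet directory) and writes every stage
artifact plus a manifest of content hashes; identical seeds reproduce
identical hashes.

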