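---
title: "spotlink: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{spotlink: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Scope

spotlink reconstructs intercellular signaling from Visium-style spatial
transcriptomics of treated tumors. The chain it implements: spot and gene
quality filtering; merging expression clusters into tissue compartments
(tumor / immune / CAF / other) with per-sample composition; pseudo-bulk
negative-binomial differential expression between two response groups;
preranked gene-set enrichment of the fold-change ranking; construction of
transcription-factor (TF) regulatory modules from co-expression with
per-spot activity scored as the area under a gene-recovery curve; and
reconstruction of ligand-receptor-TF-module networks between spatially
adjacent clusters. A synthetic tissue generator with planted ground truth
(regulons, signaling links, fold changes, localized signatures) makes every
stage testable end to end.

Cluster labels are pipeline inputs. Graph clustering, batch integration,
image processing and spot deconvolution are deliberately out of scope; a
PCA + k-means utility (`fallback_cluster()`) exists only for label-free
smoke tests.

# The model, stage by stage

## Filtering and normalization

Spots below a total-UMI floor (`min_counts`, default 250 — a conventional
QC choice, not a biologically derived constant) or on an explicit exclusion
list are removed. Genes detected in fewer than `min_spot_fraction` (2.5%)
of spots are dropped; the rule is "fraction strictly below the threshold is
excluded", so a gene detected in exactly 2.5% of spots is retained. Within
the signaling analysis the filter is applied per region (the cluster subset
under analysis), matching its role there; a global application is a switch
away.

Normalization is log-CPM, `log2(1 + 1e4 * count / spot_total)`. Every
downstream statistic — Pearson and Spearman correlations, module means, AUC
ranks — needs only a depth-removing, monotone, roughly variance-stabilized
scale, which log-CPM provides without a fitted regression model. This is a
deliberate, documented divergence from variance-stabilizing-regression
normalizers used in comparable workflows: it keeps the pipeline free of an
external fitted model while leaving all rank- and correlation-based results
essentially unchanged.

## Hex-grid geometry

Spots live on the Visium array lattice: integer `(array_row, array_col)`
with even row + column parity. Two spots of one sample are neighbors iff
their offset is `(0, ±2)` or `(±1, ±1)` — the six hex neighbors.
Cross-sample edges are never created, because each patient's tissue is an
independent physical section. Two clusters are "in direct contact" when at
least `min_contact_edges` (default 10) neighbor edges cross their boundary;
the literature phrase has no quantitative definition, and a small floor
suppresses single-spot contact artifacts.

## Pseudo-bulk differential expression

Spot counts are summed per sample within a compartment (default: one
library per patient per compartment; the alternative patient-by-cluster
unit is not used). The test is a negative-binomial Wald test per gene:

* size factors by median-of-ratios, with the geometric-mean reference
  computed over genes with no zero count in any sample;
* per-gene dispersion by method of moments on normalized counts, using
  pooled *within-group* means and variances so true group effects do not
  inflate it, floored at `1e-8`;
* dispersions shrunk on the log scale toward a fitted `a0 + a1/mean`
  trend, with weight 0.25 on the raw estimate. With six samples per group
  the raw moment estimate carries roughly ten degrees of freedom, and
  letting more of it into the Wald standard error visibly inflates the
  type-I error; weighting three quarters of the estimate to the trend
  (which pools thousands of genes) restores nominal calibration while
  keeping genuine per-gene dispersion signal. The weight is an exposed
  argument;
* a per-gene NB GLM (log link, group coefficient, size-factor offset) at
  the fixed final dispersion. Standard errors are taken at that fixed
  dispersion — not rescaled by a Pearson quasi-dispersion factor, which
  would make the statistic exactly Student-t with few degrees of freedom
  and anti-conservative under the intended normal reference;
* two-sided normal p-values, BH adjustment across all tested genes (genes
  removed by the detection filter never enter the pool, which deflates the
  BH denominator relative to an unfiltered analysis — intended), and calls
  `up_A`/`up_B` at `|log2FC| >= 2` and `padj <= 0.01`.

Genes with a complete separation (one group all zero) fall back to a
moment estimate with a 0.5 continuity correction and a delta-method SE.
Ties in p-value are broken by |statistic|, then gene id, for stable output
order. Exact equality with any external DE package is not promised; the
test surface is calibration (null false-positive rate) and planted-effect
recovery, plus a cross-check of fold-change agreement against an
independent NB implementation in the test suite.

## Preranked enrichment

The classic weighted Kolmogorov-Smirnov running sum with weight exponent 1
on genes ranked by DE log2 fold change (descending, ties by gene id). Hits
advance the sum by `|score| / sum(|score| in set)`, misses retreat by
`1/(N - m)`; the enrichment score (ES) is the extremum of largest
magnitude, and an exact tie between the positive and negative extremum
resolves to the positive one. The null is gene-label permutation (the
input is a preranked list, so phenotype permutation is unavailable): each
of `n_perm` permutations rescores a random same-size set. NES divides ES
by the mean |null ES| of matching sign; p-values and FDR q-values come
from the signed null pools, so `p >= 1/(n_perm + 1)` always. Sets whose
sign pool is empty get `NES = NaN` and are flagged rather than dropped.

## TF modules and AUC activity

For each TF in a user-supplied list, every other expressed gene receives
an importance: the absolute Spearman correlation between TF and gene
expression. Correlations are computed *within sample* and pooled as the
spot-weighted mean of signed correlations before taking the absolute
value. This matters in multi-sample cohorts: group-level fold changes and
per-sample offsets otherwise create spurious cross-sample co-expression
that can crowd genuine targets out of a module. (Workflows built on
gradient-boosting importances typically run after a batch-integration
step; within-sample pooling is the offline analogue.)

A candidate joins the module when its importance is strictly above the
TF's 95th percentile of candidate importances. The percentile is per-TF by
default; the pooled-global alternative is a switch, since either reading
of "above the 95th percentile" is defensible. An optional TF-to-target
prior table (the offline stand-in for motif-based pruning) then removes
unlisted targets, and modules with fewer than 20 genes are excluded.

Per-spot activity is the AUC of the module's gene-recovery curve: genes
ranked by descending expression within the spot (ties broken by one seeded
random permutation fixed per run, mirroring the cited scoring tool's
behavior while keeping runs reproducible), the curve counts module genes
among the top `i` ranks for `i = 1..k` with `k = ceil(0.05 * N)`, and the
score is the curve's area divided by the best achievable area. Scores are
rank-based (invariant to monotone transforms of a spot's profile) and lie
in [0, 1]. The 5% top fraction is the scoring tool's conventional default;
it is configurable.

## Signaling networks

For each sample and each ordered (sender, receiver) pair of adjacent
clusters: the region is the union of sender and receiver spots (a
receiver-only mode is a flag, as the original description is ambiguous);
the detection filter is applied within the region; each receptor's
expression is z-scaled over region spots and Pearson-correlated with each
module's raw AUC activity (only the receptor side is z-scaled — following
the method's description literally; Pearson correlation is anyway
invariant to affine rescaling of either side). Then three pruning rules:

1. the correlation of a receptor with a module that contains it as a
   target is set to exactly zero (the module would trivially track its own
   member);
2. links require `r > 0.3`, strictly and one-sided;
3. a link enters the network only with an expressed cognate ligand: some
   ligand-receptor record lists the receptor, and the ligand is detected
   in at least 5% of sender spots. The reference's own gene universe
   defines cognate pairs; a receptor absent from the reference is dropped
   and recorded in an exclusion report. Multi-subunit complexes require
   every subunit to pass — the conservative reading. The 5% sender
   detection floor is this package's choice (the source method states no
   ligand rule beyond the global detection filter) and is exposed in the
   configuration.

One edge is emitted per qualifying (ligand, receptor, module) triple, with
sender/receiver context. Every emitted network re-asserts the three rules
before it is returned.

## Signature scoring

A signature's score in a spot is the arithmetic mean of normalized
expression over the signature's genes ("averaged expression"); an
expression-bin-matched background-corrected variant (24 bins, seeded
control draws) is opt-in. Region contrasts use the two-sided Wilcoxon
rank-sum test (exact for small tie-free samples), BH-adjusted across
signatures — the source reports significance without naming a test, and
the rank-sum test is the standard distribution-free choice.
Signature-versus-cell-proportion association uses Spearman correlation
with average ranks on ties and two-sided t-approximation p-values. The
packaged cancer-stem-cell signature retains the published symbols
verbatim, but "SP", "YY1A1" (not valid gene symbols) and "NOTCH" (a family
name) are excluded from scoring by default with a loud warning rather than
silently remapped.

# The synthetic generator

Each sample is a hex patch (default 45 x 90, ~2025 spots) partitioned into
five contiguous domains (`tumor_A`, `tumor_B`, `immune`, `CAF`, `other`)
by randomized multi-source region growth: one seed per domain (central
tumor seeded at the centroid, the others at the side midpoints so each
collides with — hence touches — the tumor), round-robin expansion into
unclaimed neighbor spots until quotas are met. Counts are negative
binomial with gene-level dispersion drawn log-normal
(`meanlog = log 0.25`, `sdlog = 0.5` — typical UMI overdispersion),
per-spot depth log-normal with CV 0.3 (so the normalization path matters),
and per-sample, per-gene log-normal biological noise (`sigma = 0.25`),
which is what gives pseudo-bulk replicates realistic between-patient
variability.

Each planted regulon has a latent activity field: iid Gaussian noise
neighbor-averaged for three sweeps, standardized within the receiver
domain, clipped to ±3, zero elsewhere — any spatially smooth field
suffices, and this one has positive Moran's I by construction. Targets,
the TF gene itself and the cognate receptor load on the field
multiplicatively, *mean-centered* (`exp(beta*A - beta^2/2)`) so that
domain-average expression stays flat: module-receptor correlations then
come from the latent field rather than from shared domain-mean offsets,
which would otherwise create cross-talk between unrelated modules sharing
a receiver domain. Ligands are expressed essentially only in the sender
domain; decoy receptors and ligands are expressed but structureless, and
decoy TFs have no targets. Planted DE genes get a symmetric group shift
(`±lfc/2` per group); a planted stemness-like signature is elevated in
`tumor_B` only.

The generator converts an intended receptor-module correlation `rho` into
a log-scale loading by inverting `r = kappa * L / sqrt(L^2 + V)`, with
`kappa = 0.84` (the attenuation between latent field and AUC activity) and
`V = 1.7 * (1/mu + alpha)` (the effective log-scale noise variance of
receptor expression; the 1.7 absorbs the log1p transform, depth variation
and rank-tie noise). Both constants were calibrated once from a loading
sweep and then frozen; the explicit `receptor_loading` parameter bypasses
the conversion. No quantitative effect sizes are available for the
biological system being emulated, so defaults are chosen for testability,
not realism.

What the generator does *not* emulate: within-spot cell-type mixtures,
segmentation/doublet artifacts, zero-inflation beyond NB sampling,
ambient RNA, or any image channel. Passing tests therefore demonstrate
correctness of the statistical machinery under a well-specified model, not
performance on real tissue.

# Numerical choices and degenerate inputs

* Fractions are validated in (0, 1), the AUC top fraction in (0, 0.5];
  configuration errors surface before any stage runs.
* Zero-variance receptors yield r = 0 and are flagged; regions under 10
  spots are refused for correlation.
* Empty networks, empty module lists and samples without adjacent cluster
  pairs are legal outcomes, not errors.
* All randomness (generator, enrichment permutations, AUC tie-breaks,
  background controls) flows from one root seed, split per stage by fixed
  offsets; identical seeds reproduce byte-identical artifacts and
  manifest hashes.
* Test problem sizes: oracle comparisons run at a few hundred genes and
  up to a few thousand spots; the DE calibration cohort is 6 vs 6 samples
  of ~400 spots at 2000 genes; the network-recovery scenario is two
  samples of ~2025 spots with 8 planted links against 40 decoy receptors.
  These sizes were chosen so the whole suite exercises every claim in
  minutes on a laptop while keeping Monte-Carlo error small relative to
  each assertion's margin.

# Known limitations

* The DE module is a documented NB Wald pipeline, not a re-implementation
  of any specific external package; LFC shrinkage, independent filtering
  and outlier handling are absent by design.
* Communication scoring is correlation-based; no distance-decay weighting
  and no permutation significance for edges.
* Gene identity is by case-sensitive symbol with an optional user alias
  map; no online identifier resolution.
* The mitochondrial/ribosomal content of spots is not filtered by default;
  no such rule is part of the described workflow.
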