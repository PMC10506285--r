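#' Pipeline configuration
#'
#' Collects every threshold the pipeline applies, with the defaults used
#' throughout: genes must be detected in at least `min_spot_fraction` of spots
#' (2.5%); differential expression calls require `|log2FC| >=` `lfc_threshold`
#' (2) and BH-adjusted p `<=` `padj_threshold` (0.01); a candidate target
#' enters a TF module when its importance exceeds that TF's
#' `importance_percentile` (95th) and modules below `min_module_genes` (20)
#' are discarded; a receptor links to a module when the spot-level Pearson
#' correlation is strictly greater than `corr_threshold` (0.3); AUC activity
#' is computed over the top `aucell_top_fraction` (5%) of each spot's ranked
#' genes; cluster pairs count as spatially adjacent from `min_contact_edges`
#' (10) boundary edges; a cognate ligand counts as expressed in the sender
#' when detected in at least `ligand_expr_fraction` (5%) of sender spots.
#'
#' @param min_spot_fraction fraction of spots a gene must be detected in.
#' @param lfc_threshold absolute log2 fold-change bound for DE calls.
#' @param padj_threshold BH-adjusted p-value bound for DE calls.
#' @param importance_percentile percentile (0-100) of a TF's candidate
#'   importances a target must strictly exceed.
#' @param percentile_scope `"per_tf"` (default) or `"global"`: whether the
#'   importance percentile is taken over each TF's own candidates or over all
#'   TF-gene importances pooled.
#' @param min_module_genes minimum module size after pruning.
#' @param corr_threshold strict lower bound on receptor-module Pearson r.
#' @param aucell_top_fraction fraction of the ranked gene list integrated by
#'   the AUC recovery curve; must lie in (0, 0.5].
#' @param gsea_permutations gene-label permutations for the enrichment null.
#' @param min_contact_edges boundary-edge floor for cluster adjacency.
#' @param ligand_expr_fraction sender-side detection fraction for ligands.
#' @param min_counts spot-level total-count floor used by quality filtering.
#' @param region_mode `"union"` (correlations over sender plus receiver spots,
#'   default) or `"receiver"` (receiver spots only).
#' @param rng_seed root seed; every stage derives its own stream from it.
#'
#' @return A `spotlink_config` list, validated.
#' @export
spotlink_config <- function(min_spot_fraction = 0.025,
                            lfc_threshold = 2.0,
                            padj_threshold = 0.01,
                            importance_percentile = 95,
                            percentile_scope = c("per_tf", "global"),
                            min_module_genes = 20,
                            corr_threshold = 0.3,
                            aucell_top_fraction = 0.05,
                            gsea_permutations = 1000,
                            min_contact_edges = 10,
                            ligand_expr_fraction = 0.05,
                            min_counts = 250,
                            region_mode = c("union", "receiver"),
                            rng_seed = 1L) {
  cfg <- list(
    min_spot_fraction = min_spot_fraction,
    lfc_threshold = lfc_threshold,
    padj_threshold = padj_threshold,
    importance_percentile = importance_percentile,
    percentile_scope = match.arg(percentile_scope),
    min_module_genes = as.integer(min_module_genes),
    corr_threshold = corr_threshold,
    aucell_top_fraction = aucell_top_fraction,
    gsea_permutations = as.integer(gsea_permutations),
    min_contact_edges = as.integer(min_contact_edges),
    ligand_expr_fraction = ligand_expr_fraction,
    min_counts = min_counts,
    region_mode = match.arg(region_mode),
    rng_seed = as.integer(rng_seed)
  )
  class(cfg) <- "spotlink_config"
  validate_config(cfg)
  cfg
}

#' Validate a pipeline configuration
#'
#' @param cfg a `spotlink_config`.
#' @return `cfg`, invisibly, if valid; otherwise a parameter error naming the
#'   first offending field.
#' @export
validate_config <- function(cfg) {
  frac_fields <- c("min_spot_fraction", "ligand_expr_fraction")
  for (f in frac_fields) {
    v <- cfg[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0 || v >= 1)
      sl_parameter_error("config field '%s' must be a fraction in (0, 1); got %s", f, format(v))
  }
  if (!is.numeric(cfg$aucell_top_fraction) || cfg$aucell_top_fraction <= 0 ||
      cfg$aucell_top_fraction > 0.5)
    sl_parameter_error("aucell_top_fraction must lie in (0, 0.5]; got %s",
                       format(cfg$aucell_top_fraction))
  if (!is.finite(cfg$corr_threshold) || abs(cfg$corr_threshold) > 1)
    sl_parameter_error("corr_threshold must be a finite correlation; got %s",
                       format(cfg$corr_threshold))
  if (!is.finite(cfg$lfc_threshold) || cfg$lfc_threshold < 0)
    sl_parameter_error("lfc_threshold must be finite and non-negative")
  if (!is.finite(cfg$padj_threshold) || cfg$padj_threshold <= 0 || cfg$padj_threshold > 1)
    sl_parameter_error("padj_threshold must lie in (0, 1]")
  if (cfg$importance_percentile <= 0 || cfg$importance_percentile >= 100)
    sl_parameter_error("importance_percentile must lie in (0, 100)")
  if (cfg$min_module_genes < 1)
    sl_parameter_error("min_module_genes must be >= 1")
  if (cfg$gsea_permutations < 1)
    sl_parameter_error("gsea_permutations must be >= 1")
  if (cfg$min_contact_edges < 1)
    sl_parameter_error("min_contact_edges must be >= 1")
  if (cfg$min_counts < 0)
    sl_parameter_error("min_counts must be >= 0")
  if (!is.numeric(cfg$rng_seed) || !is.finite(cfg$rng_seed))
    sl_parameter_error("rng_seed must be a finite integer")
  invisible(cfg)
}

#' Read a configuration from YAML
#'
#' Unknown keys are rejected so typos never silently fall back to defaults.
#'
#' @param path YAML file whose keys are `spotlink_config()` arguments.
#' @return validated `spotlink_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) sl_format_error("config file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(spotlink_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    sl_parameter_error("unknown config key(s): %s", paste(bad, collapse = ", "))
  do.call(spotlink_config, vals)
}

#' @export
print.spotlink_config <- function(x, ...) {
  cat("spotlink pipeline configuration\n")
  for (f in names(x)) cat(sprintf("  %-22s %s\n", f, format(x[[f]])))
  invisible(x)
}
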