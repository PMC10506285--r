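#' Run the full pipeline end to end
#'
#' Executes the stage chain — simulate (or load), spot/gene filtering,
#' compartment merging and proportions, pseudo-bulk differential expression
#' on the tumor compartment, preranked enrichment of the fold-change ranking,
#' regulon construction and AUC activity scoring, adjacency-restricted
#' signaling-network reconstruction, and signature scoring — writing every
#' stage artifact plus a run manifest (config snapshot, seed, content hash of
#' each output) under `out_dir`. All randomness derives from
#' `config$rng_seed`, split per stage; re-running with the same inputs and
#' seed reproduces identical hashes for every deterministic stage.
#'
#' @param config a [spotlink_config()], or the path to a YAML config.
#' @param out_dir output directory.
#' @param simulate generate the input cohort with [generate_tissue()].
#' @param sim_params_obj parameters for the simulation (default
#'   [sim_params()]).
#' @param input_dir when `simulate = FALSE`: a directory in the layout
#'   written by [write_10x_triplet()].
#' @param lr optional LR reference; defaults to the truth-derived reference
#'   when simulating (required otherwise for the signaling stage).
#' @param prior optional TF-target prior table for module pruning; defaults
#'   to the truth-derived prior when simulating.
#' @param gene_sets optional named list of gene sets for enrichment and
#'   scoring; defaults to truth-derived signatures when simulating.
#' @return the run manifest, invisibly; all artifacts on disk.
#' @export
run_pipeline <- function(config = spotlink_config(), out_dir,
                         simulate = TRUE, sim_params_obj = sim_params(),
                         input_dir = NULL, lr = NULL, prior = NULL,
                         gene_sets = NULL) {
  if (is.character(config)) config <- read_config(config)
  validate_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = unclass(config), seed = config$rng_seed,
                   stages = list(), outputs = list())

  ## ---- input ----------------------------------------------------------
  if (simulate) {
    sim <- generate_tissue(sim_params_obj, seed = sl_stage_seed(config$rng_seed, "simulate"))
    ds <- annotate_from_truth(sim$dataset, sim$truth)
    truth <- sim$truth
    lr <- lr %||% truth_lr_reference(truth)
    prior <- prior %||% truth_prior(truth)
    if (is.null(gene_sets)) {
      gene_sets <- lapply(truth$planted_signatures, `[[`, "genes")
      names(gene_sets) <- names(truth$planted_signatures)
    }
    write_10x_triplet(ds, file.path(out_dir, "input"))
    jsonlite::write_json(
      list(planted_links = truth$planted_links,
           planted_de_genes = as.list(truth$planted_de_genes),
           seed = truth$generator_params$seed),
      file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  } else {
    if (is.null(input_dir)) sl_parameter_error("input_dir required when simulate = FALSE")
    if (is.null(lr))
      sl_parameter_error("signaling stage needs an LR reference (lr = )")
    ann_path <- file.path(input_dir, "annotations.tsv")
    ann <- if (file.exists(ann_path))
      utils::read.table(ann_path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
    else NULL
    ds <- read_10x_triplet(file.path(input_dir, "matrix.mtx"),
                           file.path(input_dir, "genes.tsv"),
                           file.path(input_dir, "barcodes.tsv"),
                           file.path(input_dir, "positions.csv"),
                           annotations = ann)
    truth <- NULL
  }
  manifest$stages$input <- "ok"

  ## ---- preprocess ------------------------------------------------------
  ds <- filter_low_quality_spots(ds, config$min_counts)
  ds <- filter_rare_genes(ds, config$min_spot_fraction)
  props <- compartment_proportions(ds)
  utils::write.table(props, file.path(out_dir, "compartment_proportions.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  norm <- normalize_logcpm(ds)
  manifest$stages$preprocess <- "ok"

  ## ---- differential expression + enrichment ---------------------------
  de <- NULL
  n_per_group <- table(unique(ds$spots[, c("sample_id", "group")])$group)
  if (length(n_per_group) == 2 && all(n_per_group >= 2)) {
    pb <- pseudobulk(ds, "tumor")
    de <- nb_wald_test(pb$counts, pb$groups, config = config)
    utils::write.table(de, file.path(out_dir, "de_results.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(as.list(attr(de, "summary")),
                         file.path(out_dir, "de_summary.json"), auto_unbox = TRUE)
    if (length(gene_sets)) {
      ranking <- stats::setNames(de$log2fc, de$gene)
      enr <- preranked_gsea(ranking, gene_sets, n_perm = config$gsea_permutations,
                            seed = sl_stage_seed(config$rng_seed, "gsea"))
      utils::write.table(hallmark_summary(enr)[, c("set", "size", "es", "nes", "pvalue", "fdr")],
                         file.path(out_dir, "enrichment.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    }
    manifest$stages$diffexp <- "ok"
  } else {
    manifest$stages$diffexp <- "skipped: fewer than 2 samples per group"
  }

  ## ---- regulons + activity --------------------------------------------
  tf_list <- if (!is.null(prior)) unique(prior$tf) else
    grep("^TF", rownames(norm), value = TRUE)
  net <- NULL
  if (length(tf_list) && any(tf_list %in% rownames(norm))) {
    imps <- coexpression_importance(norm, tf_list,
                                    seed = sl_stage_seed(config$rng_seed, "regulon"),
                                    sample_id = ds$spots$sample_id)
    regs <- build_modules(imps, config$importance_percentile,
                          config$min_module_genes, prior = prior,
                          scope = config$percentile_scope)
    if (length(regs)) {
      act <- aucell_scores(norm, regs, config$aucell_top_fraction,
                           seed = sl_stage_seed(config$rng_seed, "aucell"))
      utils::write.table(act, file.path(out_dir, "activity.tsv"),
                         sep = "\t", quote = FALSE, col.names = NA)
      net <- run_interaction_analysis(ds, act, regs, lr, config)
      write_network(net, file.path(out_dir, "network.tsv"))
      jsonlite::write_json(net$excluded, file.path(out_dir, "network_exclusions.json"))
      manifest$stages$signaling <- "ok"
    } else {
      manifest$stages$signaling <- "skipped: no module survived pruning"
    }
  } else {
    manifest$stages$signaling <- "skipped: no TF list available"
  }

  ## ---- signature scoring ----------------------------------------------
  if (length(gene_sets)) {
    sc <- module_score(norm, gene_sets)
    utils::write.table(sc, file.path(out_dir, "signature_scores.tsv"),
                       sep = "\t", quote = FALSE, col.names = NA)
    manifest$stages$scoring <- "ok"
  } else {
    manifest$stages$scoring <- "skipped: no gene sets"
  }

  ## ---- manifest --------------------------------------------------------
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- files[basename(files) != "manifest.json"]
  manifest$outputs <- as.list(tools::md5sum(files))
  names(manifest$outputs) <- sub(paste0("^", out_dir, "/?"), "", files)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
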