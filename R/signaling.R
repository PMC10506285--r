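#' Correlate receptor expression with module activity over a region
#'
#' Pearson correlation, over the spots of one spatial region, between each
#' module's per-spot activity (raw AUC scores) and each receptor's z-scaled
#' normalized expression (z-scaling over the region's spots). A receptor with
#' zero variance in the region yields r = 0 and is flagged.
#'
#' @param activity `activity_matrix` (modules x spots).
#' @param norm_matrix genes x spots normalized matrix.
#' @param receptors receptor gene ids present in `norm_matrix`.
#' @param region_spots spot ids of the region (>= 10).
#' @return list: `r` (receptors x modules matrix), `flagged` (receptors with
#'   degenerate variance).
#' @export
receptor_module_correlation <- function(activity, norm_matrix, receptors, region_spots) {
  if (length(region_spots) < 10L)
    sl_validation_error("region has %d spots; need >= 10 for correlation",
                        length(region_spots))
  missing <- setdiff(receptors, rownames(norm_matrix))
  if (length(missing))
    sl_validation_error("receptor(s) absent from the matrix: %s",
                        paste(missing, collapse = ", "))
  expr <- norm_matrix[receptors, region_spots, drop = FALSE]
  act <- activity[, region_spots, drop = FALSE]
  sds <- apply(expr, 1, stats::sd)
  flagged <- receptors[sds == 0]
  z <- expr
  ok <- sds > 0
  z[ok, ] <- (expr[ok, , drop = FALSE] - rowMeans(expr[ok, , drop = FALSE])) / sds[ok]
  suppressWarnings(r <- stats::cor(t(z), t(act)))
  r[!ok, ] <- 0
  r[is.na(r)] <- 0
  list(r = r, flagged = flagged)
}

#' Zero out correlations of receptors targeted by the TF
#'
#' If a receptor is itself a member of a TF module's target set, its
#' correlation with that module is set to exactly zero (the module would
#' trivially track a gene it contains).
#'
#' @param corr_matrix receptors x modules correlation matrix.
#' @param regulons list of `regulon` objects keyed by module name.
#' @return the pruned matrix.
#' @export
prune_targeted_receptors <- function(corr_matrix, regulons) {
  for (m in colnames(corr_matrix)) {
    reg <- regulons[[m]]
    if (is.null(reg)) next
    hit <- rownames(corr_matrix) %in% reg$targets
    corr_matrix[hit, m] <- 0
  }
  corr_matrix
}

#' Candidate receptor-module links above the correlation threshold
#'
#' A link is kept iff r is strictly greater than `corr_threshold` (default
#' 0.3); the rule is one-sided and strict.
#'
#' @param corr_matrix pruned receptors x modules matrix.
#' @param corr_threshold strict lower bound on r.
#' @return data.frame `receptor, tf_module, correlation`.
#' @export
link_receptors <- function(corr_matrix, corr_threshold = 0.3) {
  hit <- which(corr_matrix > corr_threshold, arr.ind = TRUE)
  data.frame(receptor = rownames(corr_matrix)[hit[, 1]],
             tf_module = colnames(corr_matrix)[hit[, 2]],
             correlation = corr_matrix[hit],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Require an expressed cognate ligand on the sender side
#'
#' A receptor-module link enters the network only if the ligand-receptor
#' reference lists a cognate ligand for the receptor and that ligand is
#' detected (count > 0) in at least `ligand_expr_fraction` of the sender
#' cluster's spots. One edge is emitted per qualifying (ligand, receptor,
#' module) triple. Multi-subunit entries require every subunit to pass:
#' all receptor subunits must be linked-compatible (the tested receptor gene
#' must be among them) and all ligand subunits must pass detection.
#'
#' @param links data.frame from [link_receptors()].
#' @param lr an [lr_reference()] table.
#' @param sender_counts raw counts matrix restricted to sender spots.
#' @param ligand_expr_fraction sender detection floor.
#' @return list: `edges` (data.frame `ligand, receptor, tf_module,
#'   correlation`), `excluded` (data.frame `receptor, reason`).
#' @export
require_cognate_ligands <- function(links, lr, sender_counts,
                                    ligand_expr_fraction = 0.05) {
  n_sender <- ncol(sender_counts)
  detected_frac <- function(gene) {
    if (!gene %in% rownames(sender_counts)) return(0)
    sum(sender_counts[gene, ] > 0) / n_sender
  }
  edges <- list(); excluded <- list()
  for (i in seq_len(nrow(links))) {
    rec <- links$receptor[i]
    recs <- vapply(lr$receptor_genes, function(g) rec %in% g, logical(1))
    if (!any(recs)) {
      excluded[[length(excluded) + 1L]] <-
        data.frame(receptor = rec, reason = "not_in_lr_reference")
      next
    }
    found <- FALSE
    for (j in which(recs)) {
      lig <- lr$ligand_genes[[j]]
      if (all(vapply(lig, detected_frac, numeric(1)) >= ligand_expr_fraction)) {
        found <- TRUE
        edges[[length(edges) + 1L]] <- data.frame(
          ligand = paste(lig, collapse = ","),
          receptor = rec,
          tf_module = links$tf_module[i],
          correlation = links$correlation[i],
          stringsAsFactors = FALSE)
      }
    }
    if (!found)
      excluded[[length(excluded) + 1L]] <-
        data.frame(receptor = rec, reason = "no_expressed_cognate_ligand")
  }
  list(
    edges = if (length(edges)) unique(do.call(rbind, edges)) else
      data.frame(ligand = character(), receptor = character(),
                 tf_module = character(), correlation = numeric()),
    excluded = if (length(excluded)) unique(do.call(rbind, excluded)) else
      data.frame(receptor = character(), reason = character())
  )
}

#' Reconstruct signaling networks between adjacent clusters
#'
#' Runs the full chain per sample and per ordered (sender, receiver) pair of
#' spatially adjacent clusters: region subsetting (sender plus receiver
#' spots, or receiver-only under `region_mode = "receiver"`), the
#' detection-fraction gene filter within the region, z-scaled receptor vs.
#' module-activity Pearson correlation, zeroing of receptors targeted by the
#' module's TF, the strict correlation threshold, and the sender-side
#' cognate-ligand requirement. Both orientations of every adjacent pair are
#' analyzed. A sample with no adjacent pair yields an empty network.
#'
#' @param ds annotated `spot_dataset` (clusters assigned, spots filtered).
#' @param activity `activity_matrix` over the same spots.
#' @param regulons the regulon list behind `activity`.
#' @param lr an [lr_reference()] table.
#' @param config a [spotlink_config()].
#' @param receptors optional receptor universe; defaults to every receptor
#'   gene named in `lr`.
#' @return a `signaling_network`: `edges` (with `sample_id`,
#'   `sender_cluster`, `receiver_cluster` columns), `excluded`, `config`,
#'   `seed`.
#' @export
run_interaction_analysis <- function(ds, activity, regulons, lr,
                                     config = spotlink_config(),
                                     receptors = NULL) {
  receptors <- receptors %||% unique(unlist(lr$receptor_genes))
  norm_all <- normalize_logcpm(ds)
  edges <- list(); excluded <- list()

  for (s in unique(ds$spots$sample_id)) {
    dss <- ds_subset(ds, spots = which(ds$spots$sample_id == s))
    g <- build_neighbor_graph(dss)
    pairs <- adjacent_cluster_pairs(g, config$min_contact_edges)
    if (!nrow(pairs)) next
    oriented <- rbind(
      data.frame(sender = pairs$cluster_a, receiver = pairs$cluster_b),
      data.frame(sender = pairs$cluster_b, receiver = pairs$cluster_a))
    for (i in seq_len(nrow(oriented))) {
      snd <- oriented$sender[i]; rcv <- oriented$receiver[i]
      region_clusters <- if (config$region_mode == "receiver") rcv else c(snd, rcv)
      region <- subset_region(dss, region_clusters)
      if (ncol(region$counts) < 10L) next
      region_f <- tryCatch(filter_rare_genes(region, config$min_spot_fraction),
                           spotlink_validation_error = function(e) NULL)
      if (is.null(region_f)) next
      rec_here <- intersect(receptors, rownames(region_f$counts))
      if (!length(rec_here)) next
      region_spots <- region_f$spots$spot_id
      cm <- receptor_module_correlation(activity, norm_all, rec_here, region_spots)
      pruned <- prune_targeted_receptors(cm$r, regulons)
      links <- link_receptors(pruned, config$corr_threshold)
      if (!nrow(links)) next
      sender_spots <- dss$spots$spot_id[dss$spots$cluster == snd]
      res <- require_cognate_ligands(links, lr,
                                     ds$counts[, sender_spots, drop = FALSE],
                                     config$ligand_expr_fraction)
      if (nrow(res$edges)) {
        res$edges$sample_id <- s
        res$edges$sender_cluster <- snd
        res$edges$receiver_cluster <- rcv
        edges[[length(edges) + 1L]] <- res$edges
      }
      if (nrow(res$excluded)) {
        res$excluded$sample_id <- s
        res$excluded$sender_cluster <- snd
        res$excluded$receiver_cluster <- rcv
        excluded[[length(excluded) + 1L]] <- res$excluded
      }
    }
  }
  empty_e <- data.frame(ligand = character(), receptor = character(),
                        tf_module = character(), correlation = numeric(),
                        sample_id = character(), sender_cluster = character(),
                        receiver_cluster = character())
  net <- structure(list(
    edges = if (length(edges)) do.call(rbind, edges) else empty_e,
    excluded = if (length(excluded)) do.call(rbind, excluded) else
      data.frame(receptor = character(), reason = character()),
    config = config,
    seed = config$rng_seed
  ), class = "signaling_network")
  rownames(net$edges) <- NULL
  validate_network(net, regulons)
  net
}

# Hard assertion of the three emission rules on every produced network.
validate_network <- function(net, regulons = NULL) {
  e <- net$edges
  thr <- net$config$corr_threshold %||% 0.3
  if (nrow(e) && any(e$correlation <= thr))
    sl_stop("spotlink_internal_error", "edge emitted at r <= %s", format(thr))
  if (!is.null(regulons) && nrow(e)) {
    for (i in seq_len(nrow(e))) {
      reg <- regulons[[e$tf_module[i]]]
      if (!is.null(reg) && e$receptor[i] %in% reg$targets)
        sl_stop("spotlink_internal_error", "edge for receptor targeted by its TF module")
    }
  }
  invisible(net)
}

#' @export
print.signaling_network <- function(x, ...) {
  cat(sprintf("signaling_network: %d edge(s), %d exclusion record(s)\n",
              nrow(x$edges), nrow(x$excluded)))
  if (nrow(x$edges)) print(utils::head(x$edges, 10))
  invisible(x)
}

#' Score a reconstructed network against the planted truth
#'
#' Precision and recall at the (receptor, TF-module) level: an edge counts as
#' recovered when its (receptor, tf) pair matches a planted link, regardless
#' of sample or cluster-pair context.
#'
#' @param network a `signaling_network`.
#' @param truth a `synthetic_truth`.
#' @return list: `precision`, `recall`, `n_recovered`, `n_planted`,
#'   `n_reported`. An empty network yields precision NaN.
#' @export
score_network_recovery <- function(network, truth) {
  planted <- unique(paste(truth$planted_links$receptor, truth$planted_links$tf))
  reported <- unique(paste(network$edges$receptor, network$edges$tf_module))
  tp <- length(intersect(reported, planted))
  list(precision = if (length(reported)) tp / length(reported) else NaN,
       recall = if (length(planted)) tp / length(planted) else NaN,
       n_recovered = tp, n_planted = length(planted),
       n_reported = length(reported))
}
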