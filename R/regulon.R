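#' Co-expression importance of every gene for each TF
#'
#' For each transcription factor, scores every other expressed gene by the
#' absolute Spearman correlation between the TF's and the gene's normalized
#' expression across spots. The pipeline only requires a ranking of candidate
#' targets; rank correlation is a deterministic, assumption-light importance
#' for that purpose. An optional regression-forest refinement can be layered
#' on by the caller; the default is correlation only.
#'
#' When `sample_id` is supplied the correlation is computed within each
#' sample and pooled as the spot-weighted mean of the signed correlations
#' before taking the absolute value; this removes sample-level confounding
#' (group fold changes, per-sample depth and biological offsets) that would
#' otherwise dominate co-expression in a multi-sample cohort.
#'
#' @param norm_matrix genes x spots normalized matrix.
#' @param tf_list TF gene ids; TFs absent from the matrix are skipped with a
#'   warning.
#' @param seed unused by the correlation importance itself (kept so callers
#'   can treat every stage uniformly); recorded on the result.
#' @param sample_id optional per-spot sample labels for within-sample pooling.
#' @return named list: tf -> named numeric vector of importances over all
#'   other genes.
#' @export
coexpression_importance <- function(norm_matrix, tf_list, seed = 1L,
                                    sample_id = NULL) {
  tf_list <- unique(tf_list)
  missing <- setdiff(tf_list, rownames(norm_matrix))
  if (length(missing)) {
    warning(sprintf("TF(s) absent from the matrix, skipped: %s",
                    paste(missing, collapse = ", ")), call. = FALSE)
    tf_list <- setdiff(tf_list, missing)
  }
  if (!length(tf_list)) sl_validation_error("no TF from the list is present in the matrix")
  # Spearman = Pearson on within-gene ranks across spots
  spearman_block <- function(cols) {
    ranks <- t(apply(norm_matrix[, cols, drop = FALSE], 1, rank))
    suppressWarnings(r <- stats::cor(t(ranks[tf_list, , drop = FALSE]), t(ranks)))
    r[is.na(r)] <- 0
    r
  }
  if (is.null(sample_id)) {
    cm <- abs(spearman_block(seq_len(ncol(norm_matrix))))
  } else {
    if (length(sample_id) != ncol(norm_matrix))
      sl_validation_error("sample_id must have one entry per spot")
    acc <- 0
    for (s in unique(sample_id)) {
      cols <- which(sample_id == s)
      acc <- acc + spearman_block(cols) * length(cols)
    }
    cm <- abs(acc / ncol(norm_matrix))
  }
  out <- lapply(tf_list, function(tf) {
    v <- cm[tf, ]
    v[setdiff(names(v), tf)]
  })
  names(out) <- tf_list
  attr(out, "seed") <- seed
  out
}

#' Build TF regulatory modules from importances
#'
#' A candidate target joins a TF's module when its importance is strictly
#' above the TF's `importance_percentile` (default 95th) of candidate
#' importances — or, with `scope = "global"`, above that percentile of all
#' TF-gene importances pooled. An optional prior table (TF -> allowed
#' targets, the offline stand-in for motif-based pruning) then removes
#' non-listed targets. Modules with fewer than `min_module_genes` genes
#' (default 20) are excluded.
#'
#' @param importances output of [coexpression_importance()].
#' @param importance_percentile percentile in (0, 100).
#' @param min_module_genes module-size floor.
#' @param prior optional data.frame with columns `tf`, `target`.
#' @param scope `"per_tf"` or `"global"` percentile pooling.
#' @return list of `regulon` objects (`tf`, `targets`, `importance`,
#'   `cutoff`, `provenance`); empty list allowed.
#' @export
build_modules <- function(importances, importance_percentile = 95,
                          min_module_genes = 20, prior = NULL,
                          scope = c("per_tf", "global")) {
  scope <- match.arg(scope)
  if (importance_percentile <= 0 || importance_percentile >= 100)
    sl_parameter_error("importance_percentile must lie in (0, 100)")
  global_cut <- if (scope == "global")
    stats::quantile(unlist(importances), importance_percentile / 100, names = FALSE)
  else NA_real_
  prior_targets <- if (!is.null(prior)) split(prior$target, prior$tf) else NULL

  mods <- list()
  for (tf in names(importances)) {
    imp <- importances[[tf]]
    cut <- if (scope == "per_tf")
      stats::quantile(imp, importance_percentile / 100, names = FALSE) else global_cut
    sel <- imp[imp > cut]
    provenance <- "coexpression"
    if (!is.null(prior_targets)) {
      allowed <- prior_targets[[tf]] %||% character()
      sel <- sel[names(sel) %in% allowed]
      provenance <- "prior-pruned"
    }
    if (length(sel) < min_module_genes) next
    mods[[tf]] <- structure(list(
      tf = tf,
      targets = names(sel),
      importance = sel,
      cutoff = cut,
      provenance = provenance
    ), class = "regulon")
  }
  mods
}

#' Per-spot module activity by AUC of the gene-recovery curve
#'
#' For each spot, genes are ranked by descending normalized expression (ties
#' broken by one seeded random permutation fixed for the whole run). The
#' recovery curve of a module counts its genes among the top i ranks for
#' i = 1..k, k = `ceil(top_fraction * N)`; the activity score is the area
#' under that step curve divided by the maximal area achievable if all module
#' genes sat at the very top. Scores therefore lie in [0, 1]: 1 when the
#' module occupies the top ranks, 0 when no module gene enters the top k.
#'
#' @param norm_matrix genes x spots normalized matrix.
#' @param regulons list of `regulon` objects (or named list with `targets`).
#' @param top_fraction fraction of the ranked list integrated, in (0, 0.5].
#' @param seed seed for the tie-breaking permutation.
#' @return `activity_matrix`: regulons x spots numeric matrix in [0, 1].
#' @export
aucell_scores <- function(norm_matrix, regulons, top_fraction = 0.05, seed = 1L) {
  if (!length(regulons)) sl_validation_error("no regulons to score")
  if (top_fraction <= 0 || top_fraction > 0.5)
    sl_parameter_error("top_fraction must lie in (0, 0.5]")
  genes <- rownames(norm_matrix)
  n <- length(genes)
  k <- ceiling(top_fraction * n)
  tiebreak <- with_seed(seed, sample.int(n))

  module_idx <- lapply(regulons, function(r) {
    tg <- if (is.list(r)) r$targets else r
    idx <- match(tg, genes)
    if (anyNA(idx)) {
      warning(sprintf("module '%s': %d gene(s) absent from the matrix, scored over the rest",
                      if (is.list(r)) r$tf else "?", sum(is.na(idx))), call. = FALSE)
      idx <- idx[!is.na(idx)]
    }
    idx
  })
  mod_names <- names(regulons) %||% vapply(regulons, function(r) r$tf, "")
  max_area <- vapply(module_idx, function(idx) {
    m <- min(length(idx), k)
    m * k - m * (m - 1) / 2
  }, numeric(1))

  scores <- matrix(0, length(regulons), ncol(norm_matrix),
                   dimnames = list(mod_names, colnames(norm_matrix)))
  for (j in seq_len(ncol(norm_matrix))) {
    ord <- order(-norm_matrix[, j], tiebreak)
    rk <- integer(n); rk[ord] <- seq_len(n)
    for (mi in seq_along(module_idx)) {
      r <- rk[module_idx[[mi]]]
      r <- r[r <= k]
      # area under the step recovery curve: each hit at rank r contributes
      # one unit of height over ranks r..k
      scores[mi, j] <- if (max_area[mi] > 0) sum(k - r + 1) / max_area[mi] else 0
    }
  }
  structure(scores, class = c("activity_matrix", class(scores)))
}
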