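#' Remove low-quality spots
#'
#' Drops spots whose total UMI count falls below `min_counts` and any spot on
#' an explicit exclusion list (the stand-in for manually flagged necrotic or
#' folded-tissue regions).
#'
#' @param ds a `spot_dataset`.
#' @param min_counts total-count floor (>= 0).
#' @param exclude_spot_ids spot ids to drop regardless of counts.
#' @return filtered dataset with an attribute `removed` — a data.frame of
#'   removed spot ids and reasons.
#' @export
filter_low_quality_spots <- function(ds, min_counts = 250, exclude_spot_ids = character()) {
  if (min_counts < 0) sl_parameter_error("min_counts must be >= 0")
  totals <- Matrix::colSums(ds$counts)
  low <- totals < min_counts
  excl <- ds$spots$spot_id %in% exclude_spot_ids
  drop <- low | excl
  if (all(drop)) sl_validation_error("filtering removed every spot")
  removed <- data.frame(
    spot_id = ds$spots$spot_id[drop],
    reason = ifelse(excl[drop], "excluded", "low_counts"),
    total = totals[drop], stringsAsFactors = FALSE)
  out <- ds_subset(ds, spots = which(!drop))
  attr(out, "removed") <- removed
  out
}

#' Drop genes detected in too few spots
#'
#' A gene is retained iff the fraction of spots with count > 0 is at least
#' `min_spot_fraction`; strictly rarer genes are dropped. Default 0.025, i.e.
#' genes detected in fewer than 2.5% of spots are excluded.
#'
#' @param ds a `spot_dataset`.
#' @param min_spot_fraction detection-fraction floor in (0, 1).
#' @return dataset restricted to retained genes.
#' @export
filter_rare_genes <- function(ds, min_spot_fraction = 0.025) {
  if (min_spot_fraction <= 0 || min_spot_fraction >= 1)
    sl_parameter_error("min_spot_fraction must lie in (0, 1)")
  det <- Matrix::rowSums(ds$counts > 0) / ncol(ds$counts)
  keep <- det >= min_spot_fraction
  if (!any(keep)) sl_validation_error("rare-gene filter removed every gene")
  ds_subset(ds, genes = which(keep))
}

#' Log-CPM normalization
#'
#' `log2(1 + 1e4 * count / spot_total)` per entry — a depth-removing,
#' variance-stabilizing monotone scale for the rank- and correlation-based
#' statistics downstream.
#'
#' @param ds a `spot_dataset` (spots with zero totals must have been removed).
#' @return dense numeric matrix, genes x spots.
#' @export
normalize_logcpm <- function(ds) {
  totals <- Matrix::colSums(ds$counts)
  if (any(totals == 0))
    sl_stop("spotlink_internal_error",
            "zero-total spot(s) reached normalization: %s",
            paste(ds$spots$spot_id[totals == 0][1:min(3, sum(totals == 0))], collapse = ", "))
  m <- as.matrix(ds$counts)
  log2(1 + sweep(m, 2, 1e4 / totals, `*`))
}

#' Merge clusters into compartments
#'
#' Populates the compartment field from a cluster-to-compartment map (the
#' step that merges multiple expression clusters of one cell type into a
#' major category). Cluster labels are left untouched.
#'
#' @param ds a `spot_dataset` with clusters assigned.
#' @param map named character vector: cluster -> compartment
#'   (tumor/immune/CAF/other).
#' @return dataset with `compartment` populated.
#' @export
merge_compartments <- function(ds, map) {
  cl <- ds$spots$cluster
  if (anyNA(cl)) sl_validation_error("clusters must be assigned before merging")
  missing <- setdiff(unique(cl), names(map))
  if (length(missing))
    sl_validation_error("no compartment mapping for cluster(s): %s",
                        paste(missing, collapse = ", "))
  ds$spots$compartment <- unname(map[cl])
  validate_spot_dataset(ds)
  ds
}

#' Per-sample compartment proportions
#'
#' @param ds a `spot_dataset` with compartments assigned.
#' @return data.frame `sample_id, compartment, fraction`; fractions sum to 1
#'   within each sample.
#' @export
compartment_proportions <- function(ds) {
  comp <- ds$spots$compartment
  if (anyNA(comp)) sl_validation_error("compartments must be assigned")
  tab <- table(ds$spots$sample_id, comp)
  frac <- tab / rowSums(tab)
  out <- as.data.frame(frac, stringsAsFactors = FALSE)
  names(out) <- c("sample_id", "compartment", "fraction")
  out$sample_id <- as.character(out$sample_id)
  out$compartment <- as.character(out$compartment)
  out$fraction <- as.numeric(out$fraction)
  out
}

#' Build the spot neighbor graph
#'
#' Two spots are neighbors iff they belong to the same sample and their array
#' offsets are `(0, +-2)` or `(+-1, +-1)` — the six hex neighbors under the
#' Visium array convention. Cross-sample edges are never created.
#'
#' @param ds a `spot_dataset`.
#' @return a `neighbor_graph`: data.frame `edges` (columns `a`, `b`, spot
#'   indices with a < b) plus the spot table reference.
#' @export
build_neighbor_graph <- function(ds) {
  sp <- ds$spots
  if (any((sp$array_row + sp$array_col) %% 2L != 0L))
    sl_validation_error("coordinate parity violates the hex dialect")
  edges <- list(); k <- 0L
  for (s in unique(sp$sample_id)) {
    idx <- which(sp$sample_id == s)
    key <- sp$array_row[idx] * 1e4 + sp$array_col[idx]
    lookup <- structure(idx, names = key)
    offs <- rbind(c(0, 2), c(1, 1), c(1, -1))  # half the offsets: each edge once
    for (o in seq_len(nrow(offs))) {
      cand <- (sp$array_row[idx] + offs[o, 1]) * 1e4 + (sp$array_col[idx] + offs[o, 2])
      j <- lookup[as.character(cand)]
      ok <- !is.na(j)
      if (any(ok)) {
        k <- k + 1L
        edges[[k]] <- cbind(a = idx[ok], b = unname(j[ok]))
      }
    }
  }
  e <- if (k) as.data.frame(do.call(rbind, edges)) else data.frame(a = integer(), b = integer())
  swap <- e$a > e$b
  tmp <- e$a[swap]; e$a[swap] <- e$b[swap]; e$b[swap] <- tmp
  e <- e[order(e$a, e$b), , drop = FALSE]
  rownames(e) <- NULL
  structure(list(edges = e, spots = sp), class = "neighbor_graph")
}

#' Count boundary edges between clusters
#'
#' @param g a `neighbor_graph` over a dataset with clusters assigned.
#' @return data.frame `cluster_a, cluster_b, n_edges` (unordered pairs,
#'   cluster_a < cluster_b), including within-cluster counts on the diagonal
#'   rows where cluster_a == cluster_b.
#' @export
cluster_contact_counts <- function(g) {
  cl <- g$spots$cluster
  if (anyNA(cl)) sl_validation_error("clusters must be assigned")
  ca <- cl[g$edges$a]; cb <- cl[g$edges$b]
  lo <- pmin(ca, cb); hi <- pmax(ca, cb)
  tab <- table(paste(lo, hi, sep = "\r"))
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  data.frame(cluster_a = vapply(parts, `[`, "", 1),
             cluster_b = vapply(parts, `[`, "", 2),
             n_edges = as.integer(tab), stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Spatially adjacent cluster pairs
#'
#' An unordered pair of distinct clusters counts as "in direct contact" when
#' at least `min_contact_edges` spot-neighbor edges cross their boundary.
#'
#' @param g a `neighbor_graph`.
#' @param min_contact_edges boundary-edge floor.
#' @return data.frame `cluster_a, cluster_b, n_edges` of qualifying pairs.
#' @export
adjacent_cluster_pairs <- function(g, min_contact_edges = 10) {
  cc <- cluster_contact_counts(g)
  cc <- cc[cc$cluster_a != cc$cluster_b & cc$n_edges >= min_contact_edges, , drop = FALSE]
  rownames(cc) <- NULL
  cc
}

#' Restrict a dataset to the spots of given clusters
#'
#' The gene universe is unchanged; only spots are subset (region definition
#' ahead of the signaling analysis).
#'
#' @param ds a `spot_dataset` with clusters assigned.
#' @param clusters non-empty character vector of cluster labels.
#' @return the spot-subset dataset.
#' @export
subset_region <- function(ds, clusters) {
  if (!length(clusters)) sl_validation_error("empty cluster subset")
  unknown <- setdiff(clusters, unique(ds$spots$cluster))
  if (length(unknown))
    sl_validation_error("unknown cluster(s): %s", paste(unknown, collapse = ", "))
  ds_subset(ds, spots = which(ds$spots$cluster %in% clusters))
}

#' PCA + k-means fallback clustering
#'
#' A label-free smoke-test utility only: spots are clustered by k-means on
#' the top principal components of the normalized matrix. Real analyses are
#' expected to supply reviewed cluster labels.
#'
#' @param ds a `spot_dataset`.
#' @param k number of clusters.
#' @param n_pcs principal components to keep.
#' @param seed RNG seed for k-means starts.
#' @return the dataset with `cluster` set to "C1"... "Ck".
#' @export
fallback_cluster <- function(ds, k = 5, n_pcs = 15, seed = 1L) {
  norm <- normalize_logcpm(ds)
  v <- apply(norm, 1, stats::var)
  top <- order(v, decreasing = TRUE)[seq_len(min(500, nrow(norm)))]
  pcs <- stats::prcomp(t(norm[top, , drop = FALSE]), rank. = min(n_pcs, length(top) - 1))$x
  km <- with_seed(seed, stats::kmeans(pcs, centers = k, nstart = 5))
  ds$spots$cluster <- paste0("C", km$cluster)
  ds
}
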