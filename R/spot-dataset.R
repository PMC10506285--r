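#' Spot-level spatial expression dataset
#'
#' The container every stage consumes: a genes x spots count matrix plus a
#' per-spot table of array coordinates (Visium convention: `array_row` in
#' 0..77, `array_col` in 0..127, row/col parity matched so the hex lattice is
#' well formed), the sample each spot belongs to, the sample-level response
#' group, and optional cluster / compartment annotations.
#'
#' @param counts non-negative integer matrix (base or `Matrix` sparse),
#'   genes x spots. Dimnames, when present, must agree with `gene_ids` /
#'   `spot_ids`.
#' @param gene_ids unique gene symbols (rows).
#' @param spot_ids unique spot barcodes (columns).
#' @param array_row,array_col integer hex-array coordinates per spot.
#' @param sample_id sample label per spot.
#' @param group response-group label per spot; all spots of one sample must
#'   share one group.
#' @param cluster optional cluster label per spot.
#' @param compartment optional compartment per spot; values outside
#'   tumor/immune/CAF/other are rejected.
#'
#' @return a `spot_dataset` object.
#' @export
spot_dataset <- function(counts, gene_ids, spot_ids, array_row, array_col,
                         sample_id, group, cluster = NULL, compartment = NULL) {
  counts <- methods::as(counts, "CsparseMatrix")
  gene_ids <- as.character(gene_ids)
  spot_ids <- as.character(spot_ids)
  spots <- data.frame(
    spot_id = spot_ids,
    array_row = as.integer(array_row),
    array_col = as.integer(array_col),
    sample_id = as.character(sample_id),
    group = as.character(group),
    cluster = if (is.null(cluster)) NA_character_ else as.character(cluster),
    compartment = if (is.null(compartment)) NA_character_ else as.character(compartment),
    stringsAsFactors = FALSE
  )
  rownames(counts) <- gene_ids
  colnames(counts) <- spot_ids
  obj <- structure(list(counts = counts, spots = spots), class = "spot_dataset")
  validate_spot_dataset(obj)
}

#' Validate a spot_dataset's invariants
#'
#' @param ds a `spot_dataset`.
#' @return `ds` invisibly on success; a validation error otherwise.
#' @export
validate_spot_dataset <- function(ds) {
  counts <- ds$counts; spots <- ds$spots
  if (nrow(spots) != ncol(counts))
    sl_validation_error("spot table has %d rows but counts has %d columns",
                        nrow(spots), ncol(counts))
  if (anyDuplicated(rownames(counts)))
    sl_validation_error("duplicate gene_ids: %s",
                        paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  if (anyDuplicated(spots$spot_id))
    sl_validation_error("duplicate spot_ids: %s",
                        paste(unique(spots$spot_id[duplicated(spots$spot_id)]), collapse = ", "))
  if (any(counts@x < 0)) sl_validation_error("counts contain negative entries")
  if (anyNA(spots$array_row) || anyNA(spots$array_col))
    sl_validation_error("every spot needs array coordinates")
  parity <- (spots$array_row + spots$array_col) %% 2L
  if (length(parity) && any(parity != 0L))
    sl_validation_error("hex dialect violated: array_row + array_col must be even for all spots")
  grp <- unique(spots[, c("sample_id", "group")])
  dup <- grp$sample_id[duplicated(grp$sample_id)]
  if (length(dup))
    sl_validation_error("sample(s) with more than one group label: %s",
                        paste(unique(dup), collapse = ", "))
  comp <- spots$compartment[!is.na(spots$compartment)]
  bad <- setdiff(unique(comp), c("tumor", "immune", "CAF", "other"))
  if (length(bad))
    sl_validation_error("unknown compartment label(s): %s", paste(bad, collapse = ", "))
  invisible(ds)
}

#' @export
print.spot_dataset <- function(x, ...) {
  cat(sprintf("spot_dataset: %d genes x %d spots, %d sample(s)\n",
              nrow(x$counts), ncol(x$counts), length(unique(x$spots$sample_id))))
  if (!all(is.na(x$spots$cluster)))
    cat("  clusters:", paste(sort(unique(x$spots$cluster)), collapse = ", "), "\n")
  if (!all(is.na(x$spots$compartment)))
    cat("  compartments:", paste(sort(unique(x$spots$compartment)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spot_dataset <- function(x) dim(x$counts)

#' Subset a spot_dataset by gene and/or spot index
#'
#' Internal helper: logical/integer/character indices; keeps counts and the
#' spot table aligned.
#' @noRd
ds_subset <- function(ds, genes = NULL, spots = NULL) {
  counts <- ds$counts
  tab <- ds$spots
  if (!is.null(genes)) counts <- counts[genes, , drop = FALSE]
  if (!is.null(spots)) {
    counts <- counts[, spots, drop = FALSE]
    if (is.character(spots)) spots <- match(spots, tab$spot_id)
    tab <- tab[spots, , drop = FALSE]
    rownames(tab) <- NULL
  }
  structure(list(counts = counts, spots = tab), class = "spot_dataset")
}
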