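#' Per-spot gene-signature module scores
#'
#' The score of a signature in a spot is the arithmetic mean of the
#' normalized expression of the signature genes present in the matrix — the
#' "averaged expression of the set" convention. An opt-in background-corrected
#' variant subtracts the mean of an expression-bin-matched control set
#' (24 bins over mean expression, controls drawn with a seed).
#'
#' @param norm_matrix genes x spots normalized matrix.
#' @param sets named list of gene id vectors; sets with no gene present are
#'   skipped with a warning.
#' @param background_correct subtract a bin-matched control-set mean.
#' @param n_bins,n_ctrl bins and controls per gene for the corrected variant.
#' @param seed seed for control draws.
#' @return `signature_score_table`: signatures x spots matrix.
#' @export
module_score <- function(norm_matrix, sets, background_correct = FALSE,
                         n_bins = 24, n_ctrl = 100, seed = 1L) {
  present <- lapply(sets, function(s) intersect(s, rownames(norm_matrix)))
  empty <- names(sets)[lengths(present) == 0]
  if (length(empty)) {
    warning(sprintf("signature(s) with no gene in the matrix, skipped: %s",
                    paste(empty, collapse = ", ")), call. = FALSE)
    present <- present[lengths(present) > 0]
  }
  if (!length(present)) sl_validation_error("no scorable signature")
  scores <- t(vapply(present, function(g)
    colMeans(norm_matrix[g, , drop = FALSE]), numeric(ncol(norm_matrix))))
  rownames(scores) <- names(present)
  if (background_correct) {
    avg <- rowMeans(norm_matrix)
    bins <- cut(rank(avg, ties.method = "first"), breaks = n_bins, labels = FALSE)
    ctrl_means <- with_seed(seed, t(vapply(present, function(g) {
      ctrl <- unlist(lapply(g, function(gene) {
        pool <- setdiff(rownames(norm_matrix)[bins == bins[match(gene, rownames(norm_matrix))]], g)
        if (!length(pool)) return(character())
        sample(pool, min(n_ctrl, length(pool)))
      }))
      if (!length(ctrl)) return(numeric(ncol(norm_matrix)))
      colMeans(norm_matrix[ctrl, , drop = FALSE])
    }, numeric(ncol(norm_matrix)))))
    scores <- scores - ctrl_means
  }
  structure(scores, class = c("signature_score_table", class(scores)))
}

#' Contrast signature scores between two spot regions
#'
#' Two-sided Wilcoxon rank-sum test per signature between disjoint regions,
#' BH-adjusted across signatures, with the median score difference
#' (region A minus region B).
#'
#' @param scores signatures x spots score matrix.
#' @param region_a_spots,region_b_spots disjoint spot-id vectors, each with
#'   at least 10 spots.
#' @return data.frame `signature, median_diff, pvalue, padj`.
#' @export
compare_regions <- function(scores, region_a_spots, region_b_spots) {
  if (length(intersect(region_a_spots, region_b_spots)))
    sl_validation_error("regions overlap in %d spot(s)",
                        length(intersect(region_a_spots, region_b_spots)))
  if (length(region_a_spots) < 10L || length(region_b_spots) < 10L)
    sl_validation_error("each region needs >= 10 spots")
  res <- lapply(rownames(scores), function(sig) {
    a <- scores[sig, region_a_spots]; b <- scores[sig, region_b_spots]
    # exact tail for small tie-free samples, normal approximation otherwise
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
    data.frame(signature = sig,
               median_diff = stats::median(a) - stats::median(b),
               pvalue = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  rownames(out) <- NULL
  out
}

#' Spearman correlation of signature-gene expression with cell proportions
#'
#' For each signature gene and each cell type, the Spearman rank correlation
#' (average ranks on ties) across the samples common to the expression and
#' proportion tables, with two-sided p-values from the t approximation.
#'
#' @param expr samples x genes expression table (matrix or data.frame with
#'   sample row names).
#' @param proportions samples x cell-type table.
#' @param signature gene ids to correlate; genes absent from `expr` are
#'   dropped with a warning.
#' @return list: `rho` and `pvalue`, gene x cell-type matrices; attribute
#'   `n_samples`.
#' @export
signature_proportion_correlation <- function(expr, proportions, signature) {
  expr <- as.matrix(expr); proportions <- as.matrix(proportions)
  common <- intersect(rownames(expr), rownames(proportions))
  if (length(common) < 5L)
    sl_validation_error("only %d common sample(s); need >= 5", length(common))
  genes <- intersect(signature, colnames(expr))
  if (!length(genes)) sl_validation_error("no signature gene present in expr")
  if (length(genes) < length(signature))
    warning(sprintf("%d signature gene(s) absent from expr",
                    length(signature) - length(genes)), call. = FALSE)
  e <- expr[common, genes, drop = FALSE]
  p <- proportions[common, , drop = FALSE]
  n <- length(common)
  suppressWarnings(rho <- stats::cor(e, p, method = "spearman"))
  tstat <- rho * sqrt((n - 2) / pmax(1 - rho^2, .Machine$double.eps))
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval[is.na(rho)] <- NA
  structure(list(rho = rho, pvalue = pval), n_samples = n)
}

#' Packaged cancer stem-cell signature
#'
#' Loads the published CSC (cancer stem cell) marker compilation shipped with
#' the package. Two printed symbols ("SP", "YY1A1") are not standard HGNC
#' gene symbols and one ("NOTCH") names a family rather than a gene; they are
#' retained in the file for fidelity to the published list but excluded from
#' scoring by default, with a warning naming them.
#'
#' @param include_ambiguous keep the non-standard symbols.
#' @return character vector of gene symbols.
#' @export
csc_signature <- function(include_ambiguous = FALSE) {
  path <- system.file("extdata", "csc_signature.gmt", package = "spotlink")
  genes <- read_gmt(path)[["CSC_SIGNATURE"]]
  ambiguous <- c("SP", "YY1A1", "NOTCH")
  if (!include_ambiguous) {
    warning(sprintf("excluding non-standard symbol(s) from the CSC signature: %s",
                    paste(intersect(ambiguous, genes), collapse = ", ")),
            call. = FALSE)
    genes <- setdiff(genes, ambiguous)
  }
  genes
}
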