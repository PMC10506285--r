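# Enrichment score by the weighted running-sum statistic (weight exponent 1):
# genes sorted by score descending; a hit advances the sum by
# |score|^w / sum(|score| over set members), a miss retreats by 1/(N - m);
# the ES is the extremum of largest absolute value.
running_sum_es <- function(sorted_scores, is_hit, weight = 1) {
  n <- length(sorted_scores)
  m <- sum(is_hit)
  w <- abs(sorted_scores)^weight
  nr <- sum(w[is_hit])
  inc <- numeric(n)
  if (nr > 0) inc[is_hit] <- w[is_hit] / nr else inc[is_hit] <- 1 / m
  inc[!is_hit] <- -1 / (n - m)
  rs <- cumsum(inc)
  mx <- max(rs); mn <- min(rs)
  # extremum of largest magnitude; a (near-)tie resolves to the positive side
  if (mx + mn >= -1e-12) mx else mn
}

#' Preranked gene-set enrichment analysis
#'
#' The classic weighted Kolmogorov-Smirnov running-sum statistic on a ranked
#' gene list (genes sorted by score descending, ties broken by gene id), with
#' a gene-label permutation null: each permutation rescores a random set of
#' the same size. NES divides the ES by the mean |null ES| of matching sign;
#' p-values and FDR q-values come from the signed null pools. Sets with fewer
#' than `min_size` genes present in the ranking are skipped with a warning.
#'
#' @param ranking named numeric vector, gene -> score (typically the DE log2
#'   fold change); no NAs.
#' @param sets a gene-set collection (named list of gene id vectors).
#' @param n_perm permutations for the null (default 1000).
#' @param seed RNG seed for the permutations.
#' @param weight running-sum weight exponent (1 = classic weighted).
#' @param min_size minimum genes of a set present in the ranking.
#' @return an `enrichment_result` data.frame: `set, size, es, nes, pvalue,
#'   fdr, leading_edge` (list-column).
#' @export
preranked_gsea <- function(ranking, sets, n_perm = 1000, seed = 1L,
                           weight = 1, min_size = 5L) {
  if (anyNA(ranking)) sl_validation_error("ranking contains NA scores")
  if (is.null(names(ranking)) || anyDuplicated(names(ranking)))
    sl_validation_error("ranking must be uniquely named by gene")
  ord <- order(-ranking, names(ranking))
  genes <- names(ranking)[ord]
  scores <- unname(ranking[ord])
  n <- length(genes)

  present <- lapply(sets, function(s) unique(s[s %in% genes]))
  sizes <- lengths(present)
  skipped <- names(sets)[sizes < min_size]
  if (length(skipped))
    warning(sprintf("skipping %d set(s) with < %d genes in the ranking: %s",
                    length(skipped), min_size,
                    paste(utils::head(skipped, 5), collapse = ", ")), call. = FALSE)
  keep <- names(sets)[sizes >= min_size]
  if (!length(keep))
    return(empty_enrichment())

  es_obs <- vapply(keep, function(nm) {
    running_sum_es(scores, genes %in% present[[nm]], weight)
  }, numeric(1))

  # permutation null per distinct set size (gene-label permutation)
  null_by_size <- with_seed(seed, {
    lapply(stats::setNames(nm = unique(sizes[keep])), function(m) {
      vapply(seq_len(n_perm), function(b) {
        hit <- logical(n)
        hit[sample.int(n, m)] <- TRUE
        running_sum_es(scores, hit, weight)
      }, numeric(1))
    })
  })

  res <- lapply(keep, function(nm) {
    m <- sizes[[nm]]
    null <- null_by_size[[as.character(m)]]
    es <- es_obs[[nm]]
    pool <- if (es >= 0) null[null >= 0] else null[null < 0]
    if (length(pool)) {
      p <- (1 + sum(abs(pool) >= abs(es))) / (1 + length(pool))
      nes <- es / mean(abs(pool))
    } else {
      p <- 1 / (n_perm + 1)
      nes <- NaN
    }
    le <- leading_edge(scores, genes, present[[nm]], weight)
    data.frame(set = nm, size = m, es = es, nes = nes, pvalue = p,
               fdr = NA_real_, stringsAsFactors = FALSE,
               leading_edge = I(list(le)))
  })
  out <- do.call(rbind, res)

  # permutation FDR: for each observed NES, the fraction of pooled null NES
  # at least as extreme (same sign), divided by the analogous observed
  # fraction, clipped to [0, 1]
  null_nes <- unlist(lapply(keep, function(nm) {
    null <- null_by_size[[as.character(sizes[[nm]])]]
    pos <- null[null >= 0]; neg <- null[null < 0]
    c(if (length(pos)) pos / mean(pos) else numeric(),
      if (length(neg)) neg / mean(abs(neg)) else numeric())
  }))
  for (i in seq_len(nrow(out))) {
    nes <- out$nes[i]
    if (!is.finite(nes)) { out$fdr[i] <- NA_real_; next }
    if (nes >= 0) {
      num <- mean(null_nes[null_nes >= 0] >= nes)
      den <- mean(out$nes[out$nes >= 0] >= nes)
    } else {
      num <- mean(null_nes[null_nes < 0] <= nes)
      den <- mean(out$nes[out$nes < 0] <= nes)
    }
    out$fdr[i] <- min(1, ifelse(den > 0, num / den, 1))
  }
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  class(out) <- c("enrichment_result", "data.frame")
  out
}

leading_edge <- function(scores, genes, set, weight) {
  is_hit <- genes %in% set
  n <- length(genes); m <- sum(is_hit)
  w <- abs(scores)^weight
  nr <- sum(w[is_hit])
  inc <- numeric(n)
  if (nr > 0) inc[is_hit] <- w[is_hit] / nr else inc[is_hit] <- 1 / m
  inc[!is_hit] <- -1 / (n - m)
  rs <- cumsum(inc)
  peak <- which.max(abs(rs))
  if (rs[peak] >= 0) genes[seq_len(peak)][is_hit[seq_len(peak)]]
  else genes[peak:n][is_hit[peak:n]]
}

empty_enrichment <- function() {
  out <- data.frame(set = character(), size = integer(), es = numeric(),
                    nes = numeric(), pvalue = numeric(), fdr = numeric(),
                    stringsAsFactors = FALSE)
  out$leading_edge <- I(list())
  class(out) <- c("enrichment_result", "data.frame")
  out
}

#' Rank an enrichment result for reporting
#'
#' Orders sets by NES descending (positive NES = enriched toward the top of
#' the ranking, i.e. group A); ties broken by set name.
#'
#' @param results an `enrichment_result`.
#' @return the reordered table.
#' @export
hallmark_summary <- function(results) {
  if (!nrow(results)) return(results)
  ord <- order(-results$nes, results$set)
  out <- results[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
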