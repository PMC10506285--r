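#' Pseudo-bulk aggregation of a compartment
#'
#' Sums raw spot counts per sample over the spots of one compartment,
#' producing bulk-like libraries for group comparison. Samples with no spot
#' in the compartment are dropped with a warning; a group left with fewer
#' than two samples is an error, since no between-sample inference is then
#' possible.
#'
#' @param ds a `spot_dataset` with compartments assigned.
#' @param compartment compartment to aggregate (e.g. "tumor").
#' @return list: `counts` (genes x samples integer matrix), `groups` (named
#'   by sample).
#' @export
pseudobulk <- function(ds, compartment) {
  comp <- ds$spots$compartment
  if (anyNA(comp)) sl_validation_error("compartments must be assigned")
  if (!compartment %in% comp)
    sl_validation_error("compartment '%s' has no spots", compartment)
  keep <- comp == compartment
  samples <- unique(ds$spots$sample_id)
  sub <- ds$counts[, keep, drop = FALSE]
  fac <- factor(ds$spots$sample_id[keep], levels = samples)
  agg <- sapply(levels(fac), function(s)
    Matrix::rowSums(sub[, fac == s, drop = FALSE]))
  agg <- as.matrix(agg)
  empty <- colSums(agg) == 0 | !(samples %in% ds$spots$sample_id[keep])
  if (any(empty)) {
    warning(sprintf("dropping sample(s) with no %s spots: %s", compartment,
                    paste(samples[empty], collapse = ", ")), call. = FALSE)
    agg <- agg[, !empty, drop = FALSE]
  }
  grp_tab <- unique(ds$spots[, c("sample_id", "group")])
  groups <- stats::setNames(grp_tab$group, grp_tab$sample_id)[colnames(agg)]
  if (any(table(groups) < 2L))
    sl_validation_error("a group has < 2 pseudo-bulk samples in compartment '%s'",
                        compartment)
  list(counts = agg, groups = groups)
}

# Median-of-ratios size factors: the reference is the per-gene geometric mean
# over samples, computed over genes with no zero count in any sample.
size_factors_mor <- function(counts) {
  if (any(colSums(counts) == 0))
    sl_validation_error("degenerate all-zero library: %s",
                        paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  pos <- rowSums(counts == 0) == 0
  if (sum(pos) < 10)
    sl_validation_error("too few all-nonzero genes (%d) for size-factor estimation", sum(pos))
  logc <- log(counts[pos, , drop = FALSE])
  ref <- rowMeans(logc)
  sf <- apply(logc, 2, function(x) exp(stats::median(x - ref)))
  sf / exp(mean(log(sf)))
}

# Per-gene NB dispersion: method of moments on size-factor-normalized counts
# using pooled within-group mean/variance so group effects do not inflate the
# estimate, floored, then shrunk on the log scale toward a fitted
# a0 + a1/mean dispersion-mean trend. raw_weight = 0.25: with cohort-scale
# sample numbers the raw moment estimate has ~10 df and carrying more of it
# into the Wald SE visibly inflates type-I error; three quarters of the
# weight therefore goes to the trend (fitted across all genes).
estimate_dispersions <- function(counts, sf, groups, floor = 1e-8,
                                 raw_weight = 0.25) {
  y <- sweep(counts, 2, sf, `/`)
  xim <- mean(1 / sf)
  glv <- unique(groups)
  mu <- rowMeans(y)
  ss <- 0; df <- 0
  for (g in glv) {
    j <- groups == g
    mg <- rowMeans(y[, j, drop = FALSE])
    ss <- ss + rowSums((y[, j, drop = FALSE] - mg)^2)
    df <- df + sum(j) - 1L
  }
  v <- ss / df
  raw <- pmax((v - mu * xim) / mu^2, floor)
  # gamma-ish trend fit on genes with informative estimates
  use <- mu > 1 & raw > floor * 10
  if (sum(use) >= 20) {
    fit <- stats::lm(raw[use] ~ I(1 / mu[use]))
    a0 <- max(unname(stats::coef(fit)[1]), 1e-6)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
    trend <- pmax(a0 + a1 / mu, floor)
  } else {
    trend <- rep(max(stats::median(raw), floor), length(raw))
  }
  final <- exp(raw_weight * log(pmax(raw, floor)) + (1 - raw_weight) * log(trend))
  list(raw = raw, trend = trend, final = pmax(final, floor), mu = mu)
}

# Wald test per gene at fixed dispersion: NB GLM with log link,
# counts ~ group with log size-factor offset.
nb_wald_gene <- function(k, x_a, off, alpha) {
  if (all(k == 0)) return(c(lfc = 0, se = NA_real_, stat = 0, p = 1))
  fit <- tryCatch(
    suppressWarnings(stats::glm(k ~ x_a + offset(off),
                                family = MASS::negative.binomial(theta = 1 / alpha))),
    error = function(e) NULL)
  if (!is.null(fit) && fit$converged && abs(stats::coef(fit)[2]) < 20) {
    # dispersion = 1: standard errors from the NB variance at the fixed
    # alpha, not a Pearson-estimated quasi-dispersion factor
    sm <- summary(fit, dispersion = 1)$coefficients
    est <- sm[2, 1]; se <- sm[2, 2]
  } else {
    # fallback for separations (a group all zero): moment estimate with a
    # 0.5 continuity correction and a delta-method standard error
    ya <- k[x_a == 1] / exp(off[x_a == 1]); yb <- k[x_a == 0] / exp(off[x_a == 0])
    est <- log(mean(ya) + 0.5) - log(mean(yb) + 0.5)
    se <- sqrt((alpha + 1 / (mean(ya) + 0.5)) / length(ya) +
               (alpha + 1 / (mean(yb) + 0.5)) / length(yb))
  }
  stat <- est / se
  c(lfc = est / log(2), se = se / log(2), stat = stat,
    p = 2 * stats::pnorm(-abs(stat)))
}

#' Negative-binomial Wald differential expression on pseudo-bulk counts
#'
#' The full pipeline: median-of-ratios size factors, pooled-within-group
#' moment dispersions shrunk toward a mean-dispersion trend, a per-gene NB
#' GLM (log link, group coefficient, size-factor offset) at the fixed final
#' dispersion, a two-sided normal Wald p-value and BH adjustment. Log2 fold
#' changes are group A over group B, where group A is `levels[1]` (default:
#' the first group encountered).
#'
#' @param counts genes x samples non-negative integer matrix.
#' @param groups character/factor of length ncol(counts); exactly 2 levels.
#' @param levels optional length-2 group ordering: c(A, B).
#' @param config a [spotlink_config()] supplying the DE call thresholds.
#' @return a `de_result` data.frame: `gene, base_mean, log2fc, se, stat,
#'   pvalue, padj, flag`, ordered by pvalue (ties by |stat| then gene).
#' @export
nb_wald_test <- function(counts, groups, levels = NULL, config = spotlink_config()) {
  groups <- as.character(groups)
  lv <- levels %||% unique(groups)
  if (length(lv) != 2L || !setequal(lv, unique(groups)))
    sl_validation_error("exactly two groups required; got %s",
                        paste(unique(groups), collapse = ", "))
  if (any(table(groups) < 2L))
    sl_validation_error("each group needs >= 2 samples")
  counts <- as.matrix(counts)
  if (any(counts < 0) || any(counts != round(counts)))
    sl_validation_error("pseudo-bulk counts must be non-negative integers")

  sf <- size_factors_mor(counts)
  disp <- estimate_dispersions(counts, sf, groups)
  x_a <- as.numeric(groups == lv[1])
  off <- log(sf)

  res <- t(vapply(seq_len(nrow(counts)), function(i)
    nb_wald_gene(counts[i, ], x_a, off, disp$final[i]),
    c(lfc = 0, se = 0, stat = 0, p = 0)))

  out <- data.frame(
    gene = rownames(counts),
    base_mean = disp$mu,
    log2fc = res[, "lfc"],
    se = res[, "se"],
    stat = res[, "stat"],
    pvalue = res[, "p"],
    stringsAsFactors = FALSE, row.names = NULL)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out <- classify_de(out, config)
  ord <- order(out$pvalue, -abs(out$stat), out$gene)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "size_factors") <- sf
  attr(out, "dispersions") <- disp$final
  attr(out, "group_a") <- lv[1]
  class(out) <- c("de_result", "data.frame")
  out
}

#' Flag differentially expressed genes
#'
#' `up_A` iff `log2fc >= lfc_threshold` and `padj <= padj_threshold`; `up_B`
#' symmetric; `ns` otherwise. Defaults: |log2FC| >= 2 and BH-adjusted
#' p <= 0.01.
#'
#' @param res a data.frame with `log2fc` and `padj`.
#' @param config a [spotlink_config()].
#' @return `res` with a `flag` column; attribute `summary` holds the up
#'   counts per direction.
#' @export
classify_de <- function(res, config = spotlink_config()) {
  sig <- !is.na(res$padj) & res$padj <= config$padj_threshold
  res$flag <- ifelse(sig & res$log2fc >= config$lfc_threshold, "up_A",
              ifelse(sig & res$log2fc <= -config$lfc_threshold, "up_B", "ns"))
  attr(res, "summary") <- c(n_up_A = sum(res$flag == "up_A"),
                            n_up_B = sum(res$flag == "up_B"))
  res
}
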