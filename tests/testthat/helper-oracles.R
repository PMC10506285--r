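# Independent brute-force oracles. Each re-derives its quantity by direct
# enumeration, sharing no code path with the package implementation.

# AUC of the gene-recovery curve: walk the ranking position by position,
# counting module genes seen so far; the area is the sum of those counts over
# the first k positions, normalized by the best achievable ranking.
brute_aucell <- function(ranked_genes, module, top_fraction) {
  n <- length(ranked_genes)
  k <- ceiling(top_fraction * n)
  m <- length(intersect(module, ranked_genes))
  area <- 0; seen <- 0
  for (i in seq_len(k)) {
    if (ranked_genes[i] %in% module) seen <- seen + 1
    area <- area + seen
  }
  best <- 0; seen <- 0
  for (i in seq_len(k)) {
    if (i <= m) seen <- seen + 1
    best <- best + seen
  }
  if (best == 0) 0 else area / best
}

# Enrichment score by explicit step-by-step walk of the running sum.
brute_es <- function(sorted_scores, hit, weight = 1) {
  n <- length(sorted_scores)
  nr <- sum(abs(sorted_scores[hit])^weight)
  m <- sum(hit)
  rs <- 0; mx <- -Inf; mn <- Inf
  for (i in seq_len(n)) {
    rs <- rs + if (hit[i]) {
      if (nr > 0) abs(sorted_scores[i])^weight / nr else 1 / m
    } else -1 / (n - m)
    if (rs > mx) mx <- rs
    if (rs < mn) mn <- rs
  }
  # same tie rule as the package: near-ties resolve to the positive extremum
  if (mx + mn >= -1e-12) mx else mn
}

# Hex neighbors by O(n^2) pair scan over the dialect's offset set.
brute_neighbor_edges <- function(spots) {
  edges <- list()
  n <- nrow(spots)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    if (spots$sample_id[i] != spots$sample_id[j]) next
    dr <- abs(spots$array_row[i] - spots$array_row[j])
    dc <- abs(spots$array_col[i] - spots$array_col[j])
    if ((dr == 0 && dc == 2) || (dr == 1 && dc == 1))
      edges[[length(edges) + 1L]] <- c(i, j)
  }
  if (!length(edges)) return(data.frame(a = integer(), b = integer()))
  e <- as.data.frame(do.call(rbind, edges)); names(e) <- c("a", "b")
  e[order(e$a, e$b), ]
}

# Benjamini-Hochberg by the literal step-up procedure.
brute_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  for (i in (n - 1):1) adj[i] <- min(adj[i], adj[i + 1])
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# Spearman rho with average ranks on ties, from the Pearson formula applied
# to hand-computed ranks.
brute_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
}

# Small hand-built dataset: hex-valid coordinates, optional clusters.
toy_dataset <- function(counts, sample_id = NULL, cluster = NULL, group = NULL) {
  n <- ncol(counts)
  coords <- hex_grid_coords(n)
  spot_dataset(
    counts = counts,
    gene_ids = rownames(counts) %||% paste0("G", seq_len(nrow(counts))),
    spot_ids = colnames(counts) %||% paste0("spot", seq_len(n)),
    array_row = coords$row, array_col = coords$col,
    sample_id = sample_id %||% rep("S1", n),
    group = group %||% rep("g1", n),
    cluster = cluster
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# n valid hex coordinates laid out row-major on a wide patch.
hex_grid_coords <- function(n, width = 20L) {
  row <- (seq_len(n) - 1L) %/% width
  pos <- (seq_len(n) - 1L) %% width
  col <- 2L * pos + (row %% 2L)
  list(row = row, col = col)
}

rand_counts <- function(n_genes, n_spots, lambda = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(stats::rpois(n_genes * n_spots, lambda), n_genes,
                dimnames = list(paste0("G", seq_len(n_genes)),
                                paste0("spot", seq_len(n_spots))))
    m
  })
}
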