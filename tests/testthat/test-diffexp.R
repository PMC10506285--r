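# Small deterministic pseudo-bulk cohort for the structural tests.
toy_pseudobulk <- function(n_genes = 80, n_per_group = 3, seed = 13,
                           lfc_genes = NULL, lfc = 0) {
  withr::with_seed(seed, {
    mu <- stats::rlnorm(n_genes, log(200), 1)
    counts <- sapply(seq_len(2 * n_per_group), function(j)
      stats::rnbinom(n_genes, mu = mu, size = 1 / 0.05))
    rownames(counts) <- paste0("G", seq_len(n_genes))
    colnames(counts) <- paste0("S", seq_len(2 * n_per_group))
    if (!is.null(lfc_genes)) {
      a_cols <- seq_len(n_per_group)
      counts[lfc_genes, a_cols] <-
        stats::rnbinom(length(lfc_genes) * n_per_group,
                       mu = mu[match(lfc_genes, rownames(counts))] * 2^lfc,
                       size = 1 / 0.05)
    }
    list(counts = counts,
         groups = rep(c("A", "B"), each = n_per_group))
  })
}

test_that("pseudobulk sums raw counts per sample and compartment", {
  counts <- matrix(c(3, 1, 4, 2, 5, 7, 6, 8), nrow = 2,
                   dimnames = list(c("G1", "G2"), paste0("s", 1:4)))
  ds <- toy_dataset(counts,
                    sample_id = c("P1", "P1", "P2", "P2"),
                    group = c("g1", "g1", "g1", "g1"),
                    cluster = rep("t", 4))
  ds$spots$compartment <- rep("tumor", 4)
  # force two groups across two extra samples to satisfy the >=2 rule
  wide <- cbind(counts, counts)
  colnames(wide) <- paste0("s", 1:8)
  ds2 <- toy_dataset(wide,
                     sample_id = rep(c("P1", "P2", "P3", "P4"), each = 2),
                     group = rep(c("gA", "gA", "gB", "gB"), each = 2),
                     cluster = rep("t", 8))
  ds2$spots$compartment <- rep("tumor", 8)
  pb <- pseudobulk(ds2, "tumor")
  expect_equal(pb$counts["G1", "P1"], 3 + 4)  # spots (3,4) sum to 7
  expect_equal(pb$counts["G2", "P2"], 7 + 8)
  expect_equal(unname(pb$groups), c("gA", "gA", "gB", "gB"))

  # partition additivity: summing all compartments equals summing all spots
  ds2$spots$compartment <- rep(c("tumor", "immune"), 4)
  tot <- pseudobulk(ds2, "tumor")$counts + pseudobulk(ds2, "immune")$counts
  manual <- sapply(unique(ds2$spots$sample_id), function(s)
    Matrix::rowSums(ds2$counts[, ds2$spots$sample_id == s, drop = FALSE]))
  expect_equal(unname(tot), unname(as.matrix(manual)))
})

test_that("pseudobulk drops empty samples with a warning and guards group size", {
  counts <- rand_counts(3, 8, seed = 1)
  ds <- toy_dataset(counts,
                    sample_id = rep(c("P1", "P2", "P3", "P4"), each = 2),
                    group = rep(c("gA", "gA", "gB", "gB"), each = 2),
                    cluster = rep("t", 8))
  comp <- rep("tumor", 8); comp[7:8] <- "immune"  # P4 has no tumor spot
  ds$spots$compartment <- comp
  expect_error(expect_warning(pseudobulk(ds, "tumor"), "P4"),
               class = "spotlink_validation_error")  # gB left with 1 sample
})

test_that("group-label symmetry: swapping groups negates fold changes", {
  tp <- toy_pseudobulk()
  de_ab <- nb_wald_test(tp$counts, tp$groups, levels = c("A", "B"))
  de_ba <- nb_wald_test(tp$counts, tp$groups, levels = c("B", "A"))
  i <- match(de_ab$gene, de_ba$gene)
  expect_equal(de_ab$log2fc, -de_ba$log2fc[i], tolerance = 1e-8)
  expect_equal(de_ab$pvalue, de_ba$pvalue[i], tolerance = 1e-8)
  flipped <- c(up_A = "up_B", up_B = "up_A", ns = "ns")
  expect_equal(unname(flipped[de_ab$flag]), de_ba$flag[i])
})

test_that("permuting samples within a group leaves statistics unchanged", {
  tp <- toy_pseudobulk()
  perm <- c(2, 3, 1, 4, 5, 6)  # shuffle inside group A only
  de1 <- nb_wald_test(tp$counts, tp$groups, levels = c("A", "B"))
  de2 <- nb_wald_test(tp$counts[, perm], tp$groups[perm], levels = c("A", "B"))
  expect_equal(de1$log2fc, de2$log2fc[match(de1$gene, de2$gene)], tolerance = 1e-10)
  expect_equal(de1$pvalue, de2$pvalue[match(de1$gene, de2$gene)], tolerance = 1e-10)
})

test_that("a gene with identical counts in both groups is a clean null", {
  tp <- toy_pseudobulk(n_genes = 30)
  # mirror the whole cohort so size factors are symmetric too
  tp$counts[, 4:6] <- tp$counts[, 1:3]
  tp$counts[1, ] <- c(50, 60, 70, 50, 60, 70)
  de <- nb_wald_test(tp$counts, tp$groups, levels = c("A", "B"))
  g1 <- de[de$gene == "G1", ]
  expect_equal(g1$log2fc, 0, tolerance = 1e-8)
  expect_equal(g1$flag, "ns")
})

test_that("DE results keep BH monotonicity and threshold flags", {
  tp <- toy_pseudobulk(n_genes = 120, lfc_genes = paste0("G", 1:10), lfc = 3)
  de <- nb_wald_test(tp$counts, tp$groups, levels = c("A", "B"))
  expect_true(all(de$padj >= de$pvalue - 1e-15))
  # rows are ordered by pvalue and padj is monotone along that order
  expect_false(is.unsorted(de$pvalue))
  expect_false(is.unsorted(de$padj))
  expect_true(all(de$flag[de$padj <= 0.01 & de$log2fc >= 2] == "up_A"))
  # our padj equals the brute-force step-up on the same p-vector
  expect_equal(de$padj, brute_bh(de$pvalue))
})

test_that("BH adjustment equals the brute-force step-up procedure", {
  withr::with_seed(99, {
    for (n in c(5, 17, 50)) {
      p <- stats::runif(n)^2
      expect_equal(stats::p.adjust(p, "BH"), brute_bh(p))
    }
  })
})

test_that("the DE flag rule applies both thresholds", {
  res <- data.frame(gene = c("a", "b", "c", "d"),
                    log2fc = c(2.5, 1.9, -3.0, -2.2),
                    padj = c(0.005, 1e-10, 0.02, 0.009))
  out <- classify_de(res, spotlink_config())
  expect_equal(out$flag, c("up_A", "ns", "ns", "up_B"))
  expect_equal(unname(attr(out, "summary")), c(1L, 1L))
})

test_that("fold-change estimates agree with an established NB DE fit", {
  skip_if_not_installed("DESeq2")
  tp <- toy_pseudobulk(n_genes = 150, n_per_group = 4, seed = 31,
                       lfc_genes = paste0("G", 1:15), lfc = 2.5)
  de <- nb_wald_test(tp$counts, tp$groups, levels = c("A", "B"))
  suppressMessages({
    dds <- DESeq2::DESeqDataSetFromMatrix(
      tp$counts, data.frame(cond = factor(tp$groups, levels = c("B", "A"))),
      ~cond)
    dds <- DESeq2::DESeq(dds, quiet = TRUE)
    ref <- DESeq2::results(dds, contrast = c("cond", "A", "B"))
  })
  i <- match(de$gene, rownames(ref))
  keep <- is.finite(ref$log2FoldChange[i])
  expect_gt(stats::cor(de$log2fc[keep], ref$log2FoldChange[i][keep]), 0.95)
  planted <- de$gene %in% paste0("G", 1:15)
  expect_true(all(de$log2fc[planted & keep] > 1))
})
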