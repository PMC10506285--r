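test_that("low-quality spot filtering drops by total count and by list", {
  counts <- matrix(0, 2, 4, dimnames = list(c("G1", "G2"), paste0("s", 1:4)))
  counts[1, ] <- c(0, 10, 500, 800)
  ds <- toy_dataset(counts)
  f <- filter_low_quality_spots(ds, min_counts = 100)
  expect_equal(f$spots$spot_id, c("s3", "s4"))
  expect_setequal(attr(f, "removed")$spot_id, c("s1", "s2"))

  f2 <- filter_low_quality_spots(ds, min_counts = 100, exclude_spot_ids = "s3")
  expect_equal(f2$spots$spot_id, "s4")

  # no-op case is the identity
  f3 <- filter_low_quality_spots(ds, min_counts = 0)
  expect_equal(dim(f3), dim(ds))

  expect_error(filter_low_quality_spots(ds, min_counts = 1e6),
               class = "spotlink_validation_error")
})

test_that("rare-gene filter keeps genes at or above the detection fraction", {
  # 100 spots; detection in 2 (dropped), 3 (kept: 3% >= 2.5%), 0 (dropped)
  counts <- matrix(0, 3, 100, dimnames = list(c("rare2", "rare3", "zero"), NULL))
  counts[1, 1:2] <- 1
  counts[2, 1:3] <- 1
  # keep one dense gene so the filtered set is non-empty regardless
  counts <- rbind(counts, dense = rep(1, 100))
  ds <- toy_dataset(counts)
  f <- filter_rare_genes(ds, 0.025)
  expect_setequal(rownames(f$counts), c("rare3", "dense"))

  # boundary: fraction exactly equal to the threshold is retained
  counts40 <- rbind(edge = c(1, rep(0, 39)), dense = rep(1, 40))
  f40 <- filter_rare_genes(toy_dataset(counts40), 0.025)
  expect_true("edge" %in% rownames(f40$counts))

  # idempotence
  expect_equal(rownames(filter_rare_genes(f, 0.025)$counts), rownames(f$counts))
})

test_that("rare-gene filter equals a brute-force nonzero scan", {
  counts <- rand_counts(60, 80, lambda = 0.08, seed = 11)
  counts[1, ] <- 5  # guarantee a survivor
  ds <- toy_dataset(counts)
  for (thr in c(0.01, 0.025, 0.1)) {
    kept <- rownames(filter_rare_genes(ds, thr)$counts)
    brute <- rownames(counts)[sapply(seq_len(nrow(counts)), function(i)
      sum(counts[i, ] > 0) / ncol(counts) >= thr)]
    expect_identical(kept, brute)
  }
})

test_that("log-CPM normalization has its closed form and scale invariance", {
  counts <- matrix(c(100, 9900, 0, 50, 100, 9850), nrow = 3,
                   dimnames = list(c("G1", "G2", "G3"), c("s1", "s2")))
  norm <- normalize_logcpm(toy_dataset(counts))
  expect_equal(norm["G1", "s1"], log2(101))  # total 1e4, count 100
  expect_equal(norm["G3", "s1"], 0)          # count 0 -> exactly 0
  # doubling all counts in a spot leaves its profile unchanged
  norm2 <- normalize_logcpm(toy_dataset(counts * 2))
  expect_equal(norm2, norm)
})

test_that("compartment merging validates the map and fills the field", {
  counts <- rand_counts(3, 8, seed = 2)
  ds <- toy_dataset(counts, cluster = rep(c("T1", "T2", "I1", "C1"), 2))
  merged <- merge_compartments(ds, c(T1 = "tumor", T2 = "tumor",
                                     I1 = "immune", C1 = "CAF"))
  expect_setequal(unique(merged$spots$compartment), c("tumor", "immune", "CAF"))
  expect_equal(merged$spots$cluster, ds$spots$cluster)  # clusters untouched

  err <- tryCatch(merge_compartments(ds, c(T1 = "tumor", T2 = "tumor", I1 = "immune")),
                  error = identity)
  expect_s3_class(err, "spotlink_validation_error")
  expect_match(conditionMessage(err), "C1")
})

test_that("compartment proportions sum to one per sample", {
  counts <- rand_counts(2, 100, seed = 3)
  comp <- c(rep("tumor", 60), rep("immune", 30), rep("CAF", 10))
  ds <- toy_dataset(counts, cluster = comp)
  ds <- merge_compartments(ds, c(tumor = "tumor", immune = "immune", CAF = "CAF"))
  pr <- compartment_proportions(ds)
  expect_equal(pr$fraction[match(c("tumor", "immune", "CAF"), pr$compartment)],
               c(0.6, 0.3, 0.1))
  # two samples: two independent unit-sum rows
  ds2 <- toy_dataset(rand_counts(2, 6, seed = 4),
                     sample_id = rep(c("A", "B"), each = 3),
                     cluster = c("t", "t", "i", "t", "i", "i"))
  ds2 <- merge_compartments(ds2, c(t = "tumor", i = "immune"))
  pr2 <- compartment_proportions(ds2)
  sums <- tapply(pr2$fraction, pr2$sample_id, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-12)
})

test_that("hex neighbor offsets follow the array dialect", {
  # a spot at (2,4) with all six dialect neighbors present
  rows <- c(2, 2, 2, 1, 1, 3, 3)
  cols <- c(4, 2, 6, 3, 5, 3, 5)
  counts <- rand_counts(2, 7, seed = 5)
  ds <- spot_dataset(counts, c("G1", "G2"), paste0("s", 1:7), rows, cols,
                     rep("S1", 7), rep("g1", 7))
  g <- build_neighbor_graph(ds)
  deg <- tabulate(c(g$edges$a, g$edges$b), 7)
  expect_equal(deg[1], 6L)   # the center touches all six
  expect_equal(nrow(g$edges), 12L)  # 6 spokes + 6 edges around the ring

  # isolated spot
  iso <- spot_dataset(rand_counts(2, 1, seed = 5), c("G1", "G2"), "s1",
                      10L, 10L, "S1", "g1")
  expect_equal(nrow(build_neighbor_graph(iso)$edges), 0L)

  # parity violation is rejected at construction
  expect_error(spot_dataset(counts[, 1, drop = FALSE], c("G1", "G2"), "s1",
                            0L, 1L, "S1", "g1"),
               class = "spotlink_validation_error")
})

test_that("neighbor graph equals brute-force pair enumeration", {
  withr::with_seed(21, {
    for (rep in 1:3) {
      n <- 150
      coords <- hex_coords(14, 26)
      pick <- sample(nrow(coords), n)
      samp <- sample(c("S1", "S2"), n, replace = TRUE)
      ds <- spot_dataset(rand_counts(2, n, seed = rep), c("G1", "G2"),
                         paste0("s", 1:n), coords$array_row[pick],
                         coords$array_col[pick], samp, rep("g1", n))
      g <- build_neighbor_graph(ds)
      brute <- brute_neighbor_edges(ds$spots)
      expect_equal(g$edges$a, brute$a)
      expect_equal(g$edges$b, brute$b)
      expect_true(all(tabulate(c(g$edges$a, g$edges$b), n) <= 6L))
    }
  })
})

test_that("cluster adjacency uses the contact-edge floor and sample isolation", {
  # two rows of 12 spots each: row of cluster A neighbors row of cluster B
  n <- 24
  rows <- rep(c(0L, 1L), each = 12)
  cols <- c(seq(0, 22, 2), seq(1, 23, 2))
  ds <- spot_dataset(rand_counts(2, n, seed = 6), c("G1", "G2"),
                     paste0("s", 1:n), rows, cols, rep("S1", n), rep("g1", n),
                     cluster = rep(c("A", "B"), each = 12))
  g <- build_neighbor_graph(ds)
  cc <- cluster_contact_counts(g)
  ab <- cc$n_edges[cc$cluster_a == "A" & cc$cluster_b == "B"]
  expect_gte(ab, 12L)
  expect_equal(nrow(adjacent_cluster_pairs(g, min_contact_edges = ab)), 1L)
  expect_equal(nrow(adjacent_cluster_pairs(g, min_contact_edges = ab + 1L)), 0L)

  # same coordinates, different samples: never adjacent
  ds2 <- spot_dataset(rand_counts(2, n, seed = 7), c("G1", "G2"),
                      paste0("s", 1:n), rows, cols,
                      rep(c("S1", "S2"), each = 12), rep("g1", n),
                      cluster = rep(c("A", "B"), each = 12))
  g2 <- build_neighbor_graph(ds2)
  expect_equal(nrow(adjacent_cluster_pairs(g2, 1)), 0L)
})

test_that("region subsetting keeps the gene universe and validates clusters", {
  counts <- rand_counts(5, 9, seed = 8)
  ds <- toy_dataset(counts, cluster = rep(c("tumor", "immune", "CAF"), 3))
  sub <- subset_region(ds, c("tumor", "immune"))
  expect_equal(nrow(sub$counts), 5L)
  expect_equal(ncol(sub$counts), 6L)
  expect_setequal(unique(sub$spots$cluster), c("tumor", "immune"))
  all3 <- subset_region(ds, c("tumor", "immune", "CAF"))
  expect_equal(dim(all3), dim(ds))
  expect_error(subset_region(ds, character()), class = "spotlink_validation_error")
  expect_error(subset_region(ds, "stroma"), class = "spotlink_validation_error")
})
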