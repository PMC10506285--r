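# Minimal fixtures: an activity matrix plus an expression matrix over named
# spots, for exercising the correlation/pruning chain in isolation.
toy_region <- function(n = 12, seed = 7) {
  withr::with_seed(seed, {
    spots <- paste0("s", seq_len(n))
    act <- matrix(stats::runif(2 * n), 2, n,
                  dimnames = list(c("TFX", "TFY"), spots))
    expr <- matrix(stats::rnorm(3 * n, 5), 3, n,
                   dimnames = list(c("R1", "R2", "R3"), spots))
    list(act = act, expr = expr, spots = spots)
  })
}

test_that("receptor-module correlation is Pearson on z-scaled expression", {
  tr <- toy_region()
  # receptor equal to an affine transform of module activity -> r = 1
  tr$expr["R1", ] <- 3 * tr$act["TFX", ] + 7
  # constant receptor -> r recorded 0 and flagged
  tr$expr["R2", ] <- 4
  out <- receptor_module_correlation(tr$act, tr$expr, c("R1", "R2", "R3"), tr$spots)
  expect_equal(unname(out$r["R1", "TFX"]), 1, tolerance = 1e-12)
  expect_equal(unname(out$r["R2", ]), c(0, 0))
  expect_equal(out$flagged, "R2")
  # hand-computed Pearson formula on the 12-spot toy
  x <- tr$expr["R3", ]; y <- tr$act["TFY", ]
  hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(unname(out$r["R3", "TFY"]), hand, tolerance = 1e-12)

  expect_error(receptor_module_correlation(tr$act, tr$expr, "R1", tr$spots[1:5]),
               class = "spotlink_validation_error")
})

test_that("targeted receptors are zeroed exactly and idempotently", {
  cm <- matrix(c(0.9, 0.5, 0, 0.8), 2, 2,
               dimnames = list(c("R1", "R2"), c("TFX", "TFY")))
  regs <- list(TFX = list(tf = "TFX", targets = c("R1", "G5")),
               TFY = list(tf = "TFY", targets = "G9"))
  p1 <- prune_targeted_receptors(cm, regs)
  expect_equal(unname(p1["R1", "TFX"]), 0)
  expect_equal(unname(p1["R2", "TFX"]), 0.5)   # untouched
  expect_equal(unname(p1["R2", "TFY"]), 0.8)
  expect_equal(prune_targeted_receptors(p1, regs), p1)  # idempotent
})

test_that("the linkage threshold is strict and one-sided", {
  cm <- matrix(c(0.31, 0.30, -0.9, 0.45), 4, 1,
               dimnames = list(paste0("R", 1:4), "TFX"))
  links <- link_receptors(cm, 0.3)
  expect_setequal(links$receptor, c("R1", "R4"))
  expect_false("R2" %in% links$receptor)  # r = 0.30 exactly: excluded
  expect_false("R3" %in% links$receptor)  # negative: excluded
})

test_that("cognate-ligand filtering follows detection in the sender", {
  links <- data.frame(receptor = c("R1", "R2", "R3"), tf_module = "TFX",
                      correlation = c(0.5, 0.6, 0.7), stringsAsFactors = FALSE)
  lr <- lr_reference(c("p1", "p2", "p3", "p4"),
                     c("L1", "L2", "L2b", "L3"),
                     c("R1", "R2", "R2", "R9"))
  # sender: 25 spots; L1 detected in 2 (8%), L2 undetected, L2b in 10 (40%)
  sender <- matrix(0, 4, 25, dimnames = list(c("L1", "L2", "L2b", "X"), NULL))
  sender[1, 1:2] <- 1; sender[3, 1:10] <- 1
  out <- require_cognate_ligands(links, lr, sender, ligand_expr_fraction = 0.05)
  expect_setequal(out$edges$receptor, c("R1", "R2"))
  expect_equal(out$edges$ligand[out$edges$receptor == "R2"], "L2b")
  expect_true("R3" %in% out$excluded$receptor)  # absent from the LR reference
  expect_equal(out$excluded$reason[out$excluded$receptor == "R3"],
               "not_in_lr_reference")

  # a receptor with two expressed ligands yields two edges
  lr2 <- lr_reference(c("q1", "q2"), c("L1", "L2b"), c("R1", "R1"))
  out2 <- require_cognate_ligands(links[1, ], lr2, sender, 0.05)
  expect_equal(nrow(out2$edges), 2L)
  expect_setequal(out2$edges$ligand, c("L1", "L2b"))
  expect_equal(unique(out2$edges$receptor), "R1")
})

test_that("multi-subunit ligands require every subunit detected", {
  links <- data.frame(receptor = "R1", tf_module = "TFX", correlation = 0.5)
  lr <- lr_reference("p1", "La,Lb", "R1")
  sender <- matrix(0, 2, 20, dimnames = list(c("La", "Lb"), NULL))
  sender[1, 1:10] <- 1            # La detected, Lb not
  out <- require_cognate_ligands(links, lr, sender, 0.05)
  expect_equal(nrow(out$edges), 0L)
  sender[2, 1:10] <- 1            # now both pass
  out2 <- require_cognate_ligands(links, lr, sender, 0.05)
  expect_equal(out2$edges$ligand, "La,Lb")
})

test_that("recovery scoring arithmetic handles edge cases", {
  truth <- list(planted_links = data.frame(
    receptor = paste0("R", 1:4), tf = paste0("T", 1:4)))
  mk_net <- function(rec, tf) structure(list(
    edges = data.frame(receptor = rec, tf_module = tf)), class = "signaling_network")
  perfect <- mk_net(paste0("R", 1:4), paste0("T", 1:4))
  expect_equal(score_network_recovery(perfect, truth)[c("precision", "recall")],
               list(precision = 1, recall = 1))
  empty <- mk_net(character(), character())
  sc <- score_network_recovery(empty, truth)
  expect_true(is.nan(sc$precision))
  expect_equal(sc$recall, 0)
  mixed <- mk_net(c(paste0("R", 1:3), "RX"), c(paste0("T", 1:3), "TX"))
  sc2 <- score_network_recovery(mixed, truth)
  expect_equal(sc2$precision, 0.75)
  expect_equal(sc2$recall, 0.75)
})

test_that("end-to-end interaction analysis respects structural rules", {
  sim <- generate_tissue(sim_params(n_per_group = c(1L, 0L), n_rows = 24L,
                                    n_cols = 40L, n_genes = 600L,
                                    n_regulons = 3L, targets_per_regulon = 25L,
                                    n_decoy_receptors = 10L, n_decoy_ligands = 10L,
                                    n_decoy_tfs = 3L, n_de_per_direction = 0L,
                                    n_signature_genes = 0L), seed = 31L)
  ds <- annotate_from_truth(sim$dataset, sim$truth)
  tr <- sim$truth
  cfg <- spotlink_config(rng_seed = 31)
  ds <- filter_rare_genes(filter_low_quality_spots(ds, cfg$min_counts),
                          cfg$min_spot_fraction)
  norm <- normalize_logcpm(ds)
  imps <- coexpression_importance(norm, names(tr$planted_regulons),
                                  sample_id = ds$spots$sample_id)
  regs <- build_modules(imps, 95, 20, prior = truth_prior(tr))
  act <- aucell_scores(norm, regs, 0.05, seed = 1)
  net <- run_interaction_analysis(ds, act, regs, truth_lr_reference(tr), cfg)

  # the three emission rules hold on every edge
  expect_true(all(net$edges$correlation > cfg$corr_threshold))
  for (i in seq_len(nrow(net$edges)))
    expect_false(net$edges$receptor[i] %in% regs[[net$edges$tf_module[i]]]$targets)

  # raising the threshold never adds edges
  cfg2 <- spotlink_config(corr_threshold = 0.45, rng_seed = 31)
  net2 <- run_interaction_analysis(ds, act, regs, truth_lr_reference(tr), cfg2)
  key <- function(n) paste(n$edges$receptor, n$edges$tf_module, n$edges$sender_cluster)
  expect_true(all(key(net2) %in% key(net)))

  # a tissue region with no adjacent pair yields an empty network, no error
  iso <- subset_region(ds, "tumor_B")
  act_iso <- act[, iso$spots$spot_id, drop = FALSE]
  net3 <- run_interaction_analysis(iso, act_iso, regs, truth_lr_reference(tr),
                                   spotlink_config(min_contact_edges = 10000L))
  expect_equal(nrow(net3$edges), 0L)
})
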