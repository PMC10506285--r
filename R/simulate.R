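#' Parameters for the synthetic tissue generator
#'
#' Defines the simulated study: a multi-sample cohort split into two response
#' groups, each sample a contiguous hex-grid tissue partitioned into five
#' spatially contiguous domains (`tumor_A`, `tumor_B`, `immune`, `CAF`,
#' `other`), negative-binomial UMI counts, planted TF regulons whose smooth
#' latent activity drives targets, the TF itself and a cognate receptor inside
#' a receiver domain, planted ligands expressed only in the sender domain,
#' decoy receptors/ligands/TFs with no planted structure, planted group-level
#' log2 fold changes, and a planted stemness-like signature confined to one
#' sub-region.
#'
#' @param n_per_group integer length-2: samples in group A (responder-like)
#'   and group B.
#' @param n_rows,n_cols extent of the per-sample hex array; spots sit at all
#'   (row, col) with even row+col, so the sample has `n_rows*n_cols/2` spots.
#' @param n_genes total gene universe (background genes fill the remainder).
#' @param n_regulons planted regulons (each with one TF, one receptor, one
#'   ligand and a planted signaling link).
#' @param targets_per_regulon planted targets per regulon.
#' @param n_decoy_receptors,n_decoy_ligands,n_decoy_tfs decoys with cognate
#'   LR-reference entries (decoy ligands are expressed, so only the
#'   correlation rules can reject the decoy receptors).
#' @param target_correlation intended spot-level Pearson correlation between
#'   a planted receptor's expression and its module activity in the receiver
#'   region; the generator converts it to a log-scale loading using the
#'   baseline mean and dispersion (see the methods vignette).
#' @param receptor_loading optional explicit log-scale receptor loading;
#'   overrides `target_correlation` when non-NULL.
#' @param target_loading log-scale loading of targets (and the TF gene) on the
#'   latent activity.
#' @param n_de_per_direction planted DE genes per direction.
#' @param de_lfc planted group log2 fold change (group A over group B).
#' @param n_signature_genes genes in the planted stemness-like signature,
#'   enriched in `tumor_B`.
#' @param signature_fold fold elevation of signature genes in their domain.
#' @param markers_per_domain flat marker genes elevated per domain.
#' @param base_mean_planted,base_mean_background baseline per-spot mean counts.
#' @param dispersion_meanlog,dispersion_sdlog log-normal gene dispersion.
#' @param depth_cv coefficient of variation of the per-spot depth factor.
#' @param sample_sigma natural-log SD of per-sample, per-gene biological
#'   variation (what makes pseudo-bulk replicates vary).
#' @param domain_fractions named fractions of spots per domain (sum to 1).
#' @param smoothing_sweeps neighbor-averaging sweeps for the latent fields.
#'
#' @return a `sim_params` list.
#' @export
sim_params <- function(n_per_group = c(1L, 1L),
                       n_rows = 45L, n_cols = 90L,
                       n_genes = 1500L,
                       n_regulons = 8L,
                       targets_per_regulon = 30L,
                       n_decoy_receptors = 40L,
                       n_decoy_ligands = 40L,
                       n_decoy_tfs = 10L,
                       target_correlation = 0.6,
                       receptor_loading = NULL,
                       target_loading = 0.8,
                       n_de_per_direction = 40L,
                       de_lfc = 2,
                       n_signature_genes = 25L,
                       signature_fold = 3,
                       markers_per_domain = 15L,
                       base_mean_planted = 8,
                       base_mean_background = 0.8,
                       dispersion_meanlog = log(0.25),
                       dispersion_sdlog = 0.5,
                       depth_cv = 0.3,
                       sample_sigma = 0.25,
                       domain_fractions = c(tumor_A = 0.30, tumor_B = 0.15,
                                            immune = 0.20, CAF = 0.15,
                                            other = 0.20),
                       smoothing_sweeps = 3L) {
  p <- as.list(environment())
  if (length(p$n_per_group) != 2L || any(p$n_per_group < 0L))
    sl_parameter_error("n_per_group must be two non-negative counts")
  if (sum(p$n_per_group) < 1L) sl_parameter_error("need at least one sample")
  if (abs(sum(p$domain_fractions) - 1) > 1e-8)
    sl_parameter_error("domain_fractions must sum to 1")
  needed <- c("tumor_A", "tumor_B", "immune", "CAF", "other")
  if (!setequal(names(p$domain_fractions), needed) ||
      any(p$domain_fractions <= 0))
    sl_parameter_error("domain_fractions must assign a positive fraction to each of: %s",
                       paste(needed, collapse = ", "))
  n_spots <- floor(p$n_rows * p$n_cols / 2)
  if (n_spots < 50L)
    sl_parameter_error("grid of %d spots is too small for %d domains",
                       n_spots, length(p$domain_fractions))
  if (!is.null(p$target_correlation) &&
      (p$target_correlation <= 0 || p$target_correlation >= 1))
    sl_parameter_error("target_correlation must lie in (0, 1)")
  class(p) <- "sim_params"
  p
}

# All hex coordinates of an n_rows x n_cols array patch (even row+col).
hex_coords <- function(n_rows, n_cols) {
  g <- expand.grid(array_row = 0:(n_rows - 1L), array_col = 0:(n_cols - 1L))
  g <- g[(g$array_row + g$array_col) %% 2L == 0L, ]
  rownames(g) <- NULL
  g
}

# Neighbor list under the Visium hex dialect: offsets (0,+-2), (+-1,+-1).
hex_neighbor_list <- function(rows, cols) {
  key <- function(r, c) r * 1e4 + c
  idx <- seq_along(rows)
  lookup <- structure(idx, names = key(rows, cols))
  offs <- rbind(c(0, 2), c(0, -2), c(1, 1), c(1, -1), c(-1, 1), c(-1, -1))
  lapply(idx, function(i) {
    cand <- key(rows[i] + offs[, 1], cols[i] + offs[, 2])
    out <- lookup[as.character(cand)]
    as.integer(out[!is.na(out)])
  })
}

# Contiguous domains by randomized multi-source region growth: one seed per
# domain, round-robin expansion into unclaimed neighbors until quotas are met,
# then leftovers are claimed by whichever domain can still expand.
grow_domains <- function(coords, nbrs, fractions) {
  n <- nrow(coords)
  domains <- names(fractions)
  quota <- round(fractions * n)
  quota[length(quota)] <- n - sum(quota[-length(quota)])
  lab <- rep(NA_character_, n)
  # seeds: tumor_A at the centroid, the others at the four side midpoints so
  # every peripheral domain collides with (hence touches) tumor_A
  ctr <- c(mean(coords$array_row), mean(coords$array_col))
  pick_near <- function(r, c) which.min((coords$array_row - r)^2 + (coords$array_col - c)^2)
  seed_pos <- list(
    tumor_A = pick_near(ctr[1], ctr[2]),
    immune  = pick_near(ctr[1], min(coords$array_col)),
    CAF     = pick_near(ctr[1], max(coords$array_col)),
    tumor_B = pick_near(max(coords$array_row), ctr[2]),
    other   = pick_near(min(coords$array_row), ctr[2])
  )
  frontier <- list()
  for (d in domains) {
    s <- seed_pos[[d]]
    if (!is.na(lab[s])) s <- which(is.na(lab))[1]
    lab[s] <- d
    frontier[[d]] <- s
  }
  claimed <- sum(!is.na(lab))
  while (claimed < n) {
    progressed <- FALSE
    for (d in domains) {
      over_quota <- sum(lab == d, na.rm = TRUE) >= quota[[d]]
      if (over_quota && any(vapply(domains, function(dd)
        sum(lab == dd, na.rm = TRUE) < quota[[dd]] && length(frontier[[dd]]) > 0,
        logical(1)))) next
      fr <- frontier[[d]]
      while (length(fr)) {
        i <- fr[sample.int(length(fr), 1L)]
        cand <- nbrs[[i]][is.na(lab[nbrs[[i]]])]
        if (length(cand)) {
          j <- cand[sample.int(length(cand), 1L)]
          lab[j] <- d
          fr <- c(fr, j)
          claimed <- claimed + 1L
          progressed <- TRUE
          break
        }
        fr <- fr[fr != i]
      }
      frontier[[d]] <- fr
      if (claimed >= n) break
    }
    if (!progressed) break
  }
  if (anyNA(lab)) lab[is.na(lab)] <- "other"  # unreachable only on degenerate grids
  lab
}

# Smooth latent activity: iid normal noise averaged with neighbors for
# `sweeps` rounds, standardized within the receiver domain, clipped to +-3,
# zero outside the receiver.
latent_field <- function(nbrs, receiver_idx, sweeps) {
  n <- length(nbrs)
  a <- stats::rnorm(n)
  for (s in seq_len(sweeps)) {
    nb_mean <- vapply(seq_len(n), function(i) {
      nb <- nbrs[[i]]
      if (length(nb)) mean(a[nb]) else a[i]
    }, numeric(1))
    a <- (a + nb_mean) / 2
  }
  out <- numeric(n)
  v <- a[receiver_idx]
  v <- (v - mean(v)) / stats::sd(v)
  out[receiver_idx] <- pmin(pmax(v, -3), 3)
  out
}

# Convert an intended receptor-module correlation into a log-scale loading.
# Model: realized r = kappa * L / sqrt(L^2 + V), where kappa is the
# correlation between module activity (an AUC readout) and the latent field,
# and V the effective log-scale noise variance of receptor expression.
# kappa = 0.84 and the inflation of V over the naive NB value 1/mu + alpha
# (a factor 1.7, absorbing the log1p transform, depth variation and rank
# tie noise) were calibrated once by simulation; see the methods vignette.
loading_for_correlation <- function(rho, mu, alpha, kappa = 0.84, v_inflation = 1.7) {
  v <- v_inflation * (1 / mu + alpha)
  rho_eff <- min(rho / kappa, 0.97)
  rho_eff * sqrt(v / (1 - rho_eff^2))
}

#' Generate a synthetic Visium-like cohort with planted truth
#'
#' Draws, per sample, a contiguous hex tissue split into five domains, then
#' negative-binomial counts whose log-mean combines: a per-gene, per-domain
#' baseline; a smooth latent activity field (per planted regulon, nonzero in
#' its receiver domain) loading the regulon's targets, its TF gene and its
#' receptor; sender-domain-only expression of cognate ligands; per-sample
#' biological noise; a group effect on planted DE genes; and a log-normal
#' per-spot depth factor. Multiplicative latent effects are mean-centered
#' (`exp(beta*A - beta^2/2)`) so domain averages stay flat and module/receptor
#' correlations across domains are driven by the latent field, not by
#' domain-mean offsets.
#'
#' @param params a [sim_params()] list.
#' @param seed integer seed; the same seed reproduces counts and truth
#'   bit-for-bit.
#' @return list with `dataset` (a [spot_dataset()]) and `truth` (a
#'   `synthetic_truth` list: `domain_map`, `planted_regulons`,
#'   `planted_links`, `planted_de_genes`, `planted_signatures`,
#'   `generator_params`).
#' @export
generate_tissue <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  with_seed(seed, generate_tissue_impl(params, seed))
}

generate_tissue_impl <- function(p, seed) {
  domains <- c("tumor_A", "tumor_B", "immune", "CAF", "other")
  coords <- hex_coords(p$n_rows, p$n_cols)
  nbrs <- hex_neighbor_list(coords$array_row, coords$array_col)
  n_spots <- nrow(coords)

  ## ---- gene universe -------------------------------------------------
  nm <- function(pre, n) if (n > 0) sprintf("%s%03d", pre, seq_len(n)) else character()
  tfs <- nm("TF", p$n_regulons)
  receptors <- nm("REC", p$n_regulons)
  ligands <- nm("LIG", p$n_regulons)
  targets <- lapply(seq_len(p$n_regulons), function(r)
    sprintf("TG%02d_%03d", r, seq_len(p$targets_per_regulon)))
  decoy_tfs <- nm("DTF", p$n_decoy_tfs)
  decoy_rec <- nm("DREC", p$n_decoy_receptors)
  decoy_lig <- nm("DLIG", p$n_decoy_ligands)
  markers <- lapply(domains, function(d) sprintf("MK_%s_%02d", d, seq_len(p$markers_per_domain)))
  names(markers) <- domains
  sig_genes <- nm("SIG", p$n_signature_genes)
  de_up_a <- nm("DEA", p$n_de_per_direction)
  de_up_b <- nm("DEB", p$n_de_per_direction)
  fixed <- c(tfs, receptors, ligands, unlist(targets), decoy_tfs, decoy_rec,
             decoy_lig, unlist(markers), sig_genes, de_up_a, de_up_b)
  n_bg <- p$n_genes - length(fixed)
  if (n_bg < 0)
    sl_parameter_error("n_genes = %d is smaller than the %d planted genes",
                       p$n_genes, length(fixed))
  bg <- if (n_bg > 0) sprintf("BG%04d", seq_len(n_bg)) else character()
  genes <- c(fixed, bg)
  G <- length(genes)

  ## ---- per-gene baselines (genes x domains), dispersions --------------
  base <- matrix(0, G, length(domains), dimnames = list(genes, domains))
  base[, ] <- stats::rlnorm(G, log(p$base_mean_background), 0.8)
  planted_flat <- c(tfs, receptors, unlist(targets), decoy_rec, decoy_lig)
  base[planted_flat, ] <- p$base_mean_planted
  base[decoy_tfs, ] <- p$base_mean_planted * 0.6
  for (d in domains) {
    base[markers[[d]], ] <- 2
    base[markers[[d]], d] <- 8
  }
  if (length(sig_genes)) {
    base[sig_genes, ] <- 2
    base[sig_genes, "tumor_B"] <- 2 * p$signature_fold
  }
  base[c(de_up_a, de_up_b), ] <- 4
  # ligands expressed in the sender domain only (sender is always tumor_A)
  if (length(ligands)) {
    base[ligands, ] <- 0.02
    base[ligands, "tumor_A"] <- p$base_mean_planted
  }
  dispersion <- stats::rlnorm(G, p$dispersion_meanlog, p$dispersion_sdlog)
  names(dispersion) <- genes

  ## ---- planted link layout -------------------------------------------
  receiver_of <- if (p$n_regulons > 0)
    rep(c("immune", "CAF"), length.out = p$n_regulons) else character()
  links <- if (p$n_regulons > 0) data.frame(
    ligand = ligands, receptor = receptors, tf = tfs,
    sender_domain = "tumor_A", receiver_domain = receiver_of,
    target_correlation = p$target_correlation, stringsAsFactors = FALSE
  ) else data.frame(ligand = character(), receptor = character(), tf = character(),
                    sender_domain = character(), receiver_domain = character(),
                    target_correlation = numeric())

  alpha_bar <- exp(p$dispersion_meanlog + p$dispersion_sdlog^2 / 2)
  rec_loading <- p$receptor_loading %||%
    loading_for_correlation(p$target_correlation, p$base_mean_planted, alpha_bar)

  ## ---- samples --------------------------------------------------------
  groups <- c(rep("responder", p$n_per_group[1]), rep("non_responder", p$n_per_group[2]))
  sample_ids <- sprintf("S%02d", seq_along(groups))
  de_lfc_vec <- c(stats::setNames(rep(p$de_lfc, length(de_up_a)), de_up_a),
                  stats::setNames(rep(-p$de_lfc, length(de_up_b)), de_up_b))

  counts_list <- list(); spot_tab <- list()
  domain_map <- list()
  latent_store <- lapply(seq_len(p$n_regulons), function(r) numeric(0))

  for (si in seq_along(sample_ids)) {
    dom <- grow_domains(coords, nbrs, p$domain_fractions)
    spot_ids <- sprintf("%s_spot%04d", sample_ids[si], seq_len(n_spots))
    log_mu <- log(base[, dom, drop = FALSE])  # genes x spots

    # planted regulons: latent field in the receiver domain loads targets,
    # the TF gene and the receptor (mean-centered multiplicative effect)
    for (r in seq_len(p$n_regulons)) {
      recv_idx <- which(dom == receiver_of[r])
      a <- latent_field(nbrs, recv_idx, p$smoothing_sweeps)
      gset <- c(targets[[r]], tfs[r])
      log_mu[gset, ] <- log_mu[gset, , drop = FALSE] +
        rep(p$target_loading * a - p$target_loading^2 / 2, each = length(gset))
      log_mu[receptors[r], ] <- log_mu[receptors[r], ] +
        rec_loading * a - rec_loading^2 / 2
      latent_store[[r]] <- c(latent_store[[r]], stats::setNames(a, spot_ids))
    }

    # group effect on planted DE genes, split symmetrically between groups
    if (length(de_lfc_vec)) {
      shift <- if (groups[si] == "responder") de_lfc_vec / 2 else -de_lfc_vec / 2
      log_mu[names(de_lfc_vec), ] <- log_mu[names(de_lfc_vec), , drop = FALSE] +
        shift * log(2)
    }

    # per-sample biological noise and per-spot depth
    samp_eff <- stats::rnorm(G, 0, p$sample_sigma)
    depth <- stats::rlnorm(n_spots, -log(1 + p$depth_cv^2) / 2,
                           sqrt(log(1 + p$depth_cv^2)))
    log_mu <- log_mu + samp_eff + rep(log(depth), each = G)

    mu <- exp(log_mu)
    k <- matrix(stats::rnbinom(length(mu), mu = mu, size = rep(1 / dispersion, n_spots)),
                nrow = G, dimnames = list(genes, spot_ids))
    counts_list[[si]] <- Matrix::Matrix(k, sparse = TRUE)
    spot_tab[[si]] <- data.frame(
      spot_id = spot_ids, array_row = coords$array_row, array_col = coords$array_col,
      sample_id = sample_ids[si], group = groups[si], domain = dom,
      stringsAsFactors = FALSE)
    domain_map[[si]] <- stats::setNames(dom, spot_ids)
  }

  spots <- do.call(rbind, spot_tab)
  counts <- do.call(cbind, counts_list)
  ds <- spot_dataset(counts, genes, spots$spot_id, spots$array_row,
                     spots$array_col, spots$sample_id, spots$group)

  planted_regulons <- lapply(seq_len(p$n_regulons), function(r)
    list(tf = tfs[r], targets = targets[[r]], latent = latent_store[[r]]))
  names(planted_regulons) <- tfs
  signatures <- if (length(sig_genes))
    list(stemness = list(genes = sig_genes, domain = "tumor_B")) else list()

  truth <- structure(list(
    domain_map = do.call(c, domain_map),
    planted_regulons = planted_regulons,
    planted_links = links,
    planted_de_genes = de_lfc_vec,
    planted_signatures = signatures,
    generator_params = c(unclass(p), list(seed = seed, receptor_loading_used = rec_loading))
  ), class = "synthetic_truth")
  list(dataset = ds, truth = truth)
}

#' Derive spot annotations from a synthetic truth
#'
#' Maps planted domains to cluster labels (identity) and to compartments
#' (`tumor_A`/`tumor_B` merge into `tumor`; `immune`, `CAF` and `other` map to
#' themselves) — the synthetic stand-in for expert-reviewed cluster labels.
#'
#' @param truth a `synthetic_truth`.
#' @return data.frame with `spot_id`, `cluster`, `compartment`.
#' @export
truth_to_annotations <- function(truth) {
  dm <- truth$domain_map
  if (!length(dm)) sl_validation_error("truth has an empty domain map")
  comp_map <- c(tumor_A = "tumor", tumor_B = "tumor", immune = "immune",
                CAF = "CAF", other = "other")
  bad <- setdiff(unique(dm), names(comp_map))
  if (length(bad))
    sl_validation_error("unknown domain label(s): %s", paste(bad, collapse = ", "))
  data.frame(spot_id = names(dm), cluster = unname(dm),
             compartment = unname(comp_map[dm]), stringsAsFactors = FALSE)
}

#' Attach truth-derived cluster/compartment annotations to a dataset
#'
#' @param ds the generated `spot_dataset`.
#' @param truth the matching `synthetic_truth`.
#' @return the dataset with `cluster` and `compartment` populated.
#' @export
annotate_from_truth <- function(ds, truth) {
  ann <- truth_to_annotations(truth)
  i <- match(ds$spots$spot_id, ann$spot_id)
  if (anyNA(i)) sl_validation_error("truth does not cover all spots")
  ds$spots$cluster <- ann$cluster[i]
  ds$spots$compartment <- ann$compartment[i]
  ds
}

#' TF-to-target prior table implied by the planted truth
#'
#' The synthetic analogue of a motif-based pruning resource: for each planted
#' TF, the allowed targets are exactly its planted targets.
#'
#' @param truth a `synthetic_truth`.
#' @return data.frame with columns `tf`, `target`.
#' @export
truth_prior <- function(truth) {
  if (!length(truth$planted_regulons))
    return(data.frame(tf = character(), target = character()))
  do.call(rbind, lapply(truth$planted_regulons, function(r)
    data.frame(tf = r$tf, target = r$targets, stringsAsFactors = FALSE)))
}

#' Ligand-receptor reference covering planted and decoy pairs
#'
#' @param truth a `synthetic_truth`.
#' @return an [lr_reference()] table listing each planted (ligand, receptor)
#'   pair and one pair per decoy receptor/ligand.
#' @export
truth_lr_reference <- function(truth) {
  p <- truth$generator_params
  lig <- c(truth$planted_links$ligand,
           if (p$n_decoy_ligands > 0) sprintf("DLIG%03d", seq_len(min(p$n_decoy_ligands, p$n_decoy_receptors))))
  rec <- c(truth$planted_links$receptor,
           if (p$n_decoy_receptors > 0) sprintf("DREC%03d", seq_len(min(p$n_decoy_ligands, p$n_decoy_receptors))))
  lr_reference(sprintf("pair%03d", seq_along(lig)), lig, rec)
}
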