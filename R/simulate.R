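#' Configure a two-group RNA-seq simulation
#'
#' Builds and validates the parameter set for [simulate_dataset()]. The
#' defaults emulate the study design the package targets: a 6 vs 6
#' two-group bulk experiment over ~12,000 genes, a minority of
#' differentially expressed (DE) genes at 1.5--4.5-fold, a 699-gene
#' "mitoproteome" set whose DE directions are skewed 475:224 towards the
#' HFE group, and a few regulators whose co-expression to their targets
#' flips sign between groups while the regulator itself is not DE.
#'
#' @param n_genes number of genes.
#' @param n_per_group samples per group (HFE and LFE).
#' @param n_regulators number of genes designated as regulators
#'   (transcription factors); regulators are never planted as DE.
#' @param n_rewired number of regulators with planted differential wiring.
#' @param de_fraction fraction of non-regulator, non-mito genes planted DE.
#' @param fold_change_range linear fold-change range for planted DE genes.
#' @param mito_set_size size of the designated mitoproteome gene set; every
#'   member is planted DE with a direction drawn from `mito_up_fraction`.
#' @param mito_up_fraction probability a mito-set gene is up in HFE
#'   (default 475/699, the skew the analysis is designed to detect).
#' @param mito_fold_range linear fold-change range for the mito set; kept
#'   modest (default 1.1--1.5) because the mitoproteome shift is a subtle
#'   coherent skew, not extreme DE.
#' @param wiring_strength coefficient of the latent regulator signal on its
#'   targets' log-means in the wired condition, in \[0, 1\].
#' @param dispersion negative-binomial overdispersion phi
#'   (variance = mu + phi * mu^2); default 0.01, the canonical biological
#'   coefficient of variation (~0.1) for genetically identical organisms,
#'   matching a single inbred line.
#' @param library_size_range range of per-sample library sizes (uniform);
#'   default 60--75 million reads, the depth of the emulated study.
#' @param noise_sd SD of optional extra Gaussian noise on the log2-mean
#'   scale (default 0 so a non-DE gene's marginal is exactly NB).
#' @param lfe_noise_factor multiplier on `noise_sd` for LFE samples, used
#'   to simulate a noisier group.
#' @param rewire_mode `"sign_flip"` (+w in HFE, -w in LFE; the default,
#'   maximising differential co-expression) or `"on_off"` (+w vs 0).
#' @param fe_mean_hfe,fe_mean_lfe feed-efficiency phenotype means of the
#'   two groups (g gain / g feed), recorded as study-design constants; the
#'   HFE/LFE contrast is `fe_mean_hfe / fe_mean_lfe` (~1.4-fold).
#' @param rng_seed integer seed; identical config + seed gives
#'   byte-identical output.
#'
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 12800,
                       n_per_group = 6,
                       n_regulators = 200,
                       n_rewired = 3,
                       de_fraction = 0.05,
                       fold_change_range = c(1.5, 4.5),
                       mito_set_size = 699,
                       mito_up_fraction = 475 / 699,
                       mito_fold_range = c(1.1, 1.5),
                       wiring_strength = 0.8,
                       dispersion = 0.01,
                       library_size_range = c(6e7, 7.5e7),
                       noise_sd = 0,
                       lfe_noise_factor = 1,
                       rewire_mode = c("sign_flip", "on_off"),
                       fe_mean_hfe = 0.65,
                       fe_mean_lfe = 0.46,
                       rng_seed = 1L) {
  rewire_mode <- match.arg(rewire_mode)
  cfg <- list(
    n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
    n_regulators = as.integer(n_regulators), n_rewired = as.integer(n_rewired),
    de_fraction = de_fraction, fold_change_range = fold_change_range,
    mito_set_size = as.integer(mito_set_size),
    mito_up_fraction = mito_up_fraction, mito_fold_range = mito_fold_range,
    wiring_strength = wiring_strength, dispersion = dispersion,
    library_size_range = library_size_range,
    noise_sd = noise_sd, lfe_noise_factor = lfe_noise_factor,
    rewire_mode = rewire_mode,
    fe_mean_hfe = fe_mean_hfe, fe_mean_lfe = fe_mean_lfe,
    rng_seed = as.integer(rng_seed)
  )
  pos_int <- function(x, field) {
    if (length(x) != 1 || is.na(x) || x < 1) {
      stop("`", field, "` must be a positive integer")
    }
  }
  pos_int(cfg$n_genes, "n_genes")
  pos_int(cfg$n_per_group, "n_per_group")
  pos_int(cfg$n_regulators, "n_regulators")
  pos_int(cfg$mito_set_size, "mito_set_size")
  if (cfg$n_rewired < 0 || cfg$n_rewired > cfg$n_regulators) {
    stop("`n_rewired` must be between 0 and n_regulators")
  }
  if (cfg$de_fraction <= 0 || cfg$de_fraction >= 1) {
    stop("`de_fraction` must be in (0, 1)")
  }
  if (cfg$de_fraction * cfg$n_genes < 2) {
    stop("`de_fraction` too small: de_fraction * n_genes must be >= 2")
  }
  if (length(cfg$fold_change_range) != 2 || any(cfg$fold_change_range <= 0) ||
      diff(cfg$fold_change_range) < 0) {
    stop("`fold_change_range` must be an increasing pair of positive reals")
  }
  if (length(cfg$mito_fold_range) != 2 || any(cfg$mito_fold_range <= 0) ||
      diff(cfg$mito_fold_range) < 0) {
    stop("`mito_fold_range` must be an increasing pair of positive reals")
  }
  if (cfg$mito_set_size > cfg$n_genes) {
    stop("`mito_set_size` must not exceed n_genes")
  }
  if (cfg$mito_set_size + cfg$n_regulators > cfg$n_genes) {
    stop("`mito_set_size` plus n_regulators must not exceed n_genes")
  }
  if (cfg$mito_up_fraction <= 0 || cfg$mito_up_fraction >= 1) {
    stop("`mito_up_fraction` must be in (0, 1)")
  }
  if (cfg$wiring_strength < 0 || cfg$wiring_strength > 1) {
    stop("`wiring_strength` must be in [0, 1]")
  }
  if (cfg$dispersion <= 0) stop("`dispersion` must be a positive real")
  if (length(cfg$library_size_range) != 2 || any(cfg$library_size_range < 1) ||
      diff(cfg$library_size_range) < 0) {
    stop("`library_size_range` must be an increasing pair of positive sizes")
  }
  if (cfg$noise_sd < 0) stop("`noise_sd` must be non-negative")
  if (cfg$lfe_noise_factor < 0) stop("`lfe_noise_factor` must be non-negative")
  structure(cfg, class = "sim_config")
}

#' Simulate a two-group count matrix with planted structure
#'
#' Draws baseline gene log2-means from Normal(4, 2) on an RPM-like scale,
#' plants (i) DE genes whose HFE mean is multiplied by a fold change drawn
#' from `fold_change_range` in a random direction, (ii) a mito set whose
#' members are DE with direction up-in-HFE with probability
#' `mito_up_fraction`, and (iii) rewired regulators: each receives a
#' standard-normal latent signal per sample added to its own log-mean (so
#' its group means stay equal -- not DE) and to its targets' log-means
#' with coefficient `+wiring_strength` in HFE and `-wiring_strength`
#' (sign flip) or `0` (`"on_off"`) in LFE. Targets are a disjoint random share of
#' the strongly DE genes, direction-coherent per rewired regulator. Counts are drawn
#' negative-binomial with overdispersion `dispersion`, scaled by uniform
#' per-sample library sizes.
#'
#' @param config a [sim_config()] object.
#' @return An object of class `sim_dataset`: a list with `counts` (integer
#'   gene x sample matrix), `groups` (named factor, HFE/LFE), `regulators`
#'   (character), `truth` (list: `de` data frame with gene/direction/fold,
#'   `mito`, `rewired`, `targets_of`), `mu` (expected count matrix) and
#'   `config`.
#' @export
simulate_dataset <- function(config) {
  if (!inherits(config, "sim_config")) {
    stop("`config` must be created by sim_config()")
  }
  set.seed(config$rng_seed)
  n_g <- config$n_genes
  n_s <- 2L * config$n_per_group
  gene_ids <- sprintf("g%05d", seq_len(n_g))
  sample_ids <- c(sprintf("HFE_%02d", seq_len(config$n_per_group)),
                  sprintf("LFE_%02d", seq_len(config$n_per_group)))
  groups <- factor(rep(GROUP_LEVELS, each = config$n_per_group),
                   levels = GROUP_LEVELS)
  names(groups) <- sample_ids
  hfe <- groups == "HFE"

  # baseline abundance on the log2 RPM-like scale
  base <- stats::rnorm(n_g, mean = 4, sd = 2)
  logmu <- matrix(base, nrow = n_g, ncol = n_s,
                  dimnames = list(gene_ids, sample_ids))

  # role assignment: regulators first (never DE), then mito set, then the
  # remaining DE genes
  reg_idx <- sample.int(n_g, config$n_regulators)
  # a regulator must be detected in every sample to be scorable: floor its
  # baseline at 32 RPM so the completeness filter keeps it even when the
  # latent wiring signal pulls individual samples low
  logmu[reg_idx, ] <- pmax(logmu[reg_idx, ], 5)
  rewired_idx <- if (config$n_rewired > 0) reg_idx[seq_len(config$n_rewired)] else integer(0)
  non_reg <- setdiff(seq_len(n_g), reg_idx)
  mito_idx <- sample(non_reg, config$mito_set_size)
  n_extra_de <- max(2L, round(config$de_fraction * n_g))
  pool <- setdiff(non_reg, mito_idx)
  if (n_extra_de > length(pool)) {
    stop("`de_fraction` too large for the remaining non-regulator genes")
  }
  extra_de_idx <- sample(pool, n_extra_de)

  de_idx <- c(mito_idx, extra_de_idx)
  dir_mito <- ifelse(stats::runif(length(mito_idx)) < config$mito_up_fraction, 1L, -1L)
  dir_extra <- sample(c(1L, -1L), length(extra_de_idx), replace = TRUE)
  de_dir <- c(dir_mito, dir_extra)
  # the mito set's shift is subtle (a coherent skew, not extreme DE); the
  # remaining DE genes carry the strong fold changes
  de_fold <- c(
    stats::runif(length(mito_idx), config$mito_fold_range[1],
                 config$mito_fold_range[2]),
    stats::runif(length(extra_de_idx), config$fold_change_range[1],
                 config$fold_change_range[2])
  )
  # HFE mean multiplied by fold^direction
  logmu[de_idx, hfe] <- logmu[de_idx, hfe] + de_dir * log2(de_fold)

  # differential wiring: latent per-sample regulator signal. Each rewired
  # regulator drives a direction-coherent, disjoint share of the planted
  # DE genes (a regulator whose activity differs between groups moves its
  # targets coherently; this is also what makes the signed RIF sums
  # informative rather than self-cancelling).
  targets_of <- list()
  if (config$n_rewired > 0) {
    # latent pathway activities: one standard-normal vector per rewired
    # regulator; within each group the vectors are centred, orthogonalised
    # and scaled to unit SD (uncorrelated pathway activities -- at n = 6
    # chance correlation between raw draws would confound the planted
    # clusters with each other)
    Z <- matrix(stats::rnorm(n_s * config$n_rewired), n_s)
    if (config$n_per_group > config$n_rewired + 1) {
      for (gi in list(hfe, !hfe)) {
        q <- qr.Q(qr(cbind(1, Z[gi, , drop = FALSE])))[, -1, drop = FALSE]
        Z[gi, ] <- sweep(q, 2, apply(q, 2, stats::sd), "/")
      }
    } else if (config$n_per_group >= 2) {
      for (gi in list(hfe, !hfe)) {
        Z[gi, ] <- scale(Z[gi, , drop = FALSE])
      }
    }
    reg_dir <- rep_len(c(1L, -1L), config$n_rewired)
    # every regulator targets the same *fraction* of its direction pool
    # (1 / the most crowded direction), so each planted cluster claims a
    # comparable slice of the extreme-PIF target set; untargeted DE genes
    # keep absorbing the remaining extreme slots
    n_max <- max(tabulate(match(reg_dir, c(1L, -1L))))
    shares <- vector("list", config$n_rewired)
    for (d in c(1L, -1L)) {
      ks <- which(reg_dir == d)
      if (length(ks) == 0) next
      pool <- sample(extra_de_idx[dir_extra == d])
      share_size <- floor(length(pool) / n_max)
      if (share_size < 1) stop("too few DE genes to assign regulator targets")
      for (i in seq_along(ks)) {
        shares[[ks[i]]] <- pool[seq.int((i - 1L) * share_size + 1L, i * share_size)]
      }
    }
    for (k in seq_len(config$n_rewired)) {
      r <- rewired_idx[k]
      tgt <- shares[[k]]
      z <- Z[, k]
      logmu[r, ] <- logmu[r, ] + z
      w_lfe <- if (config$rewire_mode == "sign_flip") -config$wiring_strength else 0
      logmu[tgt, hfe] <- logmu[tgt, hfe] +
        config$wiring_strength * rep(z[hfe], each = length(tgt))
      logmu[tgt, !hfe] <- logmu[tgt, !hfe] +
        w_lfe * rep(z[!hfe], each = length(tgt))
      targets_of[[gene_ids[r]]] <- gene_ids[sort(tgt)]
    }
  }

  if (config$noise_sd > 0) {
    sds <- ifelse(hfe, config$noise_sd, config$noise_sd * config$lfe_noise_factor)
    logmu <- logmu + matrix(stats::rnorm(n_g * n_s, sd = rep(sds, each = n_g)),
                            nrow = n_g)
  }

  lib <- round(stats::runif(n_s, config$library_size_range[1],
                            config$library_size_range[2]))
  mu <- 2^logmu * rep(lib / 1e6, each = n_g)
  counts <- matrix(stats::rnbinom(n_g * n_s, mu = mu, size = 1 / config$dispersion),
                   nrow = n_g, dimnames = dimnames(logmu))
  storage.mode(counts) <- "integer"

  structure(list(
    counts = counts,
    groups = groups,
    regulators = gene_ids[sort(reg_idx)],
    truth = list(
      de = data.frame(gene = gene_ids[de_idx],
                      direction = de_dir,
                      fold = de_fold,
                      stringsAsFactors = FALSE),
      mito = gene_ids[sort(mito_idx)],
      rewired = gene_ids[sort(rewired_idx)],
      targets_of = targets_of
    ),
    mu = mu,
    config = config
  ), class = "sim_dataset")
}

#' Write a simulated dataset to plain-text files
#'
#' Emits `counts.tsv` (genes as rows, first column `gene`, one column per
#' sample), `groups.tsv` (sample_id, group), `regulators.txt`,
#' `truth_mito.txt` and `truth_rewired.txt` (newline-delimited gene ids;
#' empty sets give zero-byte bodies) and `truth_de.tsv` (gene, direction,
#' fold). All files round-trip through [read_counts()], [read_groups()]
#' and [read_gene_set()].
#'
#' @param ds a `sim_dataset`.
#' @param directory output directory, created if absent.
#' @return Invisibly, the named character vector of file paths.
#' @export
write_dataset <- function(ds, directory) {
  stopifnot(inherits(ds, "sim_dataset"))
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory: ", directory)
  }
  paths <- c(
    counts = file.path(directory, "counts.tsv"),
    groups = file.path(directory, "groups.tsv"),
    regulators = file.path(directory, "regulators.txt"),
    truth_mito = file.path(directory, "truth_mito.txt"),
    truth_rewired = file.path(directory, "truth_rewired.txt"),
    truth_de = file.path(directory, "truth_de.tsv")
  )
  write_matrix_tsv(ds$counts, paths[["counts"]], id_col = "gene")
  utils::write.table(
    data.frame(sample_id = names(ds$groups), group = as.character(ds$groups)),
    paths[["groups"]], sep = "\t", quote = FALSE, row.names = FALSE
  )
  writeLines(ds$regulators, paths[["regulators"]])
  writeLines(ds$truth$mito, paths[["truth_mito"]])
  writeLines(ds$truth$rewired, paths[["truth_rewired"]])
  utils::write.table(ds$truth$de, paths[["truth_de"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
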