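test_that("sim_config validates fields and rejects infeasible configs", {
  cfg <- sim_config()
  expect_s3_class(cfg, "sim_config")
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(n_rewired = 300, n_regulators = 200), "n_rewired")
  expect_error(sim_config(de_fraction = 1.2), "de_fraction")
  expect_error(sim_config(mito_set_size = 20000, n_genes = 1000), "mito_set_size")
  expect_error(sim_config(fold_change_range = c(3, 2)), "fold_change_range")
  expect_error(sim_config(wiring_strength = 1.5), "wiring_strength")
  expect_error(sim_config(dispersion = 0), "dispersion")
})

test_that("identical config and seed give byte-identical output", {
  cfg <- sim_config(n_genes = 500, mito_set_size = 50, n_regulators = 20,
                    rng_seed = 42)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$counts, b$counts)
  expect_identical(a$truth, b$truth)
})

test_that("simulated dataset satisfies its structural invariants", {
  ds <- default_run()$ds
  expect_true(all(ds$counts >= 0))
  expect_type(ds$counts, "integer")
  all_truth <- c(ds$truth$de$gene, ds$truth$mito, ds$truth$rewired)
  expect_true(all(all_truth %in% rownames(ds$counts)))
  expect_true(all(ds$truth$rewired %in% ds$regulators))
  expect_setequal(unique(ds$truth$de$direction), c(1L, -1L))
  # target sets are disjoint between rewired regulators
  tg <- ds$truth$targets_of
  expect_length(unique(unlist(tg)), length(unlist(tg)))
})

test_that("null config gives equal group-wise expected counts", {
  cfg <- sim_config(n_genes = 300, n_per_group = 4, n_regulators = 5,
                    n_rewired = 0, mito_set_size = 5, de_fraction = 2 / 300,
                    fold_change_range = c(1, 1), mito_fold_range = c(1, 1),
                    wiring_strength = 0,
                    library_size_range = c(1e6, 1e6), rng_seed = 5)
  ds <- simulate_dataset(cfg)
  mu_h <- rowMeans(ds$mu[, as.character(ds$groups) == "HFE"])
  mu_l <- rowMeans(ds$mu[, as.character(ds$groups) == "LFE"])
  expect_equal(mu_h, mu_l, tolerance = 1e-12)
})

test_that("mito up-in-HFE fraction sits inside the exact binomial 99% CI", {
  cfg <- sim_config(n_genes = 2000, mito_set_size = 699,
                    mito_up_fraction = 475 / 699, n_regulators = 20,
                    rng_seed = 11)
  ds <- simulate_dataset(cfg)
  tr <- ds$truth$de
  n_up <- sum(tr$direction[tr$gene %in% ds$truth$mito] == 1L)
  ci <- stats::binom.test(round(699 * 475 / 699), 699,
                          conf.level = 0.99)$conf.int
  expect_gte(n_up / 699, ci[1])
  expect_lte(n_up / 699, ci[2])
})

test_that("rewired regulator-target correlations flip sign between groups", {
  # large-sample check: n_per_group = 20, >= 50 targets
  opp <- vapply(1:5, function(s) {
    cfg <- sim_config(n_genes = 3000, n_per_group = 20, mito_set_size = 300,
                      n_regulators = 50, n_rewired = 2, rng_seed = s)
    ds <- simulate_dataset(cfg)
    em <- suppressWarnings(normalize_counts(ds$counts))
    mean(vapply(ds$truth$rewired, function(rg) {
      tgt <- intersect(ds$truth$targets_of[[rg]], rownames(em))
      expect_gte(length(tgt), 50)
      cc <- condition_correlations(em, ds$groups, rg, tgt)
      mean(sign(cc$r_hfe) != sign(cc$r_lfe))
    }, numeric(1)))
  }, numeric(1))
  expect_gte(mean(opp), 0.95)
})

test_that("non-rewired regulators are not DE at n = 50 per group", {
  cfg <- sim_config(n_per_group = 50, rng_seed = 3)
  ds <- simulate_dataset(cfg)
  em <- suppressWarnings(normalize_counts(ds$counts))
  nonrew <- intersect(setdiff(ds$regulators, ds$truth$rewired), rownames(em))
  g <- ds$groups
  lr <- abs(log2(rowMeans(2^em[nonrew, g == "HFE"]) /
                   rowMeans(2^em[nonrew, g == "LFE"])))
  expect_lt(stats::median(lr), 0.1)
})

test_that("a non-DE gene's counts pass a chi-squared NB goodness-of-fit", {
  cfg <- sim_config(n_genes = 60, n_per_group = 400, n_regulators = 5,
                    n_rewired = 0, mito_set_size = 5, de_fraction = 0.05,
                    library_size_range = c(5e6, 5e6), dispersion = 0.05,
                    rng_seed = 7)
  ds <- simulate_dataset(cfg)
  cand <- setdiff(rownames(ds$counts), c(ds$truth$de$gene, ds$regulators))
  gene <- cand[which.min(abs(ds$mu[cand, 1] - 100))]
  x <- ds$counts[gene, ]
  mu <- ds$mu[gene, 1]
  size <- 1 / cfg$dispersion
  br <- unique(stats::qnbinom(seq(0, 1, length.out = 12), mu = mu, size = size))
  bins <- cut(x, breaks = c(-1, br[-length(br)], Inf))
  expp <- diff(c(0, stats::pnbinom(c(br[-length(br)], Inf),
                                   mu = mu, size = size)))
  obs <- as.vector(table(bins))
  keep <- expp * length(x) >= 5
  chi <- sum((obs[keep] - length(x) * expp[keep])^2 / (length(x) * expp[keep]))
  p <- stats::pchisq(chi, df = sum(keep) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
})

test_that("write_dataset round-trips through the readers", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 200, mito_set_size = 20, n_regulators = 10,
                    n_rewired = 2, rng_seed = 9)
  ds <- simulate_dataset(cfg)
  write_dataset(ds, dir)
  back <- read_dataset(dir)
  expect_identical(back$counts, ds$counts)
  expect_identical(as.character(back$groups), as.character(ds$groups))
  expect_identical(back$regulators, ds$regulators)
  expect_identical(back$truth$mito, ds$truth$mito)
  expect_identical(back$truth$rewired, ds$truth$rewired)
  expect_equal(back$truth$de$fold, ds$truth$de$fold, tolerance = 1e-10)
})

test_that("empty rewired set writes a zero-byte body and reads back empty", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_genes = 200, mito_set_size = 20, n_regulators = 10,
                    n_rewired = 0, rng_seed = 2)
  ds <- simulate_dataset(cfg)
  paths <- write_dataset(ds, dir)
  expect_identical(ds$truth$rewired, character(0))
  expect_identical(read_gene_set(paths[["truth_rewired"]]), character(0))
})
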