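test_that("condition_correlations recovers exact correlations", {
  # regulator identical to one target, anti-proportional to another
  s <- c(1, 2, 3, 4, 5, 6)
  em <- rbind(reg = c(s, 6:1), t1 = c(s, 6:1), t2 = c(-s, 1:6))
  colnames(em) <- sprintf("s%02d", 1:12)
  g <- rep(c("HFE", "LFE"), each = 6)
  cc <- condition_correlations(em, g, "reg", c("t1", "t2"))
  expect_equal(unname(cc$r_hfe["reg", ]), c(1, -1), tolerance = 1e-12)
  expect_equal(unname(cc$r_lfe["reg", ]), c(1, -1), tolerance = 1e-12)
  # hand-computed covariance/SD ratio on a 6-sample pair
  x <- c(2, 4, 4, 7, 9, 10)
  y <- c(1, 3, 2, 6, 6, 11)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  em2 <- rbind(r = c(x, rev(x)), t = c(y, rev(y)))
  colnames(em2) <- sprintf("s%02d", 1:12)
  cc2 <- condition_correlations(em2, g, "r", "t")
  expect_equal(cc2$r_hfe["r", "t"], r_hand, tolerance = 1e-12)
})

test_that("condition_correlations validates inputs and handles zero variance", {
  em <- matrix(rnorm(24), 4, 6,
               dimnames = list(c("a", "b", "c", "d"), sprintf("s%d", 1:6)))
  g <- rep(c("HFE", "LFE"), each = 3)
  expect_error(condition_correlations(em, g, "a", "nope"), "nope")
  expect_error(
    condition_correlations(em[, 1:4], c("HFE", "HFE", "LFE", "LFE"), "a", "b"),
    ">= 3 samples")
  em["b", 1:3] <- 5 # constant within HFE
  expect_warning(cc <- condition_correlations(em, g, "b", c("a", "c")),
                 "zero-variance")
  expect_equal(unname(cc$r_hfe["b", ]), c(0, 0))
})

test_that("RIF metrics match direct substitution into their formulas", {
  # single target with x = 5, d = 2, DC = 1 -> RIF1 = 10
  inputs <- list(targets = "t", regulators = "r",
                 x = c(t = 5), d = c(t = 2),
                 x_hfe = c(t = 6), x_lfe = c(t = 4),
                 r_hfe = matrix(1, 1, 1, dimnames = list("r", "t")),
                 r_lfe = matrix(0, 1, 1, dimnames = list("r", "t")))
  inputs$dc <- inputs$r_hfe - inputs$r_lfe
  expect_equal(unname(compute_rif1(inputs)), 10)
  # RIF2 with x_hfe = 4, r_hfe = 0.5, x_lfe = 2, r_lfe = 0.5 -> 3
  inputs2 <- inputs
  inputs2$x_hfe <- c(t = 4)
  inputs2$x_lfe <- c(t = 2)
  inputs2$r_hfe[] <- 0.5
  inputs2$r_lfe[] <- 0.5
  inputs2$dc <- inputs2$r_hfe - inputs2$r_lfe
  expect_equal(unname(compute_rif2(inputs2)), (4 * 0.5)^2 - (2 * 0.5)^2)
  # no rewiring: DC = 0 -> RIF1 = 0
  inputs3 <- inputs
  inputs3$r_lfe <- inputs3$r_hfe
  inputs3$dc <- inputs3$r_hfe - inputs3$r_lfe
  expect_equal(unname(compute_rif1(inputs3)), 0)
  # doubling DC quadruples RIF1
  inputs4 <- inputs
  inputs4$dc <- 2 * inputs$dc
  expect_equal(compute_rif1(inputs4), 4 * compute_rif1(inputs))
  # negating all correlations leaves RIF2 unchanged
  inputs5 <- inputs2
  inputs5$r_hfe <- -inputs5$r_hfe
  inputs5$r_lfe <- -inputs5$r_lfe
  expect_equal(compute_rif2(inputs5), compute_rif2(inputs2))
})

test_that("RIF metrics match the naive double-loop oracle on random instances", {
  for (seed in 1:25) {
    inputs <- random_rif_instance(seed)
    oracle <- naive_rif(inputs)
    expect_equal(compute_rif1(inputs), oracle$rif1, tolerance = 1e-10)
    expect_equal(compute_rif2(inputs), oracle$rif2, tolerance = 1e-10)
  }
})

test_that("standardize_and_flag z-scores exactly and flags outliers", {
  raw1 <- stats::setNames(c(0.1, -0.2, 0.05, 0.02, -0.1, 0.15, -0.05, 0.08,
                            -0.12, 10), sprintf("r%02d", 1:10))
  raw2 <- stats::setNames(seq(-0.2, 0.25, length.out = 10),
                          sprintf("r%02d", 1:10))
  tab <- standardize_and_flag(raw1, raw2)
  expect_equal(tab$rif1_z, (raw1 - mean(raw1)) / stats::sd(raw1),
               tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(mean(tab$rif1_z), 0, tolerance = 1e-9)
  expect_equal(stats::sd(tab$rif1_z), 1, tolerance = 1e-9)
  expect_identical(tab$outlier, c(rep(FALSE, 9), TRUE))
  # all-equal raw scores: no outliers, zero-SD warning per metric
  expect_warning(
    expect_warning(tab0 <- standardize_and_flag(rep(1, 3), rep(2, 3)),
                   "zero SD"),
    "zero SD")
  expect_false(any(tab0$outlier))
  expect_error(standardize_and_flag(1, numeric(0)), ">= 2")
})

test_that("self-pairs can be excluded via the flag", {
  set.seed(8)
  em <- matrix(rnorm(5 * 8, 6), 5, 8,
               dimnames = list(sprintf("t%d", 1:5), sprintf("s%d", 1:8)))
  g <- rep(c("HFE", "LFE"), each = 4)
  # regulator t1 is also a target
  inc <- rif_inputs(em, g, c("t1", "t2"), c("t1", "t3"))
  exc <- rif_inputs(em, g, c("t1", "t2"), c("t1", "t3"), exclude_self = TRUE)
  expect_equal(inc$r_hfe["t1", "t1"], 1, tolerance = 1e-12)
  expect_identical(exc$r_hfe["t1", "t1"], 0)
  expect_identical(exc$r_hfe["t2", ], inc$r_hfe["t2", ])
})

test_that("most regulators sit near zero under the default simulation", {
  r <- default_run()
  sel <- select_extreme_pif(r$det, 0.05)
  regs <- intersect(r$ds$regulators, rownames(r$em))
  rif <- suppressWarnings(
    compute_rif(r$em, r$ds$groups, regs, c(sel$up, sel$down)))
  expect_lte(stats::median(abs(rif$rif1_z)), 1)
  expect_lte(stats::median(abs(rif$rif2_z)), 1)
  # planted rewired regulators are flagged in this run
  expect_true(all(r$ds$truth$rewired %in% rif$regulator[rif$outlier]))
})
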