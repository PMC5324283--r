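# Shared fixtures and independent oracles used across the suite.

# A tiny deterministic count matrix with named genes/samples.
toy_counts <- function() {
  m <- matrix(
    c(10L, 20L, 30L, 40L,
      5L,  0L,  8L,  2L,
      100L, 90L, 110L, 95L,
      1L,  2L,  3L,  4L,
      7L,  7L,  0L,  7L),
    nrow = 5, byrow = TRUE,
    dimnames = list(sprintf("g%d", 1:5), c("HFE_1", "HFE_2", "LFE_1", "LFE_2"))
  )
  m
}

toy_groups <- function() {
  stats::setNames(c("HFE", "HFE", "LFE", "LFE"),
                  c("HFE_1", "HFE_2", "LFE_1", "LFE_2"))
}

# Default simulation run shared by several files (computed once per
# test session).
default_run <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ds <- simulate_dataset(sim_config(rng_seed = 1))
      em <- suppressWarnings(normalize_counts(ds$counts))
      det <- compute_de(em, ds$groups)
      cache <<- list(ds = ds, em = em, det = det)
    }
    cache
  }
})

# Independent exact two-sided binomial p-value by exhaustive PMF
# enumeration (minlike definition: sum of all outcome probabilities not
# exceeding the observed outcome's probability).
enum_binom_p <- function(k, n) {
  pmf <- stats::dbinom(0:n, n, 0.5)
  sum(pmf[pmf <= pmf[k + 1] * (1 + 1e-7)])
}

# Naive double-loop RIF oracle, written directly from the definitions.
naive_rif <- function(inputs) {
  n_de <- length(inputs$targets)
  rif1 <- rif2 <- stats::setNames(numeric(length(inputs$regulators)),
                                  inputs$regulators)
  for (r in inputs$regulators) {
    s1 <- s2 <- 0
    for (j in inputs$targets) {
      dc <- inputs$r_hfe[r, j] - inputs$r_lfe[r, j]
      s1 <- s1 + inputs$x[j] * inputs$d[j] * dc^2
      s2 <- s2 + (inputs$x_hfe[j] * inputs$r_hfe[r, j])^2 -
        (inputs$x_lfe[j] * inputs$r_lfe[r, j])^2
    }
    rif1[r] <- s1 / n_de
    rif2[r] <- s2 / n_de
  }
  list(rif1 = rif1, rif2 = rif2)
}

# Random small RIF instance for oracle comparisons.
random_rif_instance <- function(seed) {
  set.seed(seed)
  n_reg <- sample(2:5, 1)
  n_de <- sample(2:10, 1)
  n_per <- sample(3:6, 1)
  n_g <- n_reg + n_de
  em <- matrix(stats::rnorm(n_g * 2 * n_per, mean = 6, sd = 2), nrow = n_g,
               dimnames = list(sprintf("t%02d", seq_len(n_g)),
                               sprintf("s%02d", seq_len(2 * n_per))))
  groups <- stats::setNames(rep(c("HFE", "LFE"), each = n_per), colnames(em))
  regulators <- rownames(em)[seq_len(n_reg)]
  targets <- rownames(em)[n_reg + seq_len(n_de)]
  rif_inputs(em, groups, regulators, targets)
}
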