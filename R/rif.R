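# Regulatory Impact Factor (RIF) scoring. A regulator whose activity is
# controlled post-transcriptionally can rewire its targets between two
# conditions without being differentially expressed itself. RIF detects
# this from condition-specific co-expression: for each regulator r and
# extreme-PIF target j, with within-group Pearson correlations r_hfe and
# r_lfe and differential co-expression DC = r_hfe - r_lfe,
#
#   RIF1_r = (1/n_DE) * sum_j x_j * d_j * DC_rj^2
#   RIF2_r = (1/n_DE) * sum_j [ (x_hfe_j * r_hfe_rj)^2 - (x_lfe_j * r_lfe_rj)^2 ]
#
# where x_j is the target's average expression over all samples, d_j its
# DE (HFE minus LFE) and x_hfe_j / x_lfe_j its group means.

#' Condition-specific regulator-target correlations
#'
#' Pearson correlation between every regulator and every target, computed
#' within each group separately. A pair involving a zero-variance vector
#' within a group gets r = 0 with a warning reporting the number of
#' affected pairs (this keeps the differential co-expression defined).
#'
#' @param em expression matrix (gene x sample).
#' @param groups sample group factor/labels; >= 3 samples per group.
#' @param regulators,targets gene id vectors; all must be rows of `em`.
#' @return List of two regulator x target matrices, `r_hfe` and `r_lfe`.
#' @export
condition_correlations <- function(em, groups, regulators, targets) {
  g <- align_groups(groups, colnames(em))
  if (any(table(g) < 3)) stop("need >= 3 samples per group for correlations")
  absent <- setdiff(c(regulators, targets), rownames(em))
  if (length(absent) > 0) {
    stop("ids absent from the expression matrix: ",
         paste(absent, collapse = ", "))
  }
  one_group <- function(level) {
    sub <- em[, g == level, drop = FALSE]
    r <- suppressWarnings(stats::cor(t(sub[regulators, , drop = FALSE]),
                                     t(sub[targets, , drop = FALSE])))
    n_bad <- sum(is.na(r))
    if (n_bad > 0) {
      warning(n_bad, " zero-variance pair(s) in group ", level,
              ": correlation set to 0")
      r[is.na(r)] <- 0
    }
    r
  }
  list(r_hfe = one_group("HFE"), r_lfe = one_group("LFE"))
}

#' Assemble the inputs for the RIF metrics
#'
#' @param em expression matrix.
#' @param groups sample group factor/labels.
#' @param regulators regulator gene ids.
#' @param targets extreme-PIF target gene ids.
#' @param exclude_self zero out a regulator's pairing with itself when it
#'   is also a target (default FALSE: under a sign-agreeing correlation of
#'   1 in both groups a self-pair contributes DC = 0 to RIF1 anyway).
#' @return List with targets, regulators, x (average expression over all
#'   samples), d (DE), x_hfe, x_lfe, r_hfe, r_lfe and dc.
#' @export
rif_inputs <- function(em, groups, regulators, targets, exclude_self = FALSE) {
  if (length(targets) == 0) stop("no target genes (n_DE = 0)")
  g <- align_groups(groups, colnames(em))
  cors <- condition_correlations(em, g, regulators, targets)
  if (exclude_self) {
    self <- intersect(regulators, targets)
    for (id in self) {
      cors$r_hfe[id, id] <- 0
      cors$r_lfe[id, id] <- 0
    }
  }
  tm <- em[targets, , drop = FALSE]
  x_hfe <- rowMeans(tm[, g == "HFE", drop = FALSE])
  x_lfe <- rowMeans(tm[, g == "LFE", drop = FALSE])
  list(targets = targets, regulators = regulators,
       x = rowMeans(tm), d = x_hfe - x_lfe,
       x_hfe = x_hfe, x_lfe = x_lfe,
       r_hfe = cors$r_hfe, r_lfe = cors$r_lfe,
       dc = cors$r_hfe - cors$r_lfe)
}

#' RIF1: abundance- and DE-weighted squared differential co-expression
#'
#' @param inputs a [rif_inputs()] list.
#' @return Named numeric vector, one raw RIF1 score per regulator.
#' @export
compute_rif1 <- function(inputs) {
  n_de <- length(inputs$targets)
  if (n_de == 0) stop("n_DE = 0")
  drop(inputs$dc^2 %*% (inputs$x * inputs$d)) / n_de
}

#' RIF2: difference of squared condition-weighted co-expression
#'
#' @param inputs a [rif_inputs()] list.
#' @return Named numeric vector, one raw RIF2 score per regulator.
#' @export
compute_rif2 <- function(inputs) {
  n_de <- length(inputs$targets)
  if (n_de == 0) stop("n_DE = 0")
  hfe <- sweep(inputs$r_hfe^2, 2, inputs$x_hfe^2, "*")
  lfe <- sweep(inputs$r_lfe^2, 2, inputs$x_lfe^2, "*")
  rowMeans(hfe - lfe)
}

#' Standardise RIF scores and flag outlier regulators
#'
#' z-scores each metric across regulators (mean 0, SD 1); a regulator is
#' flagged when |z| meets `threshold` on either metric. Most regulators of
#' a typical contrast sit near 0 on both axes; the flagged few are the
#' differentially connected candidates. A zero-SD raw metric gets z = 0
#' with a warning.
#'
#' @param rif1_raw,rif2_raw raw score vectors (same length >= 2, named by
#'   regulator).
#' @param threshold |z| cut-off, default 1.96. Not a significance claim:
#'   outliers are candidates for manual exploration.
#' @return Data frame regulator, rif1_raw, rif2_raw, rif1_z, rif2_z,
#'   outlier.
#' @export
standardize_and_flag <- function(rif1_raw, rif2_raw, threshold = 1.96) {
  if (length(rif1_raw) < 2 || length(rif1_raw) != length(rif2_raw)) {
    stop("need >= 2 regulators and equal-length score vectors")
  }
  zscore <- function(v, label) {
    s <- stats::sd(v)
    if (s == 0) {
      warning("zero SD in ", label, ": z-scores set to 0")
      return(rep(0, length(v)))
    }
    (v - mean(v)) / s
  }
  z1 <- zscore(rif1_raw, "rif1_raw")
  z2 <- zscore(rif2_raw, "rif2_raw")
  data.frame(
    regulator = names(rif1_raw) %||% as.character(seq_along(rif1_raw)),
    rif1_raw = unname(rif1_raw), rif2_raw = unname(rif2_raw),
    rif1_z = unname(z1), rif2_z = unname(z2),
    outlier = abs(z1) >= threshold | abs(z2) >= threshold,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Full RIF analysis of a normalised expression matrix
#'
#' Builds the inputs, computes both metrics and standardises them.
#'
#' @inheritParams rif_inputs
#' @param threshold outlier |z| cut-off (default 1.96).
#' @return A [standardize_and_flag()] table.
#' @export
compute_rif <- function(em, groups, regulators, targets, threshold = 1.96,
                        exclude_self = FALSE) {
  inputs <- rif_inputs(em, groups, regulators, targets, exclude_self)
  standardize_and_flag(compute_rif1(inputs), compute_rif2(inputs), threshold)
}
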