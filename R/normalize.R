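# Normalisation chain: completeness filter -> RPM -> log2 -> quantile,
# with a PCA check that the normalised data still separates the groups.

#' Keep genes detected in every sample
#'
#' RNA-seq count matrices carry no NA; a "missing value" is a zero count.
#' Retains exactly the genes whose count is positive in all samples,
#' preserving gene order; the sample axis is unchanged.
#'
#' @param counts integer gene x sample matrix.
#' @param missing a predicate on counts marking missing values
#'   (default: zero).
#' @return The filtered count matrix.
#' @export
filter_complete <- function(counts, missing = function(x) x == 0) {
  validate_counts(counts)
  keep <- rowSums(missing(counts)) == 0
  if (!any(keep)) stop("no complete genes")
  counts[keep, , drop = FALSE]
}

#' Reads-per-million scaling
#'
#' `rpm[g, s] = counts[g, s] / colsum[s] * 1e6`, with the denominator taken
#' from the matrix as provided (so RPM computed before filtering uses
#' totals over all detected genes).
#'
#' @param counts non-negative gene x sample matrix.
#' @return Real matrix whose columns each sum to 1e6.
#' @export
to_rpm <- function(counts) {
  cs <- colSums(counts)
  zero <- cs == 0
  if (any(zero)) {
    stop("zero library size for sample(s): ",
         paste(colnames(counts)[zero], collapse = ", "))
  }
  sweep(counts, 2, cs, "/") * 1e6
}

#' Log2 transform with pseudocount
#'
#' @param rpm real matrix.
#' @param pseudocount non-negative real added before the log (default 1,
#'   keeping the transform total on matrices containing zeros).
#' @return `log2(rpm + pseudocount)` elementwise.
#' @export
log2_transform <- function(rpm, pseudocount = 1) {
  shifted <- rpm + pseudocount
  if (any(shifted <= 0)) {
    bad <- which(shifted <= 0, arr.ind = TRUE)[1, ]
    stop("non-positive value at gene '", rownames(rpm)[bad[1]],
         "', sample '", colnames(rpm)[bad[2]], "' after pseudocount")
  }
  log2(shifted)
}

#' Quantile normalisation
#'
#' Classic rank-mean procedure: each sample's values are replaced by the
#' across-sample mean of the order statistics at the same rank, so every
#' sample ends with the identical empirical distribution. Ties receive the
#' mean of the rank-means they span. A single-sample matrix is returned
#' unchanged with a warning.
#'
#' @param m real matrix, no missing values.
#' @return Matrix of the same shape; sorted columns are identical.
#' @export
quantile_normalize <- function(m) {
  if (anyNA(m)) stop("quantile normalisation requires no missing values")
  if (ncol(m) < 2) {
    warning("single-sample matrix: quantile normalisation is a no-op")
    return(m)
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Run the full normalisation chain
#'
#' Fixed order: (completeness filter) -> RPM -> log2 -> quantile. By
#' default RPM denominators are the library totals over all detected genes
#' and the completeness filter is applied to the RPM matrix afterwards;
#' `filter_first = TRUE` filters the counts before computing totals.
#'
#' @param counts integer gene x sample matrix.
#' @param pseudocount passed to [log2_transform()].
#' @param filter_first filter before computing RPM denominators?
#' @return Normalised expression matrix with a `provenance` attribute
#'   listing the applied transforms.
#' @export
normalize_counts <- function(counts, pseudocount = 1, filter_first = FALSE) {
  validate_counts(counts)
  if (filter_first) {
    counts <- filter_complete(counts)
    rpm <- to_rpm(counts)
    prov <- c("filter_complete", "rpm")
  } else {
    keep <- rownames(filter_complete(counts))
    rpm <- to_rpm(counts)[keep, , drop = FALSE]
    prov <- c("rpm", "filter_complete")
  }
  em <- quantile_normalize(log2_transform(rpm, pseudocount))
  attr(em, "provenance") <- c(prov, "log2", "quantile")
  em
}

#' PCA check of group separability
#'
#' Centres genes (no unit-variance scaling), computes the top two sample
#' principal components and asks whether a linear boundary in PC1--PC2
#' separates the HFE and LFE groups with at most one misclassified sample.
#' The boundary is the linear discriminant fitted to the two groups; when
#' the within-group covariance is singular the nearest-group-centroid rule
#' is used instead.
#'
#' @param em expression matrix (gene x sample).
#' @param groups sample group factor/labels (HFE/LFE).
#' @param max_misclassified threshold for declaring separation (default 1).
#' @return List with `coords` (data frame sample/PC1/PC2/group),
#'   `misclassified` (count), and `separated` (logical).
#' @export
pca_group_check <- function(em, groups, max_misclassified = 1) {
  if (ncol(em) < 3) stop("PCA group check needs at least 3 samples")
  g <- align_groups(groups, colnames(em))
  if (any(table(g) < 2)) stop("need >= 2 samples per group")
  pc <- stats::prcomp(t(em), center = TRUE, scale. = FALSE)
  k <- min(2L, ncol(pc$x))
  coords <- pc$x[, seq_len(k), drop = FALSE]
  if (k == 1) coords <- cbind(coords, PC2 = 0)
  pred <- tryCatch({
    fit <- MASS::lda(coords, grouping = g)
    as.character(stats::predict(fit, coords)$class)
  }, error = function(e) {
    # singular within-group covariance: nearest group centroid
    cen <- rbind(colMeans(coords[g == "HFE", , drop = FALSE]),
                 colMeans(coords[g == "LFE", , drop = FALSE]))
    GROUP_LEVELS[apply(coords, 1, function(p) {
      which.min(c(sum((p - cen[1, ])^2), sum((p - cen[2, ])^2)))
    })]
  })
  mis <- sum(pred != as.character(g))
  list(
    coords = data.frame(sample = colnames(em), PC1 = coords[, 1],
                        PC2 = coords[, 2], group = as.character(g),
                        row.names = NULL),
    misclassified = mis,
    separated = mis <= max_misclassified
  )
}
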