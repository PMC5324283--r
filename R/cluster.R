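# Hierarchical clustering of samples on the extreme-PIF panel: does the
# panel alone re-discover the treatment groups, and which group is more
# dispersed?

#' Row-standardise a panel matrix
#'
#' Centres each gene row to mean 0 and scales to SD 1 (population SD by
#' default; the choice only rescales rows uniformly and cannot change the
#' tree under correlation distance).
#'
#' @param m real matrix with >= 2 columns.
#' @param sd_type `"population"` (divide by n) or `"sample"` (n - 1).
#' @return Row-standardised matrix.
#' @export
row_normalize <- function(m, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  if (ncol(m) < 2) stop("need >= 2 columns")
  ctr <- m - rowMeans(m)
  denom <- if (sd_type == "population") ncol(m) else ncol(m) - 1
  s <- sqrt(rowSums(ctr^2) / denom)
  zero <- s == 0
  if (any(zero)) {
    stop("zero-SD row(s): ", paste(rownames(m)[zero], collapse = ", "))
  }
  ctr / s
}

#' Cluster samples on a gene panel
#'
#' Agglomerative clustering of the columns (samples) of a panel matrix,
#' deterministic given its inputs. Reports the k = 2 cut assignment, its
#' purity against the known groups (fraction of samples matching the
#' majority group of their cluster), the mean pairwise within-group
#' distance per group, and the dendrogram in Newick form.
#'
#' @param panel_matrix real matrix (panel genes x samples), >= 3 samples.
#' @param groups sample group factor/labels (HFE/LFE).
#' @param distance `"pearson"` (1 - correlation, the default) or
#'   `"euclidean"`.
#' @param linkage `"average"` (default), `"complete"` or `"ward"`.
#' @return Object of class `cluster_report`: list with `hclust`, `newick`,
#'   `assignment` (named integer, k = 2), `purity`, `dispersion_hfe`,
#'   `dispersion_lfe`.
#' @export
cluster_samples <- function(panel_matrix, groups,
                            distance = c("pearson", "euclidean"),
                            linkage = c("average", "complete", "ward")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (ncol(panel_matrix) < 3) stop("need >= 3 samples")
  g <- align_groups(groups, colnames(panel_matrix))
  d <- switch(distance,
    pearson = stats::as.dist(1 - stats::cor(panel_matrix)),
    euclidean = stats::dist(t(panel_matrix))
  )
  hc <- stats::hclust(d, method = switch(linkage, ward = "ward.D2", linkage))
  assignment <- stats::cutree(hc, k = 2)
  # purity: fraction of samples whose group matches the majority group of
  # their cluster
  per_cluster_major <- vapply(split(as.character(g), assignment), function(labs) {
    names(which.max(table(labs)))
  }, character(1))
  purity <- mean(per_cluster_major[as.character(assignment)] == as.character(g))
  dm <- as.matrix(d)
  within_disp <- function(level) {
    idx <- which(g == level)
    if (length(idx) < 2) return(NA_real_)
    mean(dm[idx, idx][lower.tri(dm[idx, idx])])
  }
  structure(list(
    hclust = hc,
    newick = ape::write.tree(ape::as.phylo(hc)),
    assignment = assignment,
    purity = purity,
    dispersion_hfe = within_disp("HFE"),
    dispersion_lfe = within_disp("LFE")
  ), class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf(
    "Sample clustering (k = 2): purity %.3f | dispersion HFE %.4f, LFE %.4f\n",
    x$purity, x$dispersion_hfe, x$dispersion_lfe))
  invisible(x)
}
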