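# Direction-of-change skew of a designated gene set (e.g. the
# mitoproteome) against a 50:50 null, by exact binomial statistics. A
# coordinated shift of a large functional set is detectable even when no
# single member is individually significant.

#' Count up/down/tied directions of a gene set
#'
#' Counts are taken over the intersection of `gene_set` with the DE table;
#' ids absent from the table are returned in `missing`, not counted. Ties
#' (m = 0) are evidence for neither direction and are excluded from the
#' test downstream.
#'
#' @param det a [compute_de()] table.
#' @param gene_set non-empty character vector of gene ids.
#' @return List with n_up, n_down, n_tied, n_set and missing.
#' @export
count_directions <- function(det, gene_set) {
  if (length(gene_set) == 0) stop("`gene_set` must be non-empty")
  missing <- setdiff(gene_set, det$gene)
  present <- intersect(gene_set, det$gene)
  if (length(present) == 0) stop("no genes of the set are present in the DE table")
  m <- det$m[match(present, det$gene)]
  list(n_up = sum(m > 0), n_down = sum(m < 0), n_tied = sum(m == 0),
       n_set = length(present), missing = missing)
}

#' Exact binomial test of direction skew
#'
#' Two-sided exact binomial test of `n_up` successes in `n_up + n_down`
#' trials at p = 0.5, two-sided by summing the probabilities of all
#' outcomes no more likely than the observed one. Ties are excluded from
#' the trials and reported.
#'
#' @param n_up,n_down direction counts (non-negative, total >= 1).
#' @param n_tied excluded tie count (reporting only).
#' @return Object of class `skew_result`: n_up, n_down, n_tied, n_set,
#'   p_value and direction (`up-in-HFE`, `down-in-HFE` or `none`).
#' @export
binomial_skew_test <- function(n_up, n_down, n_tied = 0) {
  if (n_up < 0 || n_down < 0 || n_tied < 0) stop("counts must be non-negative")
  n <- n_up + n_down
  if (n < 1) stop("need at least one untied gene")
  p <- stats::binom.test(n_up, n, p = 0.5, alternative = "two.sided")$p.value
  direction <- if (n_up > n_down) "up-in-HFE" else if (n_up < n_down) "down-in-HFE" else "none"
  structure(list(n_up = n_up, n_down = n_down, n_tied = n_tied,
                 n_set = n_up + n_down + n_tied,
                 p_value = p, direction = direction),
            class = "skew_result")
}

#' @export
print.skew_result <- function(x, ...) {
  cat(sprintf(
    "Direction skew: %d up vs %d down (%d tied) | binomial P = %.3g | %s\n",
    x$n_up, x$n_down, x$n_tied, x$p_value, x$direction))
  invisible(x)
}

#' Direction-skew test of a gene set against a DE table
#'
#' Convenience wrapper: [count_directions()] then [binomial_skew_test()].
#'
#' @inheritParams count_directions
#' @return A `skew_result` (see [binomial_skew_test()]); genes of the set
#'   absent from the table are attached as attribute `missing`.
#' @export
mito_skew <- function(det, gene_set) {
  cts <- count_directions(det, gene_set)
  res <- binomial_skew_test(cts$n_up, cts$n_down, cts$n_tied)
  attr(res, "missing") <- cts$missing
  res
}
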