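# MA-style differential expression and the Phenotypic Impact Factor (PIF)
# ranking. With only a handful of animals per group, per-gene significance
# testing is underpowered; PIF (abundance x DE) instead emphasises
# abundant, strongly changed transcripts and feeds the downstream
# set-level analyses.

#' Per-gene abundance, differential expression and PIF
#'
#' For each gene computes the group means on the normalised log2 scale,
#' the MA-plot coordinates `a = (x_hfe + x_lfe) / 2` (average abundance)
#' and `m = x_hfe - x_lfe` (differential expression, HFE minus LFE), the
#' signed linear fold change `sign(m) * 2^|m|` (1 when m = 0), and
#' `pif = a * m`.
#'
#' @param em expression matrix (gene x sample), log2 scale.
#' @param groups sample group factor/labels (HFE/LFE), both non-empty.
#' @return Data frame with columns gene, x_hfe, x_lfe, a, m, fold_change,
#'   pif, rank_pif (dense rank, pif descending).
#' @export
compute_de <- function(em, groups) {
  g <- align_groups(groups, colnames(em))
  x_hfe <- rowMeans(em[, g == "HFE", drop = FALSE])
  x_lfe <- rowMeans(em[, g == "LFE", drop = FALSE])
  m <- x_hfe - x_lfe
  a <- (x_hfe + x_lfe) / 2
  fold <- ifelse(m == 0, 1, sign(m) * 2^abs(m))
  pif <- a * m
  det <- data.frame(gene = rownames(em), x_hfe = x_hfe, x_lfe = x_lfe,
                    a = a, m = m, fold_change = fold, pif = pif,
                    row.names = NULL, stringsAsFactors = FALSE)
  det$rank_pif <- match(det$pif, sort(unique(det$pif), decreasing = TRUE))
  det
}

# Order genes by pif (descending or ascending), ties broken by gene id.
pif_order <- function(det, decreasing = TRUE) {
  if (decreasing) {
    order(-det$pif, det$gene)
  } else {
    order(det$pif, det$gene)
  }
}

#' Select the extreme-PIF target sets
#'
#' Splits a nominal `fraction` symmetrically: the top
#' `floor(fraction/2 * n)` genes by PIF form the up set and the bottom as
#' many the down set (for 10,412 genes at the nominal 5% this is 260 up +
#' 260 down = 520 targets). Ties are broken by gene id so the selection is
#' deterministic.
#'
#' @param det a [compute_de()] table.
#' @param fraction total extreme fraction in (0, 1), default 0.05.
#' @return List with character vectors `up` and `down`.
#' @export
select_extreme_pif <- function(det, fraction = 0.05) {
  if (fraction <= 0 || fraction >= 1) stop("`fraction` must be in (0, 1)")
  n_half <- floor(fraction / 2 * nrow(det))
  if (n_half == 0) stop("fraction too small: no genes selected")
  list(
    up = det$gene[pif_order(det, TRUE)][seq_len(n_half)],
    down = det$gene[pif_order(det, FALSE)][seq_len(n_half)]
  )
}

#' Select the top-k discrimination panel
#'
#' The top `k` and bottom `k` genes by PIF, concatenated (default k = 20,
#' the 40-gene heatmap panel used to discriminate samples by clustering).
#'
#' @param det a [compute_de()] table.
#' @param k panel half-size; `2k` must not exceed the gene count.
#' @return Character vector of 2k gene ids (up block then down block).
#' @export
select_panel <- function(det, k = 20) {
  if (k < 1) stop("`k` must be positive")
  if (2 * k > nrow(det)) stop("2k exceeds the number of genes")
  c(det$gene[pif_order(det, TRUE)][seq_len(k)],
    det$gene[pif_order(det, FALSE)][seq_len(k)])
}

#' MA plot table
#'
#' (A, M) pairs per gene with a highlight flag for a supplied gene set
#' (slow-fibre panels, the mitoproteome, extreme PIF, ...). Highlight ids
#' absent from the table raise a warning listing them, not an error.
#'
#' @param det a [compute_de()] table.
#' @param highlight character vector of gene ids to flag.
#' @return Data frame gene, a, m, highlighted.
#' @export
ma_table <- function(det, highlight = character()) {
  absent <- setdiff(highlight, det$gene)
  if (length(absent) > 0) {
    warning("highlight ids absent from the DE table: ",
            paste(absent, collapse = ", "))
  }
  data.frame(gene = det$gene, a = det$a, m = det$m,
             highlighted = det$gene %in% highlight,
             row.names = NULL, stringsAsFactors = FALSE)
}
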