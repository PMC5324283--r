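# End-to-end orchestration: filter -> normalise -> PCA check -> DE/PIF ->
# mito skew -> extreme-PIF selection -> RIF -> panel clustering, with
# every intermediate table written to disk and a run manifest sufficient
# to re-execute an identical run.

#' Build and validate a pipeline configuration
#'
#' @param counts_file counts TSV (genes x samples).
#' @param groups_file two-column TSV (sample_id, group).
#' @param regulator_file newline-delimited regulator gene ids.
#' @param mito_file newline-delimited mitoproteome gene ids.
#' @param out_dir output directory.
#' @param pseudocount added before log2 (default 1).
#' @param extreme_fraction nominal extreme-PIF fraction (default 0.05).
#' @param panel_k panel half-size (default 20).
#' @param z_threshold RIF outlier |z| cut-off (default 1.96).
#' @param distance,linkage clustering options (see [cluster_samples()]).
#' @param rpm_before_filter compute RPM denominators before the
#'   completeness filter (default TRUE).
#' @param seed integer seed recorded in the manifest (the analysis stages
#'   themselves are deterministic).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_file, groups_file, regulator_file,
                            mito_file = NULL, out_dir,
                            pseudocount = 1, extreme_fraction = 0.05,
                            panel_k = 20, z_threshold = 1.96,
                            distance = "pearson", linkage = "average",
                            rpm_before_filter = TRUE, seed = 1L) {
  if (pseudocount < 0) stop("`pseudocount` must be non-negative")
  if (extreme_fraction <= 0 || extreme_fraction >= 1) {
    stop("`extreme_fraction` must be in (0, 1)")
  }
  if (panel_k < 1) stop("`panel_k` must be positive")
  if (!distance %in% c("pearson", "euclidean")) {
    stop("`distance` must be one of: pearson, euclidean")
  }
  if (!linkage %in% c("average", "complete", "ward")) {
    stop("`linkage` must be one of: average, complete, ward")
  }
  structure(list(
    counts_file = counts_file, groups_file = groups_file,
    regulator_file = regulator_file, mito_file = mito_file,
    out_dir = out_dir, pseudocount = pseudocount,
    extreme_fraction = extreme_fraction, panel_k = panel_k,
    z_threshold = z_threshold, distance = distance, linkage = linkage,
    rpm_before_filter = rpm_before_filter, seed = as.integer(seed)
  ), class = "pipeline_config")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

log_stage <- function(name, ...) {
  message(sprintf("[%s] %s", name, paste0(...)))
}

#' Run the full analysis pipeline
#'
#' Executes every stage in the fixed order, writing each intermediate
#' table under `out_dir`. Any stage error aborts with the stage name;
#' outputs of earlier stages are retained. Re-running with identical
#' inputs and seed reproduces all outputs bit-for-bit (timestamps live
#' only in the manifest).
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results of every stage.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)

  counts <- stage("read", read_counts(config$counts_file))
  groups <- stage("read", read_groups(config$groups_file))
  groups <- align_groups(groups, colnames(counts))
  log_stage("read", nrow(counts), " genes x ", ncol(counts), " samples")

  em <- stage("normalize", normalize_counts(
    counts, pseudocount = config$pseudocount,
    filter_first = !config$rpm_before_filter))
  write_matrix_tsv(round(em, 10), file.path(out, "normalized.tsv"))
  log_stage("normalize", nrow(em), " complete genes retained")

  pca <- stage("pca_check", pca_group_check(em, groups))
  utils::write.table(pca$coords, file.path(out, "pca_coords.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  log_stage("pca_check", "separated = ", pca$separated,
            " (misclassified ", pca$misclassified, ")")

  det <- stage("de", compute_de(em, groups))
  utils::write.table(det, file.path(out, "de_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  skew <- NULL
  if (!is.null(config$mito_file)) {
    # set files are read inside their stage so that a missing file aborts
    # here, leaving the earlier stage outputs intact
    mito <- stage("mito_skew", read_gene_set(config$mito_file))
    skew <- stage("mito_skew", mito_skew(det, mito))
    utils::write.table(
      data.frame(n_up = skew$n_up, n_down = skew$n_down,
                 n_tied = skew$n_tied, p_value = skew$p_value,
                 direction = skew$direction),
      file.path(out, "mito_skew.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE)
    log_stage("mito_skew", skew$n_up, " up vs ", skew$n_down,
              " down, P = ", format(skew$p_value, digits = 3))
  }

  targets <- stage("extreme_pif", select_extreme_pif(det, config$extreme_fraction))
  writeLines(targets$up, file.path(out, "targets_up.txt"))
  writeLines(targets$down, file.path(out, "targets_down.txt"))
  log_stage("extreme_pif", length(targets$up), " up + ",
            length(targets$down), " down targets")

  rif <- stage("rif", {
    regulators <- read_gene_set(config$regulator_file)
    regs <- intersect(regulators, rownames(em))
    if (length(regs) < 2) stop("fewer than 2 regulators present in the matrix")
    compute_rif(em, groups, regs, c(targets$up, targets$down),
                threshold = config$z_threshold)
  })
  utils::write.table(rif, file.path(out, "rif_table.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_stage("rif", sum(rif$outlier), " outlier regulator(s) of ", nrow(rif))

  clust <- stage("cluster", {
    panel <- select_panel(det, config$panel_k)
    writeLines(panel, file.path(out, "panel.txt"))
    cluster_samples(row_normalize(em[panel, , drop = FALSE]), groups,
                    distance = config$distance, linkage = config$linkage)
  })
  writeLines(clust$newick, file.path(out, "dendrogram.nwk"))
  writeLines(c(
    sprintf("purity\t%.6f", clust$purity),
    sprintf("dispersion_hfe\t%.6f", clust$dispersion_hfe),
    sprintf("dispersion_lfe\t%.6f", clust$dispersion_lfe),
    paste0("assignment\t",
           paste(names(clust$assignment), clust$assignment,
                 sep = ":", collapse = ","))
  ), file.path(out, "cluster_report.tsv"))
  log_stage("cluster", "purity = ", format(clust$purity, digits = 3))

  manifest <- c(
    paste0("rifdc_version\t", as.character(utils::packageVersion("rifdc"))),
    paste0("timestamp\t", format(Sys.time(), "%Y-%m-%dT%H:%M:%S")),
    vapply(setdiff(names(config), "out_dir"), function(k) {
      paste0(k, "\t", paste(format(config[[k]]), collapse = ","))
    }, character(1)),
    paste0("n_genes_input\t", nrow(counts)),
    paste0("n_genes_complete\t", nrow(em)),
    paste0("n_samples\t", ncol(counts)),
    paste0("n_regulators_used\t", nrow(rif)),
    paste0("n_targets\t", length(targets$up) + length(targets$down))
  )
  writeLines(manifest, file.path(out, "manifest.tsv"))

  invisible(list(counts = counts, groups = groups, em = em, pca = pca,
                 det = det, skew = skew, targets = targets, rif = rif,
                 cluster = clust))
}
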