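# Readers and writers for the pipeline's plain-text formats. All tables
# are tab-delimited UTF-8 without quoting; gene sets are newline-delimited
# identifiers.

write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE, row.names = NULL)
  colnames(df)[1] <- id_col
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop("cannot write file: ", path)
  invisible(path)
}

#' Read a gene x sample count matrix from TSV
#'
#' Expects a header row of sample ids, a first column of gene ids and
#' integer counts. Duplicate ids and non-integer counts are hard errors
#' citing the offending line.
#'
#' @param path TSV file path.
#' @return Integer matrix with gene rownames and sample colnames.
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("count matrix needs a gene column and >= 1 sample: ", path)
  genes <- as.character(df[[1]])
  dup <- which(duplicated(genes))
  if (length(dup) > 0) {
    stop("duplicate gene id '", genes[dup[1]], "' on line ", dup[1] + 1L,
         " of ", path)
  }
  if (anyDuplicated(colnames(df)[-1])) stop("duplicate sample ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(!apply(df[, -1, drop = FALSE], 1, function(r) {
      all(grepl("^\\s*[0-9]+\\s*$", r))
    }))
    stop("non-integer count on line ", bad[1] + 1L, " of ", path)
  }
  if (any(m != round(m)) || any(m < 0)) {
    bad <- which(rowSums(m != round(m) | m < 0) > 0)
    stop("non-integer count on line ", bad[1] + 1L, " of ", path)
  }
  storage.mode(m) <- "integer"
  rownames(m) <- genes
  validate_counts(m)
  m
}

#' Read a sample-to-group mapping from a two-column TSV
#'
#' @param path TSV with columns `sample_id` and `group` (HFE/LFE).
#' @return Named factor with levels HFE, LFE.
#' @export
read_groups <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("group file needs two columns (sample_id, group): ", path)
  dup <- which(duplicated(df[[1]]))
  if (length(dup) > 0) {
    stop("duplicate sample id '", df[[1]][dup[1]], "' on line ", dup[1] + 1L,
         " of ", path)
  }
  align_groups(stats::setNames(df[[2]], df[[1]]), df[[1]])
}

#' Read a newline-delimited gene-identifier set
#'
#' Blank lines (including trailing ones) are ignored; duplicates are an
#' error citing the line.
#'
#' @param path text file, one identifier per line.
#' @return Character vector (possibly empty).
#' @export
read_gene_set <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  ids <- readLines(path)
  keep <- trimws(ids) != ""
  dup <- which(keep & duplicated(ifelse(keep, trimws(ids), NA_character_),
                                 incomparables = NA))
  if (length(dup) > 0) {
    stop("duplicate identifier '", trimws(ids[dup[1]]), "' on line ", dup[1],
         " of ", path)
  }
  trimws(ids[keep])
}

#' Read a simulated dataset written by [write_dataset()]
#'
#' @param directory directory containing `counts.tsv`, `groups.tsv` and the
#'   gene-set files.
#' @return A list with `counts`, `groups`, `regulators`, and `truth`
#'   (`mito`, `rewired`, `de`).
#' @export
read_dataset <- function(directory) {
  list(
    counts = read_counts(file.path(directory, "counts.tsv")),
    groups = read_groups(file.path(directory, "groups.tsv")),
    regulators = read_gene_set(file.path(directory, "regulators.txt")),
    truth = list(
      mito = read_gene_set(file.path(directory, "truth_mito.txt")),
      rewired = read_gene_set(file.path(directory, "truth_rewired.txt")),
      de = utils::read.delim(file.path(directory, "truth_de.tsv"),
                             stringsAsFactors = FALSE)
    )
  )
}
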