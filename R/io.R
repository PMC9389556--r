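#' Read / write expression matrices as TSV
#'
#' Matrices are stored genes-in-rows with a leading id column and sample ids
#' in the header.
#'
#' @param m matrix to write.
#' @param path file path.
#' @param id_col name of the id column (default "gene").
#' @return `read_matrix_tsv` returns a numeric matrix with rownames.
#' @export
write_matrix_tsv <- function(m, path, id_col = "gene") {
  df <- data.frame(rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_matrix_tsv
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: set name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  sets
}

#' Write a generated cohort to a directory
#'
#' Expression/cytokine/metabolite matrices and the sample table as TSV, the
#' ground truth and cell proportions as JSON.
#'
#' @param cohort result of [generate_cohort()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix_tsv(cohort$expr, file.path(dir, "expression.tsv"))
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(cohort$cytokines))
    write_matrix_tsv(cohort$cytokines, file.path(dir, "cytokines.tsv"), "cytokine")
  if (!is.null(cohort$metabolites))
    write_matrix_tsv(cohort$metabolites, file.path(dir, "metabolites.tsv"), "metabolite")
  if (!is.null(cohort$cellprops))
    write_matrix_tsv(cohort$cellprops, file.path(dir, "cellprops.tsv"), "subject")
  truth <- cohort$truth
  truth_out <- list(
    module_membership = data.frame(
      gene = names(truth$module_membership),
      module = unname(truth$module_membership)),
    predictive_genes = truth$predictive_genes,
    driver_tfs = truth$driver_tfs,
    outcome = data.frame(subject = names(truth$outcome),
                         outcome = unname(truth$outcome)),
    regulons = truth$regulons)
  jsonlite::write_json(truth_out, file.path(dir, "truth.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}
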