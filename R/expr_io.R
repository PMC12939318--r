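## Plain-text I/O for expression matrices and cohorts: a gene-by-sample
## values TSV plus a sample-annotation sidecar (sample, condition,
## group), an optional gene-by-group q-value TSV, and a patient-by-gene
## cohort TSV.

#' Write / read a replicate expression matrix as TSV
#'
#' `write_expression()` writes three files under `prefix`:
#' `<prefix>_values.tsv` (genes x samples, first column `gene`),
#' `<prefix>_samples.tsv` (columns `sample`, `condition`, `group`) and,
#' if q-values are present, `<prefix>_qvalues.tsv` (first column
#' `gene`, one column per group). `read_expression()` reads them back;
#' a write/read round trip reproduces the object.
#'
#' @param expr an [expression_matrix()].
#' @param prefix output path prefix.
#' @return `write_expression()`: the three paths, invisibly;
#'   `read_expression()`: an [expression_matrix()].
#' @export
write_expression <- function(expr, prefix) {
  stopifnot(inherits(expr, "expression_matrix"))
  p_values <- paste0(prefix, "_values.tsv")
  p_samples <- paste0(prefix, "_samples.tsv")
  p_q <- paste0(prefix, "_qvalues.tsv")
  write.table(data.frame(gene = rownames(expr$values), expr$values,
                         check.names = FALSE),
              p_values, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = colnames(expr$values),
                         condition = unname(expr$condition),
                         group = unname(expr$group)),
              p_samples, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(values = p_values, samples = p_samples)
  if (!is.null(expr$qvalues)) {
    write.table(data.frame(gene = rownames(expr$qvalues), expr$qvalues,
                           check.names = FALSE),
                p_q, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, qvalues = p_q)
  }
  invisible(paths)
}

#' @rdname write_expression
#' @export
read_expression <- function(prefix) {
  p_values <- paste0(prefix, "_values.tsv")
  p_samples <- paste0(prefix, "_samples.tsv")
  p_q <- paste0(prefix, "_qvalues.tsv")
  for (p in c(p_values, p_samples)) {
    if (!file.exists(p)) stop("file not found: ", p)
  }
  vals <- read.delim(p_values, check.names = FALSE)
  m <- as.matrix(vals[, -1, drop = FALSE])
  rownames(m) <- vals$gene
  ann <- read.delim(p_samples)
  ann <- ann[match(colnames(m), ann$sample), , drop = FALSE]
  qv <- NULL
  if (file.exists(p_q)) {
    qt <- read.delim(p_q, check.names = FALSE)
    qv <- as.matrix(qt[, -1, drop = FALSE])
    rownames(qv) <- qt$gene
  }
  expression_matrix(m, ann$condition, ann$group, qvalues = qv)
}

#' Write / read a patient cohort table as TSV
#'
#' Patients x genes, first column `patient`.
#'
#' @param cohort numeric patient-by-gene matrix.
#' @param path file path.
#' @return `write_cohort()`: `path`, invisibly; `read_cohort()`: the
#'   matrix.
#' @export
write_cohort <- function(cohort, path) {
  stopifnot(is.matrix(cohort), !is.null(rownames(cohort)))
  write.table(data.frame(patient = rownames(cohort), cohort,
                         check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- read.delim(path, check.names = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$patient
  m
}
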