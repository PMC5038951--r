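# Tab-separated readers and writers for the pipeline's file formats.

#' Read a gene expression matrix from TSV
#'
#' First column = gene id, header row = sample ids.
#'
#' @param path File path.
#' @return Numeric genes x samples matrix.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  genes <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- genes
  m
}

#' Write an expression (or any numeric) matrix to TSV
#'
#' @param m Matrix with row and column names.
#' @param path Output path.
#' @param id_col Name of the first (row id) column.
#' @param header Optional comment lines written before the table.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "id", header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  df <- data.frame(rownames(m), m, check.names = FALSE)
  names(df)[1] <- id_col
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a sample label file (TSV: sample id, label)
#'
#' @param path File path.
#' @return Named character vector.
#' @export
read_labels_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  stats::setNames(as.character(df[[2]]), as.character(df[[1]]))
}

#' Read a survival table (TSV: patient id, time, event)
#'
#' @param path File path.
#' @return Data frame: patient, time, event.
#' @export
read_survival_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, comment.char = "#")
  out <- data.frame(patient = as.character(df[[1]]),
                    time = as.numeric(df[[2]]),
                    event = as.integer(df[[3]]))
  check_survival(out)
}

#' Write a data frame to TSV with an optional comment header
#'
#' @param df Data frame.
#' @param path Output path.
#' @param header Optional comment lines (written as `# ...`).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
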