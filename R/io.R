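# TSV readers/writers for the expression, covariate, genotype and result
# tables. Dialect: tab-separated UTF-8, single header row, '#' comment lines,
# missing values as empty cells.

write_tsv <- function(df, path, digits = 6) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, digits))
  ok <- tryCatch({
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "")
    TRUE
  }, error = function(e) FALSE, warning = function(w) FALSE)
  if (!ok) stop("cannot write file: ", path)
  invisible(path)
}

# fixture matrices keep 10 significant digits (relative round-trip error
# below 1e-9); result tables use the documented 6
write_matrix_tsv <- function(mat, path, id_col) {
  ids <- if (is.null(rownames(mat))) character(nrow(mat)) else rownames(mat)
  df <- data.frame(ids, as.data.frame(unclass(mat)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv(df, path, digits = 10)
}

read_tsv_raw <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, sep = "\t", comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE, na.strings = "")
}

read_id_matrix <- function(path, id_col) {
  df <- read_tsv_raw(path)
  if (names(df)[1] != id_col)
    stop(sprintf("first column of %s must be '%s'", path, id_col))
  ids <- as.character(df[[1]])
  body <- df[, -1, drop = FALSE]
  for (j in seq_along(body)) {
    col <- body[[j]]
    if (!is.numeric(col)) {
      conv <- suppressWarnings(as.numeric(col))
      bad <- which(is.na(conv) & !is.na(col))
      if (length(bad) > 0)
        stop(sprintf("non-numeric cell '%s' in %s at row '%s', column '%s'",
                     col[bad[1]], path, ids[bad[1]], names(body)[j]))
      body[[j]] <- conv
    }
  }
  mat <- as.matrix(body)
  storage.mode(mat) <- "double"
  rownames(mat) <- ids
  mat
}

#' Read an expression matrix from TSV
#'
#' Expects a `gene_id` first column and one column per sample.
#'
#' @param path TSV file path.
#' @param stage processing-stage tag to attach (`"raw"` by default).
#' @return an [expr_matrix()].
#' @export
read_expression <- function(path, stage = "raw") {
  expr_matrix(read_id_matrix(path, "gene_id"), stage)
}

#' Read a sample covariate table from TSV
#'
#' Columns: `sample_id, donor_id, tissue, pmi_min, age, gender, bmi, rin`.
#' Empty `pmi_min` cells become `NA` (missing PMI, excluded downstream).
#'
#' @param path TSV file path.
#' @return validated data.frame.
#' @export
read_samples <- function(path) {
  df <- read_tsv_raw(path)
  for (col in c("pmi_min", "age", "gender", "bmi", "rin"))
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  validate_samples(df)
}

#' Read a genotype matrix from TSV
#'
#' Expects a `snp_id` first column and one 0/1/2-coded column per donor.
#' Any cell outside \{0, 1, 2\} is a parse error naming the cell.
#'
#' @param path TSV file path.
#' @return a [geno_matrix()].
#' @export
read_genotypes <- function(path) {
  geno_matrix(read_id_matrix(path, "snp_id"))
}

#' Write a result table to TSV
#'
#' Columns are written in their existing (documented) order with numeric
#' values at 6 significant digits. An empty table yields a header-only file.
#'
#' @param table a result data.frame (association, interaction or DV records).
#' @param path output file path.
#' @return invisibly, the path.
#' @export
write_results <- function(table, path) {
  if (!is.data.frame(table)) stop("`table` must be a data.frame")
  write_tsv(table, path)
}

#' Read a result table written by [write_results()]
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_results <- function(path) read_tsv_raw(path)
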