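## TSV matrix/table I/O. Reals are written with 15 significant digits so a
## write/read round trip reproduces values to (at least) 12 significant
## digits; integers are written without a decimal point.

#' Write a numeric matrix as TSV
#'
#' First column `id` holds row names; remaining columns are samples.
#' @param m Numeric matrix with row and column names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  assert_that(!is.null(rownames(m)) && !is.null(colnames(m)),
              "matrix must have row and column names")
  df <- data.frame(id = rownames(m), stringsAsFactors = FALSE,
                   check.names = FALSE)
  for (j in seq_len(ncol(m))) df[[colnames(m)[j]]] <- fmt_num(m[, j])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a numeric matrix written by [write_matrix_tsv()]
#'
#' @param path TSV path with an `id` first column.
#' @return Numeric matrix.
#' @export
read_matrix_tsv <- function(path) {
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   check.names = FALSE)
  assert_that(names(df)[1] == "id", paste(path, "must start with an id column"))
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df$id)
  m
}

fmt_num <- function(x) {
  out <- character(length(x))
  int <- !is.na(x) & abs(x - round(x)) < .Machine$double.eps * pmax(1, abs(x))
  out[int] <- sprintf("%d", as.integer(round(x[int])))
  out[!int] <- sprintf("%.15g", x[!int])
  out[is.na(x)] <- "NA"
  out
}

#' Write a data.frame as TSV (reals kept to 15 significant digits)
#'
#' @param df data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.numeric(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#'
#' @param path TSV path with a header row.
#' @return data.frame.
#' @export
read_table_tsv <- function(path) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, check.names = FALSE)
}
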