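#' Coerce expression input to a validated gene-by-sample matrix
#'
#' The package's expression container is a plain numeric matrix: genes in
#' rows (unique symbols as rownames), samples in columns, non-negative
#' finite values on a normalized scale (FPKM-like). Tibbles/data frames
#' with the gene symbol in the first column are accepted and converted.
#'
#' @param x Numeric matrix with rownames, or a data frame whose first
#'   column holds gene symbols.
#' @return Validated numeric matrix.
#' @export
as_expression_matrix <- function(x) {
  if (is.data.frame(x)) {
    genes <- as.character(x[[1]])
    m <- as.matrix(x[, -1, drop = FALSE])
    storage.mode(m) <- "double"
    rownames(m) <- genes
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x))
    abort("expression must be a numeric matrix or a data frame")
  if (is.null(rownames(x)) || any(!nzchar(rownames(x))))
    abort("expression matrix needs gene symbols as rownames")
  if (anyDuplicated(rownames(x)))
    abort(paste0("duplicate gene symbol(s): ",
                 paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", ")))
  if (any(!is.finite(x))) abort("expression contains non-finite values")
  if (any(x < 0)) abort("expression contains negative values")
  if (is.null(colnames(x)))
    colnames(x) <- paste0("s", seq_len(ncol(x)))
  x
}

#' Read / write delimited expression matrices
#'
#' Expected layout: first column gene symbol, header row of sample ids;
#' TSV or CSV decided by file extension. `#`-prefixed lines are comments.
#'
#' @param path File path.
#' @return `read_expression()`: a validated gene-by-sample matrix.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) abort(paste0("expression file not found: ", path))
  reader <- if (grepl("\\.csv$", path, ignore.case = TRUE))
    readr::read_csv else readr::read_tsv
  as_expression_matrix(reader(path, show_col_types = FALSE, progress = FALSE,
                              comment = "#"))
}

#' @rdname read_expression
#' @param expr Expression input accepted by [as_expression_matrix()].
#' @param comment Optional comment line(s) written before the header.
#' @export
write_expression <- function(expr, path, comment = NULL) {
  expr <- as_expression_matrix(expr)
  df <- tibble::as_tibble(expr, rownames = "gene")
  write_tsv_commented_(df, path, comment)
  invisible(path)
}

# shared writer: optional '#' comment lines, then a TSV body
write_tsv_commented_ <- function(df, path, comment = NULL) {
  txt <- readr::format_tsv(df)
  if (!is.null(comment) && length(comment) > 0)
    txt <- paste0(paste0("# ", comment, collapse = "\n"), "\n", txt)
  writeLines(sub("\n$", "", txt), path)
  invisible(path)
}
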