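#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample identifiers and a first column of gene
#' identifiers; remaining cells are normalized expression values. The
#' delimiter is inferred from the file extension (`.csv` gives comma,
#' anything else tab).
#'
#' @param path Path to a delimited text file.
#' @return A numeric genes x samples matrix with gene ids as row names and
#'   sample ids as column names, validated by [validate_expression()].
#' @seealso [validate_expression()]
#' @export
read_expression <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("expression file needs a gene-id column plus samples")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  validate_expression(m)
}

#' Validate (and clean) an expression matrix
#'
#' Enforces the contract assumed throughout the package: unique gene and
#' sample identifiers, no missing values, at least 3 genes and 3 samples.
#' Rows containing missing values are dropped with a message; constant
#' (zero-variance) genes are dropped with a warning, since they carry no
#' co-expression information and would produce undefined correlations.
#'
#' @param expr Numeric genes x samples matrix with dimnames.
#' @param drop_constant Drop zero-variance gene rows (default `TRUE`).
#' @return The validated matrix (possibly with rows removed).
#' @export
validate_expression <- function(expr, drop_constant = TRUE) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression must be a numeric matrix")
  if (is.null(rownames(expr)) || is.null(colnames(expr)))
    stop("expression matrix needs gene row names and sample column names")
  if (anyDuplicated(rownames(expr))) stop("duplicate gene identifiers")
  if (anyDuplicated(colnames(expr))) stop("duplicate sample identifiers")
  bad <- !complete.cases(expr)
  if (any(bad)) {
    message(sum(bad), " gene(s) with missing values dropped")
    expr <- expr[!bad, , drop = FALSE]
  }
  if (drop_constant) {
    v <- apply(expr, 1L, function(x) max(x) - min(x))
    if (any(v == 0)) {
      warning(sum(v == 0), " constant-expression gene(s) dropped")
      expr <- expr[v > 0, , drop = FALSE]
    }
  }
  if (nrow(expr) < 3L || ncol(expr) < 3L)
    stop("need at least 3 genes and 3 samples after cleaning")
  expr
}
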