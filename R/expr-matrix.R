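#' Expression matrix container
#'
#' A genes-by-samples numeric matrix carrying a scale tag (`"counts"` or
#' `"log2"`). Gene IDs are row names, sample IDs column names; both must be
#' unique. Values on the log2 scale must be finite.
#'
#' @param values numeric matrix, genes in rows, samples in columns, with
#'   row and column names.
#' @param scale `"counts"` or `"log2"`.
#' @return the matrix with class `expr_matrix` and a `scale` attribute.
#' @export
expression_matrix <- function(values, scale = c("log2", "counts")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values))
    stop("values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("gene IDs (rownames) and sample IDs (colnames) are required")
  if (anyDuplicated(rownames(values))) stop("duplicated gene IDs")
  if (anyDuplicated(colnames(values))) stop("duplicated sample IDs")
  if (scale == "log2" && !all(is.finite(values)))
    stop("log2-scale values must be finite")
  if (scale == "counts" && any(values < 0))
    stop("counts must be non-negative")
  structure(values, class = c("expr_matrix", class(values)), scale = scale)
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (%s scale)\n",
              nrow(x), ncol(x), attr(x, "scale")))
  invisible(x)
}

expr_scale <- function(x) {
  sc <- attr(x, "scale")
  if (is.null(sc)) "log2" else sc
}

# subsetting keeps the class and scale tag
#' @export
`[.expr_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out))
    out <- structure(out, class = class(x), scale = attr(x, "scale"))
  out
}

#' Read / write an expression matrix as TSV
#'
#' First column holds gene IDs, the header names the samples.
#'
#' @param x an [expression_matrix()].
#' @param path file path.
#' @param scale scale tag to attach when reading.
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_tsv
#' @export
read_expression_tsv <- function(path, scale = c("log2", "counts")) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, match.arg(scale))
}
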