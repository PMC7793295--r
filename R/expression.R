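# Replicate expression tables (TPM-like units) with a sample -> condition map.

#' Construct an expression matrix
#'
#' @param values Numeric matrix, genes in rows (unique rownames), samples in
#'   columns (colnames). Values must be nonnegative with no missing entries.
#' @param groups Named character vector mapping every sample (column) to its
#'   condition label; exactly two labels per contrast.
#' @return An object of class `expr_matrix`: list with `values` and `groups`.
#' @export
expression_matrix <- function(values, groups) {
  stopifnot(is.matrix(values), is.numeric(values))
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene id in expression matrix")
  if (anyNA(values)) stop("missing values in expression matrix")
  if (any(values < 0)) stop("negative expression value")
  missing <- setdiff(colnames(values), names(groups))
  if (length(missing))
    stop("samples missing from condition map: ",
         paste(missing, collapse = ", "))
  groups <- groups[colnames(values)]
  structure(list(values = values, groups = groups), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat("expr_matrix:", nrow(x$values), "genes x", ncol(x$values),
      "samples; groups:", paste(unique(x$groups), collapse = ", "), "\n")
  invisible(x)
}

#' Read an expression table (TSV)
#'
#' Expects a header row of sample ids and a first column of gene ids.
#'
#' @param path Input TSV.
#' @param condition_map Named character vector, sample -> condition label.
#' @return An `expr_matrix`.
#' @export
read_expression_table <- function(path, condition_map) {
  x <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                         stringsAsFactors = FALSE)
  genes <- x[[1]]
  if (anyDuplicated(genes)) stop("duplicate gene id in ", path)
  m <- as.matrix(x[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric expression values in ", path)
  rownames(m) <- genes
  expression_matrix(m, condition_map)
}

#' Write an expression table (TSV)
#'
#' @param expr An `expr_matrix`.
#' @param path Output TSV.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(expr, path) {
  df <- data.frame(gene_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Internal: columns of a group label.
group_columns <- function(expr, group) {
  cols <- names(expr$groups)[expr$groups == group]
  if (length(cols) == 0) stop("group label not present in matrix: ", group)
  cols
}
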