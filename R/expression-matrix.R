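#' Expression matrix container
#'
#' A light container for a genes x columns expression matrix. Rows are genes,
#' columns are cells (single-cell data) or samples (bulk data). The `scale`
#' flag records whether entries are raw counts or counts-per-million (CPM).
#'
#' @param values Numeric matrix (genes x columns) with unique, non-empty
#'   rownames (gene ids) and colnames (cell/sample ids). Entries must be
#'   finite and non-negative.
#' @param scale Either `"counts"` or `"cpm"`.
#' @return An object of class `expression_matrix` with fields `values` and
#'   `scale`.
#' @examples
#' m <- matrix(c(1, 3, 2, 4), 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
#' em <- expression_matrix(m)
#' gene_ids(em)
#' @export
expression_matrix <- function(values, scale = c("counts", "cpm")) {
  scale <- match.arg(scale)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("'values' must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("'values' must carry gene ids as rownames and column ids as colnames")
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate column ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  }
  if (!all(is.finite(values))) stop("expression values must be finite")
  if (min(values) < 0) stop("expression values must be non-negative")
  if (scale == "cpm") {
    tot <- colSums(values)
    bad <- tot > 0 & abs(tot - 1e6) > 1e-6 * 1e6
    if (any(bad)) {
      stop("cpm-scaled columns must sum to 1e6: ",
           paste(colnames(values)[bad][seq_len(min(3, sum(bad)))], collapse = ", "))
    }
  }
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d genes x %d columns [%s]\n",
              nrow(x$values), ncol(x$values), x$scale))
  invisible(x)
}

#' @export
dim.expression_matrix <- function(x) dim(x$values)

#' @rdname expression_matrix
#' @param x An `expression_matrix`.
#' @export
gene_ids <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
column_ids <- function(x) colnames(x$values)

#' Annotated single-cell dataset
#'
#' Bundles a single-cell expression matrix with per-cell cell-type and
#' subject labels. Cell-type and subject order is fixed at first appearance
#' in the annotation, and all downstream matrices (reference profile,
#' proportions) use that order.
#'
#' @param expr An [expression_matrix()] of genes x cells.
#' @param cell_type Character vector of cell-type labels, one per cell
#'   (named by cell id, or in column order).
#' @param subject Character vector of subject labels, one per cell.
#' @return An object of class `single_cell_dataset` with fields `expr`,
#'   `cell_type`, `subject` (both label vectors aligned to `column_ids(expr)`
#'   and stored as factors whose level order is first appearance).
#' @export
single_cell_dataset <- function(expr, cell_type, subject) {
  stopifnot(inherits(expr, "expression_matrix"))
  cells <- column_ids(expr)
  align <- function(v, what) {
    if (length(v) != length(cells)) {
      stop(sprintf("'%s' must have one entry per cell (%d != %d)",
                   what, length(v), length(cells)))
    }
    v <- as.character(v)
    if (!is.null(names(v))) {
      if (!setequal(names(v), cells)) stop(sprintf("'%s' names do not match cell ids", what))
      v <- v[cells]
    }
    if (anyNA(v)) stop(sprintf("'%s' contains missing labels", what))
    factor(v, levels = unique(v))
  }
  cell_type <- align(cell_type, "cell_type")
  subject <- align(subject, "subject")
  if (nlevels(cell_type) < 2) stop("need at least 2 cell types")
  structure(list(expr = expr, cell_type = cell_type, subject = subject),
            class = "single_cell_dataset")
}

#' @export
print.single_cell_dataset <- function(x, ...) {
  cat(sprintf("<single_cell_dataset> %d genes x %d cells, %d cell types, %d subjects\n",
              nrow(x$expr$values), ncol(x$expr$values),
              nlevels(x$cell_type), nlevels(x$subject)))
  invisible(x)
}

#' Bulk RNA-seq dataset
#'
#' @param expr An [expression_matrix()] of genes x samples.
#' @return An object of class `bulk_dataset`.
#' @export
bulk_dataset <- function(expr) {
  stopifnot(inherits(expr, "expression_matrix"))
  if (ncol(expr$values) < 1) stop("bulk dataset needs at least one sample")
  structure(list(expr = expr), class = "bulk_dataset")
}

#' @export
print.bulk_dataset <- function(x, ...) {
  cat(sprintf("<bulk_dataset> %d genes x %d samples [%s]\n",
              nrow(x$expr$values), ncol(x$expr$values), x$expr$scale))
  invisible(x)
}

## internal: replace the values of an expression_matrix, keeping checks cheap
.replace_values <- function(em, values, scale = em$scale) {
  structure(list(values = values, scale = scale), class = "expression_matrix")
}

## internal: row-subset a single_cell_dataset / bulk_dataset by gene ids
.subset_genes_sc <- function(sc, genes) {
  sc$expr <- .replace_values(sc$expr, sc$expr$values[genes, , drop = FALSE])
  sc
}

.subset_genes_bulk <- function(bulk, genes) {
  bulk$expr <- .replace_values(bulk$expr, bulk$expr$values[genes, , drop = FALSE])
  bulk
}
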