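#' Build the single-cell reference profile
#'
#' The reference profile Z is a genes x cell-types matrix whose column c is
#' the mean CPM expression over all cells of type c, pooled across subjects.
#' Pooling (rather than averaging per-subject means) is robust to unbalanced
#' per-subject cell counts.
#'
#' @param sc A [single_cell_dataset()] whose expression is CPM-scaled.
#' @return A list of class `reference_profile` with fields `Z` (genes x C
#'   matrix), `cell_types`, `gene_ids`.
#' @export
build_reference <- function(sc) {
  stopifnot(inherits(sc, "single_cell_dataset"))
  if (sc$expr$scale != "cpm") stop("build_reference expects CPM-scaled single-cell data")
  types <- levels(sc$cell_type)
  counts <- table(sc$cell_type)
  if (any(counts == 0)) {
    stop("cell type(s) with zero cells: ", paste(types[counts == 0], collapse = ", "))
  }
  Z <- vapply(types, function(tp) {
    rowMeans(sc$expr$values[, sc$cell_type == tp, drop = FALSE])
  }, numeric(nrow(sc$expr$values)))
  dimnames(Z) <- list(gene_ids(sc$expr), types)
  structure(list(Z = Z, cell_types = types, gene_ids = gene_ids(sc$expr)),
            class = "reference_profile")
}

#' @export
print.reference_profile <- function(x, ...) {
  cat(sprintf("<reference_profile> %d genes x %d cell types\n",
              nrow(x$Z), ncol(x$Z)))
  invisible(x)
}

#' Cell-type proportions observed in the single-cell data
#'
#' For each subject j, the fraction of that subject's cells annotated as
#' each cell type. Columns lie on the unit simplex.
#'
#' @param sc A [single_cell_dataset()].
#' @return A C x J matrix (cell types x subjects); columns sum to one.
#' @export
observed_proportions <- function(sc) {
  stopifnot(inherits(sc, "single_cell_dataset"))
  tab <- table(sc$cell_type, sc$subject)
  n <- colSums(tab)
  if (any(n == 0)) {
    stop("subject(s) with zero cells: ",
         paste(colnames(tab)[n == 0], collapse = ", "))
  }
  P <- sweep(unclass(tab), 2, n, "/")
  dimnames(P) <- list(levels(sc$cell_type), levels(sc$subject))
  P
}

#' Pseudo-bulk expression from a reference profile and proportions
#'
#' The pseudo-bulk for subject j is the proportion-weighted sum of
#' reference columns, `Y = Z %*% P` (genes x subjects).
#'
#' @param ref A `reference_profile` from [build_reference()].
#' @param P A C x J proportion matrix with rownames equal to
#'   `ref$cell_types` in the same order.
#' @return A genes x J matrix with gene and subject dimnames.
#' @export
pseudo_bulk <- function(ref, P) {
  stopifnot(inherits(ref, "reference_profile"), is.matrix(P))
  if (!identical(rownames(P), ref$cell_types)) {
    stop("cell-type labels of proportions do not match the reference profile")
  }
  ref$Z %*% P
}

## validate that each column of P lies on the unit simplex
.check_simplex <- function(P, tol = 1e-8) {
  if (min(P) < -tol) stop("proportions must be non-negative")
  s <- colSums(P)
  if (any(abs(s - 1) > tol)) stop("proportion columns must sum to one")
  invisible(TRUE)
}
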