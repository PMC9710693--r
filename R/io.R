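#' Read an expression matrix from disk
#'
#' CSV/TSV layout: first column gene id, header row of column ids.
#' MatrixMarket (`mtx`) layout: coordinate file plus sidecar `genes.txt` and
#' `barcodes.txt` (one id per line) in the same directory, or at paths given
#' explicitly.
#'
#' @param path Path to the matrix file.
#' @param format One of `"csv"`, `"tsv"`, `"mtx"`. Default guesses from the
#'   file extension.
#' @param genes_path,cells_path For `mtx` only: paths to the row/column id
#'   sidecar files; default `genes.txt` / `barcodes.txt` next to `path`.
#' @return An [expression_matrix()] with `scale = "counts"`, identifiers in
#'   file order.
#' @export
read_expression <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                            genes_path = NULL, cells_path = NULL) {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "tsv", mtx = "mtx",
                     stop("cannot guess format from extension '", ext, "'"))
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, row.names = NULL,
                        check.names = FALSE, stringsAsFactors = FALSE),
      error = function(e) stop("parse error in ", path, ": ", conditionMessage(e)))
    if (ncol(df) < 2) stop("parse error in ", path, ": need gene id column plus data")
    ids <- as.character(df[[1]])
    m <- as.matrix(df[, -1, drop = FALSE])
    if (!is.numeric(m)) {
      bad <- which(!vapply(df[-1], is.numeric, logical(1)))[1]
      stop("parse error in ", path, ": non-numeric entries in column '",
           colnames(df)[bad + 1], "'")
    }
    rownames(m) <- ids
  } else {
    dir <- dirname(path)
    if (is.null(genes_path)) genes_path <- file.path(dir, "genes.txt")
    if (is.null(cells_path)) cells_path <- file.path(dir, "barcodes.txt")
    for (p in c(genes_path, cells_path)) {
      if (!file.exists(p)) stop("mtx sidecar file not found: ", p)
    }
    mm <- tryCatch(Matrix::readMM(path),
                   error = function(e) stop("parse error in ", path, ": ",
                                            conditionMessage(e)))
    genes <- readLines(genes_path)
    cells <- readLines(cells_path)
    if (nrow(mm) != length(genes)) {
      stop("mtx dimension mismatch: ", nrow(mm), " rows but ",
           length(genes), " gene ids in ", genes_path)
    }
    if (ncol(mm) != length(cells)) {
      stop("mtx dimension mismatch: ", ncol(mm), " columns but ",
           length(cells), " ids in ", cells_path)
    }
    m <- as.matrix(mm)
    dimnames(m) <- list(genes, cells)
  }
  expression_matrix(m, scale = "counts")
}

#' Write an expression matrix to disk
#'
#' Inverse of [read_expression()]; round-trips values and identifiers.
#'
#' @param m An [expression_matrix()].
#' @param path Output path.
#' @param format `"csv"`, `"tsv"` or `"mtx"` (sidecar `genes.txt` and
#'   `barcodes.txt` are written next to the mtx file).
#' @return `path`, invisibly.
#' @export
write_expression <- function(m, path, format = c("csv", "tsv", "mtx")) {
  stopifnot(inherits(m, "expression_matrix"))
  format <- match.arg(format)
  if (format %in% c("csv", "tsv")) {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene_id = gene_ids(m), m$values, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  } else {
    Matrix::writeMM(Matrix::Matrix(m$values, sparse = TRUE), path)
    dir <- dirname(path)
    writeLines(gene_ids(m), file.path(dir, "genes.txt"))
    writeLines(column_ids(m), file.path(dir, "barcodes.txt"))
  }
  invisible(path)
}

#' Read a cell annotation table
#'
#' TSV with columns `cell_id`, `cell_type`, `subject`.
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with those three character columns.
#' @export
read_cell_annotations <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("cell_id", "cell_type", "subject")
  miss <- setdiff(need, colnames(df))
  if (length(miss)) stop("annotation file missing columns: ", paste(miss, collapse = ", "))
  df[need]
}

#' Convert counts to counts-per-million
#'
#' Each column is divided by its total and multiplied by 1e6, so nonzero
#' columns sum to one million. All-zero columns pass through unchanged with
#' a warning (empty cells are tolerated here and dropped from covariance
#' computations downstream).
#'
#' @param m An [expression_matrix()] with `scale = "counts"`.
#' @return The CPM-scaled [expression_matrix()].
#' @export
cpm_normalize <- function(m) {
  stopifnot(inherits(m, "expression_matrix"))
  if (m$scale != "counts") stop("cpm_normalize expects a counts-scale matrix")
  tot <- colSums(m$values)
  zero <- tot == 0
  if (any(zero)) {
    warning(sum(zero), " all-zero column(s) left unnormalized: ",
            paste(colnames(m$values)[zero][seq_len(min(3, sum(zero)))], collapse = ", "))
  }
  scale_by <- ifelse(zero, 0, 1e6 / tot)
  v <- sweep(m$values, 2, scale_by, "*")
  .replace_values(m, v, scale = "cpm")
}

#' Restrict single-cell and bulk data to their common genes
#'
#' Both datasets are subset to the intersection of their gene ids and
#' reordered lexicographically so every downstream matrix is deterministic.
#'
#' @param sc A [single_cell_dataset()].
#' @param bulk A [bulk_dataset()].
#' @return A list with elements `sc` and `bulk` on the shared gene space.
#' @export
align_genes <- function(sc, bulk) {
  stopifnot(inherits(sc, "single_cell_dataset"), inherits(bulk, "bulk_dataset"))
  common <- intersect(gene_ids(sc$expr), gene_ids(bulk$expr))
  if (length(common) == 0) stop("no genes shared between single-cell and bulk data")
  common <- sort(common, method = "radix")
  list(sc = .subset_genes_sc(sc, common), bulk = .subset_genes_bulk(bulk, common))
}

#' Pre-processing gene filters
#'
#' Removes, from both datasets at once: genes with zero variance across
#' single cells; genes with an all-zero bulk row; and mitochondrial genes,
#' recognized case-insensitively by gene-symbol prefix. Gene order is
#' otherwise preserved.
#'
#' @param sc A [single_cell_dataset()] (gene space already aligned with `bulk`).
#' @param bulk A [bulk_dataset()].
#' @param mito_prefixes Character vector of prefixes marking mitochondrial
#'   genes; default `c("MT-", "mt-")` (matching is case-insensitive, so the
#'   default covers "Mt-" etc.).
#' @return A list with filtered `sc` and `bulk`, plus an attribute
#'   `"removed"` giving per-rule counts.
#' @export
filter_genes <- function(sc, bulk, mito_prefixes = c("MT-", "mt-")) {
  stopifnot(inherits(sc, "single_cell_dataset"), inherits(bulk, "bulk_dataset"))
  gs <- gene_ids(sc$expr)
  if (!identical(gs, gene_ids(bulk$expr))) {
    stop("gene spaces differ; call align_genes() first")
  }
  v <- .row_vars(sc$expr$values)
  zero_var <- v <= 0
  zero_bulk <- rowSums(bulk$expr$values) == 0
  pat <- paste0("^(", paste(gsub("([][{}()+*^$|\\\\?.-])", "\\\\\\1",
                                 unique(tolower(mito_prefixes))), collapse = "|"), ")")
  mito <- grepl(pat, tolower(gs))
  drop <- zero_var | zero_bulk | mito
  if (all(drop)) stop("all genes removed by pre-processing filters")
  keep <- gs[!drop]
  out <- list(sc = .subset_genes_sc(sc, keep), bulk = .subset_genes_bulk(bulk, keep))
  attr(out, "removed") <- c(zero_variance_sc = sum(zero_var),
                            all_zero_bulk = sum(zero_bulk),
                            mitochondrial = sum(mito))
  out
}

## row variances with divisor n, single pass over a (possibly large) matrix
.row_vars <- function(m) {
  mu <- rowMeans(m)
  rowMeans(m * m) - mu * mu
}
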