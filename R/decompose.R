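#' Simplex-constrained least-squares proportions for one sample
#'
#' Minimizes `||Z p - x||^2` subject to `p >= 0` and `sum(p) = 1`, as a
#' convex quadratic program solved by the Goldfarb-Idnani dual active-set
#' method. When Z has collinear columns (rank-deficient Gram matrix) a tiny
#' ridge is added, which selects the minimum-Euclidean-norm solution among
#' the tied minimizers, and a warning names the collinear cell types.
#'
#' @param Z Reference matrix, genes x C (a `reference_profile` is accepted).
#' @param x Length-G expression vector for one bulk sample.
#' @return A list with `p` (length-C simplex vector, named by cell type)
#'   and `residual` (`||Z p - x||`).
#' @export
solve_proportions <- function(Z, x) {
  if (inherits(Z, "reference_profile")) Z <- Z$Z
  stopifnot(is.matrix(Z), is.numeric(x))
  if (length(x) != nrow(Z)) stop("length of x must equal nrow(Z)")
  if (!all(is.finite(Z)) || !all(is.finite(x))) stop("inputs must be finite")
  C <- ncol(Z)
  if (nrow(Z) < C) {
    warning("fewer genes (", nrow(Z), ") than cell types (", C,
            "); proportions may not be identifiable")
  }
  ## scale the objective so the QP tolerances are size-independent
  sc <- max(abs(Z), 1e-300)
  Zs <- Z / sc
  xs <- x / sc
  D <- crossprod(Zs)
  d <- crossprod(Zs, xs)[, 1]
  qr_rank <- qr(Zs)$rank
  if (qr_rank < C) {
    dup <- colnames(Z)
    warning("reference columns are collinear (rank ", qr_rank, " < ", C,
            if (!is.null(dup)) paste0("; types: ", paste(dup, collapse = ", ")) else "",
            "); returning the minimum-norm solution")
    diag(D) <- diag(D) + 1e-10 * mean(diag(D))
  }
  A <- cbind(rep(1, C), diag(C))
  b0 <- c(1, rep(0, C))
  sol <- tryCatch(
    quadprog::solve.QP(D, d, A, b0, meq = 1),
    error = function(e) {
      diag(D) <- diag(D) + 1e-8 * mean(diag(D))
      tryCatch(quadprog::solve.QP(D, d, A, b0, meq = 1),
               error = function(e2) stop("constrained least-squares solver failed: ",
                                         conditionMessage(e2)))
    })
  p <- pmax(sol$solution, 0)
  p <- p / sum(p)
  names(p) <- colnames(Z)
  list(p = p, residual = sqrt(sum((Z %*% p - x)^2)))
}

## Shared pipeline up to marker-restricted Z, Y, X; both `decompose()` and
## the benchmark reuse it so marker selection is not recomputed per mode.
.prepare_decomposition <- function(sc, bulk, threshold = 0.5,
                                   mito_prefixes = c("MT-", "mt-"),
                                   use_de_prefilter = FALSE, alpha = 0.05) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE)
    })
  }
  aligned <- stage("align_genes", align_genes(sc, bulk))
  flt <- stage("filter_genes",
               filter_genes(aligned$sc, aligned$bulk, mito_prefixes = mito_prefixes))
  counts <- c(common = nrow(aligned$sc$expr$values),
              filtered = nrow(flt$sc$expr$values))
  sc_f <- flt$sc
  bulk_f <- flt$bulk
  sc_f$expr <- stage("cpm_normalize", suppressWarnings(cpm_normalize(sc_f$expr)))
  bulk_cpm <- stage("cpm_normalize", suppressWarnings(cpm_normalize(bulk_f$expr)))
  ref <- stage("build_reference", build_reference(sc_f))
  P_sc <- stage("observed_proportions", observed_proportions(sc_f))
  Y <- stage("pseudo_bulk", pseudo_bulk(ref, P_sc))
  tab <- stage("detection_fractions", detection_fractions(flt$sc))
  if (use_de_prefilter) tab <- stage("de_prefilter", de_prefilter(flt$sc, tab, alpha))
  mk <- stage("select_markers", select_markers(tab, threshold = threshold))
  counts["markers"] <- length(unique(mk$gene_id))
  list(Z = restrict_to_markers(ref$Z, mk),
       Y = restrict_to_markers(Y, mk),
       X = restrict_to_markers(bulk_cpm$values, mk),
       sc_proportions = P_sc,
       markers = mk,
       cell_types = ref$cell_types,
       gene_counts = counts)
}

## transform + per-sample solve, given prepared marker-restricted matrices
.solve_stage <- function(prep, mode, floor = 1e-8) {
  Xt <- switch(mode,
               none = prep$X,
               univariate = univariate_transform(prep$X, prep$Y),
               multivariate = multivariate_transform(prep$X, prep$Y, floor = floor),
               stop("unknown mode: ", mode))
  fits <- lapply(seq_len(ncol(Xt)), function(i) solve_proportions(prep$Z, Xt[, i]))
  P <- vapply(fits, `[[`, numeric(ncol(prep$Z)), "p")
  dimnames(P) <- list(prep$cell_types, colnames(prep$X))
  res <- vapply(fits, `[[`, numeric(1), "residual")
  names(res) <- colnames(prep$X)
  structure(list(proportions = P, residual_norm = res, mode = mode,
                 gene_counts = prep$gene_counts, markers = prep$markers),
            class = "decomposition_result")
}

#' @export
print.decomposition_result <- function(x, ...) {
  cat(sprintf("<decomposition_result> mode=%s, %d cell types x %d samples, %d marker genes\n",
              x$mode, nrow(x$proportions), ncol(x$proportions),
              length(unique(x$markers$gene_id))))
  print(round(x$proportions, 4))
  invisible(x)
}

#' End-to-end cell-type decomposition of bulk RNA-seq
#'
#' Runs the full pipeline: align the gene spaces, apply the pre-processing
#' filters, CPM-normalize both datasets, build the reference profile and
#' observed single-cell proportions, form the pseudo-bulk, select marker
#' genes by detection-percentage difference, restrict all matrices to
#' markers, transform the bulk (per `mode`), and solve the sum-to-one
#' non-negative least-squares problem for every bulk sample.
#'
#' @param sc A [single_cell_dataset()] with counts.
#' @param bulk A [bulk_dataset()] with counts.
#' @param mode `"multivariate"` (covariance-based transform, the default),
#'   `"univariate"` (gene-wise transform), or `"none"` (no transform; for
#'   ablation and noiseless checks).
#' @param threshold Marker detection-difference threshold, default 0.5.
#' @param mito_prefixes Mitochondrial gene-id prefixes, default
#'   `c("MT-", "mt-")`.
#' @param floor Relative eigenvalue floor for inverse roots, default 1e-8.
#' @param use_de_prefilter Apply the Wilcoxon/BH marker pre-filter
#'   ([de_prefilter()]) before the percentage rule; default `FALSE`.
#' @param verbose Print per-stage gene counts.
#' @return A `decomposition_result`: `proportions` (C x samples, columns on
#'   the unit simplex), `residual_norm` per sample, `mode`, `gene_counts`
#'   surviving each stage, and the marker table.
#' @examples
#' sim <- simulate_single_cell(simulation_config(
#'   n_genes = 300, n_cells = 150, n_types = 3, n_subjects = 3, seed = 7))
#' bk <- simulate_bulk(sim$sc, n_bulk = 5, noise_cv = 0, seed = 8)
#' fit <- decompose(sim$sc, bk$bulk, mode = "none")
#' mae(bk$true_proportions, fit$proportions)
#' @export
decompose <- function(sc, bulk, mode = c("multivariate", "univariate", "none"),
                      threshold = 0.5, mito_prefixes = c("MT-", "mt-"),
                      floor = 1e-8, use_de_prefilter = FALSE, verbose = FALSE) {
  mode <- match.arg(mode)
  prep <- .prepare_decomposition(sc, bulk, threshold = threshold,
                                 mito_prefixes = mito_prefixes,
                                 use_de_prefilter = use_de_prefilter)
  if (verbose) {
    message("genes per stage: ",
            paste(names(prep$gene_counts), prep$gene_counts,
                  sep = "=", collapse = ", "))
  }
  .solve_stage(prep, mode, floor = floor)
}
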