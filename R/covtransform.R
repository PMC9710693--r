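#' Sample moments of an expression matrix
#'
#' Row means and the sample covariance across columns. The covariance uses
#' divisor n (the number of columns), not n - 1; every downstream shrinkage
#' and transform quantity uses the same convention.
#'
#' @param m A genes x n numeric matrix, or an [expression_matrix()].
#' @return A list of class `moment_summary` with fields `mean` (length-G),
#'   `cov` (G x G, divisor n), `n`.
#' @export
moments <- function(m) {
  v <- if (inherits(m, "expression_matrix")) m$values else m
  stopifnot(is.matrix(v))
  n <- ncol(v)
  if (n < 2) stop("need at least 2 columns to compute moments")
  mu <- rowMeans(v)
  xc <- v - mu
  cv <- tcrossprod(xc) / n
  structure(list(mean = mu, cov = cv, n = n), class = "moment_summary")
}

#' Ledoit-Wolf linear shrinkage covariance estimate
#'
#' Shrinks the sample covariance S (divisor n) towards the scaled identity
#' nu * I with nu = trace(S)/G, using the plug-in intensity that minimizes
#' the expected squared Frobenius loss, clipped to \[0, 1\]. The result
#' `(1 - rho) * S + rho * nu * I` is positive-definite whenever nu > 0 and
#' rho > 0, even when variables far outnumber observations.
#'
#' The estimate is kept in factored form (`alpha * I + B %*% t(B)` with B of
#' rank at most n), so matrix roots can be applied in O(G n^2) without ever
#' forming the G x G matrix; `as.matrix()` materializes it.
#'
#' @param x A G x n data matrix (variables in rows, observations in
#'   columns). Centering uses the row means; the intensity is computed from
#'   the centered columns with the same 1/n convention as [moments()].
#' @param intensity Optional forced shrinkage intensity in \[0, 1\];
#'   `NULL` (default) uses the plug-in estimate.
#' @return A list of class `shrunk_cov` with fields `intensity`,
#'   `target_scale` (nu), `mean`, `n`, `G`, and the low-rank factor `B`.
#' @export
lw_shrink <- function(x, intensity = NULL) {
  v <- if (inherits(x, "expression_matrix")) x$values else x
  stopifnot(is.matrix(v))
  G <- nrow(v)
  n <- ncol(v)
  if (n < 2) stop("need at least 2 observations")
  mu <- rowMeans(v)
  xc <- v - mu
  ## All scalars below depend on the centered data only through inner
  ## products, computed from whichever Gram matrix (n x n or G x G) is
  ## smaller: col_sq = x_k' x_k, s_norm2 = ||S||_F^2 with S = xc xc'/n,
  ## and qf = sum_k x_k' S x_k = n * s_norm2.
  if (n <= G) {
    gram <- crossprod(xc)                     # n x n
    col_sq <- diag(gram)
    s_norm2 <- sum(gram * gram) / n^2
  } else {
    outer_g <- tcrossprod(xc)                 # G x G
    col_sq <- colSums(xc * xc)
    s_norm2 <- sum(outer_g * outer_g) / n^2
  }
  tr_s <- sum(col_sq) / n
  nu <- tr_s / G
  if (nu <= 0) stop("all-zero covariance: no shrinkage target exists")
  d2 <- s_norm2 / G - nu^2                    # ||S - nu I||_F^2 / G
  if (is.null(intensity)) {
    if (d2 <= .Machine$double.eps * nu^2) {
      rho <- 0                                # S already equals nu * I
    } else {
      b2bar <- (sum(col_sq^2) - n * s_norm2) / (n^2 * G)
      b2 <- min(b2bar, d2)
      rho <- min(1, max(0, b2 / d2))
    }
  } else {
    if (intensity < 0 || intensity > 1) stop("'intensity' must be in [0, 1]")
    rho <- intensity
  }
  structure(list(intensity = rho, target_scale = nu, mean = mu, n = n, G = G,
                 B = sqrt((1 - rho) / n) * xc),
            class = "shrunk_cov")
}

#' @export
print.shrunk_cov <- function(x, ...) {
  cat(sprintf("<shrunk_cov> %d x %d, intensity %.4g, target scale %.4g\n",
              x$G, x$G, x$intensity, x$target_scale))
  invisible(x)
}

#' @export
as.matrix.shrunk_cov <- function(x, ...) {
  m <- tcrossprod(x$B)
  diag(m) <- diag(m) + x$intensity * x$target_scale
  m
}

## Apply a matrix power (+1/2 or -1/2) of a shrunk covariance to M without
## forming the G x G matrix. The estimate is alpha*I + B B'; with B = U D V',
## its eigenvalues are alpha + d_i^2 on span(U) and alpha elsewhere.
## Eigenvalues below floor * lambda_max are raised to the floor first.
.shrunk_cov_pow_mult <- function(sc, power, M, floor = 1e-8) {
  alpha <- sc$intensity * sc$target_scale
  sv <- svd(sc$B, nu = min(dim(sc$B)), nv = 0)
  d2 <- sv$d^2
  lam_max <- max(alpha + if (length(d2)) d2[1] else 0, alpha)
  if (lam_max <= 0) stop("zero matrix has no matrix root")
  lam_min <- floor * lam_max
  f_top <- pmax(alpha + d2, lam_min)^power
  f_tail <- max(alpha, lam_min)^power
  U <- sv$u
  proj <- crossprod(U, M)
  f_tail * M + U %*% ((f_top - f_tail) * proj)
}

## check symmetry up to a relative tolerance
.check_symmetric <- function(m, tol = 1e-8) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) stop("matrix must be square")
  ref <- max(abs(m), 1e-300)
  if (max(abs(m - t(m))) > tol * ref) stop("matrix is not symmetric")
  invisible(TRUE)
}

#' Symmetric matrix root and inverse root
#'
#' Computed by symmetric eigendecomposition; eigenvalues below
#' `floor * max(eigenvalue)` are raised to that floor before taking the
#' power, which guards inverse roots against numerically zero eigenvalues.
#'
#' @param c A symmetric matrix (checked within a relative tolerance of 1e-8).
#' @param floor Relative eigenvalue floor, default 1e-8.
#' @return The symmetric matrix `c^(1/2)` (resp. `c^(-1/2)`).
#' @export
sym_root <- function(c, floor = 1e-8) .sym_pow(c, 0.5, floor)

#' @rdname sym_root
#' @export
sym_inv_root <- function(c, floor = 1e-8) .sym_pow(c, -0.5, floor)

.sym_pow <- function(m, power, floor) {
  .check_symmetric(m)
  stopifnot(floor > 0)
  e <- eigen((m + t(m)) / 2, symmetric = TRUE)
  lam_max <- max(e$values)
  if (lam_max <= 0) stop("matrix has no positive eigenvalues")
  lam <- pmax(e$values, floor * lam_max)
  e$vectors %*% (lam^power * t(e$vectors))
}

## shared input checks for the two bulk transformations
.check_transform_inputs <- function(bulk, Y) {
  X <- if (inherits(bulk, "bulk_dataset")) bulk$expr$values else bulk
  stopifnot(is.matrix(X), is.matrix(Y))
  if (nrow(X) != nrow(Y)) stop("bulk and pseudo-bulk have different gene counts")
  if (!is.null(rownames(X)) && !is.null(rownames(Y)) &&
      !identical(rownames(X), rownames(Y))) {
    stop("bulk and pseudo-bulk gene ids differ or are ordered differently")
  }
  X
}

#' Univariate (gene-wise) bulk transformation
#'
#' For each gene independently, the bulk expression is location-scale
#' matched to the pseudo-bulk distribution:
#' `Xu_gi = Ybar_g + sqrt(J/(J+1)) * sqrt(sY_gg / sX_gg) * (X_gi - Xbar_g)`,
#' where the variances use divisor J (pseudo-bulk) and I (bulk), and
#' J/(J+1) deflates the single-cell-derived variance because the number of
#' single-cell subjects J is small.
#'
#' @param bulk A [bulk_dataset()] (CPM scale) or genes x I matrix.
#' @param Y Pseudo-bulk genes x J matrix from [pseudo_bulk()].
#' @return The transformed genes x I matrix.
#' @export
univariate_transform <- function(bulk, Y) {
  X <- .check_transform_inputs(bulk, Y)
  J <- ncol(Y)
  I <- ncol(X)
  if (J < 2 || I < 2) stop("need at least 2 pseudo-bulk subjects and 2 bulk samples")
  ybar <- rowMeans(Y)
  xbar <- rowMeans(X)
  sy <- .row_vars(Y)
  sx <- .row_vars(X)
  if (any(sx <= 0)) {
    stop("zero bulk variance for gene(s): ",
         paste(rownames(X)[sx <= 0][seq_len(min(5, sum(sx <= 0)))], collapse = ", "),
         " (should have been removed by filtering)")
  }
  fac <- sqrt(J / (J + 1)) * sqrt(sy / sx)
  out <- ybar + fac * (X - xbar)
  dimnames(out) <- dimnames(X)
  out
}

#' Multivariate (covariance-based) bulk transformation
#'
#' Whitens the centered bulk expression with the inverse root of its
#' shrinkage-estimated covariance and recolors it with the root of the
#' shrinkage-estimated pseudo-bulk covariance:
#' `Xm = Ybar + sqrt(J/(J+1)) * SYs^(1/2) %*% SXs^(-1/2) %*% (X - Xbar)`.
#' Both covariances (divisor J resp. I) are Ledoit-Wolf shrunk
#' ([lw_shrink()]), which makes the inverse root well defined even though
#' genes typically far outnumber samples. The product of the two roots is
#' applied in the printed order and not symmetrized. The output's sample
#' mean is exactly `Ybar` and its column count is that of the bulk.
#'
#' Matrix roots are applied through the factored low-rank form of the
#' shrunk covariances, so cost is O(G * (I^2 + J^2)) rather than O(G^3);
#' on small inputs the result agrees with the dense [sym_root()] route.
#'
#' @param bulk A [bulk_dataset()] (CPM scale) or genes x I matrix,
#'   restricted to marker genes.
#' @param Y Pseudo-bulk genes x J matrix on the same genes.
#' @param floor Relative eigenvalue floor for the inverse root, default
#'   1e-8; with shrinkage active it is normally inactive.
#' @param intensity Optional forced shrinkage intensity (applied to both
#'   covariances) for diagnostics; `NULL` (default) estimates each.
#' @return The transformed genes x I matrix.
#' @export
multivariate_transform <- function(bulk, Y, floor = 1e-8, intensity = NULL) {
  X <- .check_transform_inputs(bulk, Y)
  J <- ncol(Y)
  I <- ncol(X)
  if (J < 2 || I < 2) stop("need at least 2 pseudo-bulk subjects and 2 bulk samples")
  sy <- lw_shrink(Y, intensity = intensity)
  xc <- X - rowMeans(X)
  if (max(abs(xc)) == 0) {
    ## degenerate bulk with identical columns: Eq. maps every column to Ybar
    out <- matrix(sy$mean, nrow(X), I, dimnames = dimnames(X))
    return(out)
  }
  sx <- lw_shrink(X, intensity = intensity)
  w <- .shrunk_cov_pow_mult(sx, -0.5, xc, floor = floor)
  out <- sy$mean + sqrt(J / (J + 1)) * .shrunk_cov_pow_mult(sy, 0.5, w, floor = floor)
  dimnames(out) <- dimnames(X)
  out
}
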