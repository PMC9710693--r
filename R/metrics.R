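## check two proportion matrices are comparable, return them aligned
.check_pair <- function(true, est) {
  stopifnot(is.matrix(true), is.matrix(est))
  if (!all(dim(true) == dim(est))) stop("proportion matrices differ in shape")
  if (!is.null(rownames(true)) && !is.null(rownames(est))) {
    if (!setequal(rownames(true), rownames(est))) {
      stop("cell-type labels differ between true and estimated proportions")
    }
    est <- est[rownames(true), , drop = FALSE]
  }
  if (!is.null(colnames(true)) && !is.null(colnames(est))) {
    if (!setequal(colnames(true), colnames(est))) {
      stop("sample labels differ between true and estimated proportions")
    }
    est <- est[, colnames(true), drop = FALSE]
  }
  list(true = true, est = est)
}

#' Accuracy metrics for estimated cell-type proportions
#'
#' Element-wise mean squared error, mean absolute error, and the Spearman
#' rank correlation between true and estimated proportion matrices, each
#' computed over all C x K entries pooled (one summary number per method).
#' Matrices with cell-type / sample dimnames are aligned by label first.
#'
#' @param true,est C x K proportion matrices with matching labels.
#' @return A single number; `spearman_r` lies in \[-1, 1\] (ties get
#'   average ranks) and errors on constant input, where the rank
#'   correlation is undefined.
#' @export
mse <- function(true, est) {
  z <- .check_pair(true, est)
  mean((z$true - z$est)^2)
}

#' @rdname mse
#' @export
mae <- function(true, est) {
  z <- .check_pair(true, est)
  mean(abs(z$true - z$est))
}

#' @rdname mse
#' @export
spearman_r <- function(true, est) {
  z <- .check_pair(true, est)
  a <- as.vector(z$true)
  b <- as.vector(z$est)
  if (length(a) < 2) stop("need at least 2 entries for a rank correlation")
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("rank correlation undefined for a constant proportion matrix")
  }
  stats::cor(a, b, method = "spearman")
}
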