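# Small in-code fixtures shared across test files.

# A tiny annotated single-cell dataset with hand-controllable counts.
# `counts` is genes x cells; labels recycle over cells.
make_sc <- function(counts, types, subjects = "s1") {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("c", seq_len(ncol(counts)))
  }
  single_cell_dataset(expression_matrix(counts, scale = "counts"),
                      cell_type = rep_len(types, ncol(counts)),
                      subject = rep_len(subjects, ncol(counts)))
}

make_bulk <- function(counts) {
  if (is.null(rownames(counts))) {
    rownames(counts) <- paste0("g", seq_len(nrow(counts)))
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- paste0("b", seq_len(ncol(counts)))
  }
  bulk_dataset(expression_matrix(counts, scale = "counts"))
}

# A small but realistic simulated world used by several files.
small_world <- function(seed = 3, n_genes = 800, n_cells = 400) {
  cfg <- simulation_config(n_genes = n_genes, n_cells = n_cells, n_types = 4,
                           n_subjects = 6, seed = seed)
  simulate_single_cell(cfg)
}

# Exhaustive simplex grid search oracle for the constrained least-squares
# problem (C = 3 only): minimizes ||Z p - x|| over the step-h grid.
grid_search_simplex <- function(Z, x, h = 1e-3) {
  stopifnot(ncol(Z) == 3)
  p1 <- seq(0, 1, by = h)
  best <- NULL
  best_val <- Inf
  for (a in p1) {
    b <- seq(0, 1 - a, by = h)
    P <- rbind(a, b, 1 - a - b)
    vals <- colSums((Z %*% P - as.vector(x))^2)
    i <- which.min(vals)
    if (vals[i] < best_val) {
      best_val <- vals[i]
      best <- P[, i]
    }
  }
  best
}
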