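#' Simulation configuration
#'
#' Parameters of the synthetic single-cell generator. The defaults are the
#' benchmark conditions used throughout: 10 000 genes, 1000 cells, 5 cell
#' types, differential-expression probability 0.7 with log-normal DE
#' factors (location 3, scale 1).
#'
#' @param n_genes,n_cells,n_types Dimensions of the simulated dataset.
#' @param de_prob Probability that a gene is differentially expressed in a
#'   given cell type.
#' @param de_facLoc,de_facScale Location and scale (log scale) of the
#'   log-normal differential-expression factor; each factor is inverted
#'   (1/f, i.e. down-regulation) with probability 1/2.
#' @param n_bulk Number of pseudo-bulk samples generated per iteration.
#' @param n_subjects Number of single-cell subjects.
#' @param coexpr_blocks Number of correlated gene blocks; a per-cell latent
#'   factor shared within a block induces gene-gene co-expression.
#' @param coexpr_sd Log-scale standard deviation of the block latent effect
#'   (0 disables co-expression); default 0.3, a moderate module-level
#'   correlation.
#' @param lib_sd Log-scale sd of the per-cell library-size factor.
#' @param bcv Biological coefficient of variation of the negative-binomial
#'   counts (`size = 1/bcv^2`).
#' @param mean_meanlog,mean_sdlog Log-normal parameters of the baseline
#'   gene means.
#' @param noise_cv Coefficient of variation of the multiplicative gamma
#'   noise applied to simulated bulk samples (see [simulate_bulk()]).
#' @param seed Integer seed; the generator is bit-reproducible given
#'   (config, seed).
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 10000, n_cells = 1000, n_types = 5,
                              de_prob = 0.7, de_facLoc = 3, de_facScale = 1,
                              n_bulk = 20, n_subjects = 8,
                              coexpr_blocks = 10, coexpr_sd = 0.3,
                              lib_sd = 0.2, bcv = 0.3,
                              mean_meanlog = 1, mean_sdlog = 1,
                              noise_cv = 0.1, seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_cells = as.integer(n_cells),
              n_types = as.integer(n_types), de_prob = de_prob,
              de_facLoc = de_facLoc, de_facScale = de_facScale,
              n_bulk = as.integer(n_bulk), n_subjects = as.integer(n_subjects),
              coexpr_blocks = as.integer(coexpr_blocks), coexpr_sd = coexpr_sd,
              lib_sd = lib_sd, bcv = bcv,
              mean_meanlog = mean_meanlog, mean_sdlog = mean_sdlog,
              noise_cv = noise_cv, seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_genes > 0, n_cells > 0, n_types >= 2, n_subjects >= 1,
              n_bulk >= 1, de_prob >= 0, de_prob <= 1, de_facScale > 0,
              coexpr_blocks >= 1, coexpr_sd >= 0, lib_sd >= 0, bcv > 0,
              noise_cv >= 0)
  })
  structure(cfg, class = "simulation_config")
}

#' Uniform draw from the unit simplex
#'
#' A symmetric Dirichlet(1) draw: C independent Exp(1)/Gamma(1) variates
#' normalized to sum to one, which is uniform on the simplex.
#'
#' @param C Number of components (>= 2).
#' @param n Number of draws.
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A C x n matrix, each column non-negative and summing to 1.
#' @export
random_simplex <- function(C, n = 1, seed = NULL) {
  stopifnot(C >= 2, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(stats::rgamma(C * n, shape = 1), C, n)
  sweep(g, 2, colSums(g), "/")
}

#' Simulate an annotated single-cell dataset with known proportions
#'
#' A co-expression-aware negative-binomial generator. Baseline gene means
#' are log-normal; each gene is differentially expressed in each cell type
#' with probability `de_prob`, with log-normal multiplicative factors
#' (location `de_facLoc`, scale `de_facScale`), inverted with probability
#' 1/2. Genes are partitioned into `coexpr_blocks` blocks sharing a
#' per-cell latent log-normal factor (sd `coexpr_sd`), inducing gene-gene
#' correlation. Cells are assigned uniformly to subjects; each subject's
#' cell-type proportions are a fresh uniform simplex draw and cells are
#' typed accordingly. Counts are negative-binomial around the type-,
#' library- and block-scaled means (`size = 1/bcv^2`).
#'
#' @param cfg A [simulation_config()].
#' @return A list with `sc` (a [single_cell_dataset()] of counts) and
#'   `true_proportions` (C x n_subjects matrix of the per-subject sampling
#'   proportions; the realized per-subject fractions are available via
#'   [observed_proportions()]).
#' @export
simulate_single_cell <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  G <- cfg$n_genes; n <- cfg$n_cells; C <- cfg$n_types
  mu <- stats::rlnorm(G, cfg$mean_meanlog, cfg$mean_sdlog)
  de <- matrix(stats::rbinom(G * C, 1, cfg$de_prob) == 1, G, C)
  fac <- matrix(stats::rlnorm(G * C, cfg$de_facLoc, cfg$de_facScale), G, C)
  flip <- matrix(stats::runif(G * C) < 0.5, G, C)
  fac[flip] <- 1 / fac[flip]
  fac[!de] <- 1
  lam <- mu * fac                                    # G x C type means
  subj <- sample.int(cfg$n_subjects, n, replace = TRUE)
  P_true <- random_simplex(C, cfg$n_subjects)
  draw_types <- function() {
    vapply(subj, function(j) sample.int(C, 1, prob = P_true[, j]), integer(1))
  }
  type <- draw_types()
  if (length(unique(type)) < C) {
    type <- draw_types()                             # resample once
    if (length(unique(type)) < C) {
      stop("cell type(s) received zero cells; increase n_cells or rebalance proportions")
    }
  }
  lib <- stats::rlnorm(n, 0, cfg$lib_sd)
  block <- sample(rep_len(seq_len(cfg$coexpr_blocks), G))
  u <- matrix(stats::rnorm(cfg$coexpr_blocks * n), cfg$coexpr_blocks, n)
  co <- exp(cfg$coexpr_sd * u[block, , drop = FALSE] - cfg$coexpr_sd^2 / 2)
  m <- lam[, type, drop = FALSE] * rep(lib, each = G) * co
  counts <- matrix(stats::rnbinom(G * n, mu = m, size = 1 / cfg$bcv^2), G, n)
  storage.mode(counts) <- "double"
  dimnames(counts) <- list(sprintf("gene%05d", seq_len(G)),
                           sprintf("cell%05d", seq_len(n)))
  dimnames(P_true) <- list(sprintf("type%d", seq_len(C)),
                           sprintf("subject%d", seq_len(cfg$n_subjects)))
  sc <- single_cell_dataset(
    expression_matrix(counts, scale = "counts"),
    cell_type = factor(sprintf("type%d", type),
                       levels = sprintf("type%d", seq_len(C))),
    subject = factor(sprintf("subject%d", subj),
                     levels = sprintf("subject%d", seq_len(cfg$n_subjects))))
  list(sc = sc, true_proportions = P_true)
}

#' Simulate bulk samples as mixtures of the single-cell type profiles
#'
#' For each bulk sample a fresh uniform simplex vector is drawn; the sample
#' is the proportion-weighted mixture of the per-type mean relative
#' abundances (mean CPM over the cells of each type), so the mixing weights
#' are exactly the relative-abundance proportions the decomposition
#' estimates. The mixture is scaled to a bulk sequencing depth of
#' `bulk_depth` reads, optionally perturbed gene-wise by multiplicative
#' gamma noise with coefficient of variation `noise_cv` (0 gives noiseless
#' pseudo-bulk, the benchmark default), and rounded to counts.
#'
#' @param sc A [single_cell_dataset()] of counts.
#' @param n_bulk Number of bulk samples.
#' @param noise_cv Coefficient of variation of the gamma noise; default 0.1.
#' @param bulk_depth Target library size per bulk sample; default 3e7.
#' @param seed Optional seed.
#' @return A list with `bulk` (a [bulk_dataset()]) and `true_proportions`
#'   (C x n_bulk matrix; columns sum to 1).
#' @export
simulate_bulk <- function(sc, n_bulk = 20, noise_cv = 0.1, bulk_depth = 3e7,
                          seed = NULL) {
  stopifnot(inherits(sc, "single_cell_dataset"), n_bulk >= 1, noise_cv >= 0,
            bulk_depth > 0)
  if (!is.null(seed)) set.seed(seed)
  cp <- suppressWarnings(cpm_normalize(sc$expr))
  types <- levels(sc$cell_type)
  prof <- vapply(types, function(tp) {
    rowMeans(cp$values[, sc$cell_type == tp, drop = FALSE])
  }, numeric(nrow(cp$values)))
  Q <- random_simplex(length(types), n_bulk)
  dimnames(Q) <- list(types, sprintf("bulk%03d", seq_len(n_bulk)))
  B <- (prof %*% Q) * (bulk_depth / 1e6)
  if (noise_cv > 0) {
    shape <- 1 / noise_cv^2
    B <- B * matrix(stats::rgamma(length(B), shape = shape, rate = shape),
                    nrow(B), ncol(B))
  }
  B <- round(B)
  dimnames(B) <- list(gene_ids(sc$expr), colnames(Q))
  list(bulk = bulk_dataset(expression_matrix(B, scale = "counts")),
       true_proportions = Q)
}

#' Realized per-subject pseudo-bulk from a single-cell dataset
#'
#' Aggregates the counts of each subject's cells into one bulk sample (the
#' standard pseudo-bulk construction), giving one bulk sample per
#' single-cell subject whose true cell-type proportions are the subject's
#' realized single-cell fractions. This is the bulk design the simulation
#' benchmark uses by default: it evaluates the decomposition on bulk
#' samples drawn from the same population of mixtures the pseudo-bulk
#' reference describes.
#'
#' @param sc A [single_cell_dataset()] of counts.
#' @return A list with `bulk` (a [bulk_dataset()], one sample per subject)
#'   and `true_proportions` (C x J, the observed per-subject fractions).
#' @export
aggregate_subject_pseudobulk <- function(sc) {
  stopifnot(inherits(sc, "single_cell_dataset"))
  counts <- sc$expr$values
  agg <- vapply(levels(sc$subject), function(s) {
    rowSums(counts[, sc$subject == s, drop = FALSE])
  }, numeric(nrow(counts)))
  dimnames(agg) <- list(gene_ids(sc$expr), levels(sc$subject))
  truth <- observed_proportions(sc)
  list(bulk = bulk_dataset(expression_matrix(agg, scale = "counts")),
       true_proportions = truth)
}

#' Simulation benchmark of the decomposition modes
#'
#' Repeats, `n_iter` times: simulate a single-cell dataset, generate bulk
#' samples with known proportions from it, decompose the bulk with each
#' requested mode, and score the estimates (Spearman R over all pooled
#' entries, MSE, MAE). Reports per-mode averages over the successful
#' iterations. Iterations where a stage fails (e.g. a cell type without
#' markers) are excluded and counted.
#'
#' Three bulk designs are available. `"subject"` (default) uses the
#' realized per-subject pseudo-bulk aggregates
#' ([aggregate_subject_pseudobulk()]): bulk mixtures from the same subjects
#' the reference describes, carrying the count-level sampling noise of
#' ~n_cells/n_subjects cells each. `"noiseless"` uses the exact pseudo-bulk
#' construction `Y = Z %*% P` with P the observed per-subject proportions —
#' no count noise at all, the strictest reading of a noiseless pseudo-bulk
#' (note that on this design the univariate and multivariate transforms
#' coincide algebraically, since the bulk *is* the pseudo-bulk and the two
#' shrunk covariances cancel). `"fresh"` uses independent simplex-weighted
#' mixtures from [simulate_bulk()], a strictly harder setting in which the
#' distribution-matching transforms are handed a bulk cohort unrelated to
#' the single-cell subjects.
#'
#' Per-iteration seeds are `cfg$seed + iter - 1`, so results are
#' reproducible and mode comparisons share identical data.
#'
#' @param cfg A [simulation_config()].
#' @param n_iter Number of simulation iterations.
#' @param modes Subset of `c("multivariate", "univariate", "none")`.
#' @param bulk_design `"subject"` (per-subject pseudo-bulk, default),
#'   `"noiseless"` (exact `Z %*% P` pseudo-bulk) or `"fresh"` (independent
#'   mixtures).
#' @param noise_cv Bulk noise CV for `bulk_design = "fresh"`; default 0
#'   (noiseless pseudo-bulk).
#' @param threshold Marker threshold passed to the pipeline.
#' @param verbose Print a line per iteration.
#' @return A list of class `benchmark_summary`: `summary` (data.frame with
#'   per-mode mean R, MSE, MAE), `per_iteration` (long data.frame),
#'   `n_iter`, `n_failed`.
#' @export
benchmark <- function(cfg, n_iter = 25,
                      modes = c("multivariate", "univariate"),
                      bulk_design = c("subject", "noiseless", "fresh"),
                      noise_cv = 0, threshold = 0.5, verbose = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"), n_iter >= 1)
  bulk_design <- match.arg(bulk_design)
  modes <- match.arg(modes, c("multivariate", "univariate", "none"),
                     several.ok = TRUE)
  rows <- list()
  n_failed <- 0L
  for (it in seq_len(n_iter)) {
    it_seed <- cfg$seed + it - 1L
    cfg_it <- cfg
    cfg_it$seed <- it_seed
    res <- tryCatch({
      sim <- simulate_single_cell(cfg_it)
      bk <- switch(bulk_design,
        subject = aggregate_subject_pseudobulk(sim$sc),
        noiseless = {
          sc_cpm <- sim$sc
          sc_cpm$expr <- suppressWarnings(cpm_normalize(sc_cpm$expr))
          ref <- build_reference(sc_cpm)
          P <- observed_proportions(sc_cpm)
          Y <- pseudo_bulk(ref, P)
          list(bulk = bulk_dataset(expression_matrix(Y, scale = "counts")),
               true_proportions = P)
        },
        fresh = simulate_bulk(sim$sc, n_bulk = cfg$n_bulk,
                              noise_cv = noise_cv, seed = it_seed + 500000L))
      prep <- .prepare_decomposition(sim$sc, bk$bulk, threshold = threshold)
      lapply(modes, function(md) {
        fit <- .solve_stage(prep, md)
        data.frame(iteration = it, mode = md,
                   R = spearman_r(bk$true_proportions, fit$proportions),
                   MSE = mse(bk$true_proportions, fit$proportions),
                   MAE = mae(bk$true_proportions, fit$proportions),
                   n_markers = length(unique(prep$markers$gene_id)))
      })
    }, error = function(e) {
      warning("iteration ", it, " failed: ", conditionMessage(e), call. = FALSE)
      NULL
    })
    if (is.null(res)) {
      n_failed <- n_failed + 1L
    } else {
      rows <- c(rows, res)
      if (verbose) {
        message(sprintf("iter %d/%d: %s", it, n_iter,
                        paste(sprintf("%s MAE=%.4g", vapply(res, `[[`, "", "mode"),
                                      vapply(res, `[[`, 1, "MAE")), collapse = ", ")))
      }
    }
  }
  if (!length(rows)) stop("all benchmark iterations failed")
  per_iter <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per_iter, per_iter$mode), function(d) {
    data.frame(mode = d$mode[1], R = mean(d$R), MSE = mean(d$MSE),
               MAE = mean(d$MAE), iterations = nrow(d))
  }))
  agg <- agg[match(intersect(modes, agg$mode), agg$mode), , drop = FALSE]
  rownames(agg) <- NULL
  structure(list(summary = agg, per_iteration = per_iter,
                 n_iter = n_iter, n_failed = n_failed),
            class = "benchmark_summary")
}

#' @export
print.benchmark_summary <- function(x, ...) {
  cat(sprintf("<benchmark_summary> %d iterations (%d failed)\n",
              x$n_iter, x$n_failed))
  print(x$summary, row.names = FALSE)
  invisible(x)
}
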