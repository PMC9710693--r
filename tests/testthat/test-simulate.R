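test_that("mse, mae and spearman_r behave as defined", {
  t1 <- matrix(c(0, 1, 0.5, 0.5), 2,
               dimnames = list(c("A", "B"), c("s1", "s2")))
  expect_equal(mse(t1, t1), 0)
  expect_equal(mae(t1, t1), 0)
  expect_equal(spearman_r(t1, t1), 1)

  e1 <- matrix(c(1, 0, 0.5, 0.5), 2, dimnames = dimnames(t1))
  # errors are (1, 1, 0, 0): MSE = MAE = 0.5
  expect_equal(mse(t1, e1), 0.5)
  expect_equal(mae(t1, e1), 0.5)

  # proportions live in [0,1], so squared errors never exceed absolute ones
  set.seed(6)
  a <- random_simplex(4, 10); b <- random_simplex(4, 10)
  expect_lte(mse(a, b), mae(a, b))

  # rank invariance under strictly increasing transforms; reversal gives -1
  tr <- matrix(seq(0.1, 0.8, length.out = 8) / sum(seq(0.1, 0.8, length.out = 8)), 4)
  expect_equal(spearman_r(tr, sqrt(tr)), 1)
  expect_equal(spearman_r(tr, max(tr) - tr + 0.01), -1)
  expect_error(spearman_r(tr, tr * 0 + 0.25), "undefined")

  # metrics align by label and are invariant to column permutation
  perm <- e1[, c(2, 1)]
  expect_equal(mse(t1, perm), mse(t1, e1))
  bad <- e1
  rownames(bad) <- c("A", "X")
  expect_error(mse(t1, bad), "labels")
})

test_that("random_simplex is uniform on the simplex and reproducible", {
  p <- random_simplex(5, seed = 2)
  expect_equal(sum(p), 1)
  expect_true(all(p >= 0))
  expect_identical(random_simplex(5, seed = 2), p)

  # Dirichlet(1) mean is 1/C per coordinate
  draws <- random_simplex(5, n = 1e4, seed = 3)
  expect_lt(max(abs(rowMeans(draws) - 1 / 5)), 0.01)
})

test_that("the single-cell generator is reproducible and honors its switches", {
  cfg <- simulation_config(n_genes = 200, n_cells = 150, n_types = 3,
                           n_subjects = 4, seed = 10)
  a <- simulate_single_cell(cfg)
  b <- simulate_single_cell(cfg)
  expect_identical(a$sc$expr$values, b$sc$expr$values)
  expect_identical(a$true_proportions, b$true_proportions)
  expect_equal(unname(colSums(a$true_proportions)), rep(1, 4))
  expect_equal(nlevels(a$sc$cell_type), 3)

  # with de_prob = 0 the type labels carry no expression signal, so the
  # marker rule finds nothing to separate the types
  cfg0 <- simulation_config(n_genes = 300, n_cells = 200, n_types = 3,
                            n_subjects = 3, de_prob = 0, seed = 12)
  sim0 <- simulate_single_cell(cfg0)
  expect_error(select_markers(detection_fractions(sim0$sc)), "no marker genes")
})

test_that("differential-expression factors yield markers for every type in most runs", {
  # at the benchmark's DE strength, marker selection should cover all types
  # in at least 95% of seeded runs of a reduced-size generator
  ok <- 0L
  n_runs <- 40L
  for (s in seq_len(n_runs)) {
    cfg <- simulation_config(n_genes = 1000, n_cells = 500, n_types = 5,
                             n_subjects = 8, seed = s)
    sim <- simulate_single_cell(cfg)
    got <- tryCatch({
      select_markers(detection_fractions(sim$sc), threshold = 0.5)
      TRUE
    }, error = function(e) FALSE)
    ok <- ok + got
  }
  expect_gte(ok / n_runs, 0.95)
})

test_that("simulate_bulk mixes type profiles and is exact when noiseless", {
  sim <- small_world(seed = 18, n_genes = 300, n_cells = 300)
  bk <- simulate_bulk(sim$sc, n_bulk = 8, noise_cv = 0, seed = 19)
  expect_equal(unname(colSums(bk$true_proportions)), rep(1, 8))

  # a pure sample is proportional to that type's mean CPM profile
  cp <- suppressWarnings(cpm_normalize(sim$sc$expr))
  prof1 <- rowMeans(cp$values[, sim$sc$cell_type == levels(sim$sc$cell_type)[1]])
  pure <- prof1 * 30          # depth 3e7 / 1e6
  i_max <- which.max(bk$true_proportions[1, ])
  # rebuild the same sample mixture to bound rounding error only
  mix <- vapply(levels(sim$sc$cell_type), function(tp)
    rowMeans(cp$values[, sim$sc$cell_type == tp, drop = FALSE]),
    numeric(nrow(cp$values))) %*% bk$true_proportions[, i_max] * 30
  expect_lt(max(abs(bk$bulk$expr$values[, i_max] - mix)), 0.5 + 1e-9)
  expect_equal(cor(pure, bk$bulk$expr$values[, i_max]) > 0.5, TRUE)

  # noiseless mixtures are recovered nearly exactly without a transform
  fit <- decompose(sim$sc, bk$bulk, mode = "none")
  expect_lt(mae(bk$true_proportions, fit$proportions), 0.02)
})

test_that("per-subject pseudo-bulk aggregation matches the annotation bookkeeping", {
  sim <- small_world(seed = 22, n_genes = 150, n_cells = 120)
  bk <- aggregate_subject_pseudobulk(sim$sc)
  expect_equal(ncol(bk$bulk$expr$values), nlevels(sim$sc$subject))
  expect_equal(unname(colSums(bk$true_proportions)),
               rep(1, nlevels(sim$sc$subject)))
  s1 <- levels(sim$sc$subject)[1]
  expect_equal(bk$bulk$expr$values[, s1],
               rowSums(sim$sc$expr$values[, sim$sc$subject == s1]))
})

test_that("benchmark aggregates per-iteration metrics coherently", {
  cfg <- simulation_config(n_genes = 600, n_cells = 300, n_types = 4,
                           n_subjects = 6, seed = 30)
  b <- benchmark(cfg, n_iter = 3, modes = c("none", "multivariate"))
  expect_equal(b$n_failed, 0L)
  expect_setequal(b$summary$mode, c("none", "multivariate"))
  # averages lie between the per-iteration extremes
  for (md in b$summary$mode) {
    d <- b$per_iteration[b$per_iteration$mode == md, ]
    expect_gte(b$summary$MAE[b$summary$mode == md], min(d$MAE))
    expect_lte(b$summary$MAE[b$summary$mode == md], max(d$MAE))
  }
  # noiseless subject pseudo-bulk is decomposed accurately even untransformed
  expect_lt(b$summary$MSE[b$summary$mode == "none"], 1e-2)

  # reruns with the same config are identical
  b2 <- benchmark(cfg, n_iter = 3, modes = c("none", "multivariate"))
  expect_identical(b$summary, b2$summary)
})
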