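test_that("moments uses the divisor-n covariance convention", {
  m <- matrix(c(0, 5, 2, 7), 2, dimnames = list(c("g1", "g2"), c("a", "b")))
  mo <- moments(m)
  expect_equal(unname(mo$mean), c(1, 6))
  # variance with divisor n: ((0-1)^2 + (2-1)^2) / 2 = 1
  expect_equal(unname(diag(mo$cov)), c(1, 1))
  expect_equal(mo$n, 2)

  # identical columns give the zero matrix; column order is irrelevant
  same <- matrix(3, 4, 5, dimnames = list(paste0("g", 1:4), paste0("c", 1:5)))
  expect_equal(max(abs(moments(same)$cov)), 0)
  set.seed(1)
  x <- matrix(rnorm(40), 5)
  expect_equal(moments(x)$cov, moments(x[, sample(8)])$cov)
  expect_error(moments(x[, 1, drop = FALSE]), "at least 2")
})

test_that("lw_shrink reproduces the reference plug-in estimator", {
  # frozen oracle: this exact fixture was evaluated with an independent
  # implementation of the same estimator (sklearn.covariance.ledoit_wolf),
  # which returned intensity 0.11033677457852 and the leading row below
  set.seed(7)
  G <- 5; n <- 40
  A <- matrix(rnorm(G * G), G)
  Sig <- crossprod(A) + diag(G)
  x <- t(chol(Sig)) %*% matrix(rnorm(G * n), G, n) + 3
  s <- lw_shrink(x)
  expect_equal(s$intensity, 0.11033677457852, tolerance = 1e-10)
  expect_equal(as.matrix(s)[1, 1:3],
               c(10.258608299, -5.700981131, -6.118911617), tolerance = 1e-8)

  # shrunk matrix satisfies its defining convex combination
  mo <- moments(x)
  expect_equal(as.matrix(s),
               (1 - s$intensity) * mo$cov +
                 s$intensity * s$target_scale * diag(G),
               tolerance = 1e-10)

  # data whose sample covariance is already nu * I is returned unchanged
  iso <- matrix(c(1, 1, 1, -1, -1, 1, -1, -1), 2)  # centered cov = I (divisor 4)
  rownames(iso) <- c("g1", "g2")
  si <- lw_shrink(iso)
  expect_equal(as.matrix(si), diag(2), ignore_attr = TRUE, tolerance = 1e-12)

  expect_error(lw_shrink(matrix(1, 3, 4)), "all-zero covariance")
})

test_that("shrinkage makes singular sample covariances positive-definite", {
  set.seed(13)
  x <- matrix(rnorm(50 * 10), 50, 10)   # G = 50 >> n = 10: S is singular
  s <- lw_shrink(x)
  expect_gt(s$intensity, 0)
  expect_lte(s$intensity, 1)
  ev <- eigen(as.matrix(s), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # conditioning never degrades relative to the sample covariance
  sev <- eigen(moments(x)$cov, symmetric = TRUE, only.values = TRUE)$values
  expect_lt(max(ev) / min(ev), max(sev) / max(min(sev), 1e-300))
})

test_that("lw_shrink is consistent: large n recovers the true covariance", {
  set.seed(101)
  Sig <- matrix(c(2, 0.8, 0.8, 1), 2)
  x <- t(chol(Sig)) %*% matrix(rnorm(2 * 1e5), 2)
  s <- lw_shrink(x)
  expect_lt(sqrt(sum((as.matrix(s) - Sig)^2)), 0.05)
  expect_lt(s$intensity, 0.05)
})

test_that("symmetric roots satisfy their defining identities", {
  d <- diag(c(4, 9))
  expect_equal(sym_root(d), diag(c(2, 3)))
  expect_equal(sym_inv_root(d), diag(c(1 / 2, 1 / 3)))

  set.seed(8)
  A <- matrix(rnorm(16), 4)
  c <- crossprod(A) + diag(4)
  r <- sym_root(c)
  expect_equal(r %*% r, c, tolerance = 1e-8)
  ir <- sym_inv_root(c)
  expect_equal(ir %*% c %*% ir, diag(4), tolerance = 1e-8)
  expect_equal(ir %*% r, diag(4), tolerance = 1e-8)
  expect_error(sym_root(matrix(1:4, 2)), "not symmetric")
})

test_that("factored root application equals the dense eigendecomposition route", {
  set.seed(19)
  x <- matrix(rnorm(8 * 12, sd = 2), 8, 12)
  s <- lw_shrink(x)
  M <- matrix(rnorm(8 * 3), 8, 3)
  dense <- as.matrix(s)
  expect_equal(cscdecon:::.shrunk_cov_pow_mult(s, 0.5, M),
               sym_root(dense, floor = 1e-12) %*% M, tolerance = 1e-9)
  expect_equal(cscdecon:::.shrunk_cov_pow_mult(s, -0.5, M),
               sym_inv_root(dense, floor = 1e-12) %*% M, tolerance = 1e-9)
})

test_that("univariate transform matches the printed location-scale formula", {
  # hand case: Ybar = 10, sY = 4, Xbar = 5, sX = 1, J = 3, X = 6
  # -> 10 + sqrt(3/4) * sqrt(4/1) * 1 = 11.7320508
  Y <- matrix(10 + c(-2, 0, 2) * sqrt(3 / 2), 1)  # mean 10, var 4 (divisor n)
  expect_equal(cscdecon:::.row_vars(Y)[1], 4)
  X <- matrix(5 + c(1, -1, 1, -1), 1)                        # mean 5, var 1
  rownames(Y) <- rownames(X) <- "g"
  out <- univariate_transform(X, Y)
  expect_equal(unname(out[1, 1]), 10 + sqrt(3 / 4) * 2, tolerance = 1e-7)

  # a bulk value at the bulk mean maps to the pseudo-bulk mean
  X2 <- matrix(c(5, 4, 6), 1, dimnames = list("g", NULL))
  expect_equal(unname(univariate_transform(X2, Y)[1, 1]), 10)

  # the transformed gene's variance is (J/(J+1)) * sY
  set.seed(3)
  Xr <- matrix(rnorm(20, 50, 3), 1, dimnames = list("g", NULL))
  Yr <- matrix(rnorm(6, 80, 5), 1, dimnames = list("g", NULL))
  tr <- univariate_transform(Xr, Yr)
  expect_equal(cscdecon:::.row_vars(tr)[[1]],
               (6 / 7) * cscdecon:::.row_vars(Yr)[[1]], tolerance = 1e-9)

  # zero bulk variance is refused with the gene named
  Xc <- matrix(5, 1, 4, dimnames = list("g", NULL))
  expect_error(univariate_transform(Xc, Y), "zero bulk variance.*g")
})

test_that("multivariate transform has the exact algebraic fixed points", {
  set.seed(23)
  G <- 6; J <- 5; I <- 7
  Y <- matrix(rlnorm(G * J, 3, 0.5), G, dimnames = list(paste0("g", 1:G), NULL))

  # constant-column bulk maps every column to the pseudo-bulk mean exactly
  Xc <- matrix(rep(rlnorm(G, 3, 0.5), I), G, dimnames = list(paste0("g", 1:G), NULL))
  out <- multivariate_transform(Xc, Y)
  expect_equal(out, matrix(rowMeans(Y), G, I, dimnames = dimnames(Xc)))

  # when X is Y itself the shrunk covariances coincide, the roots cancel,
  # and the map is pure centering plus the J/(J+1) contraction
  out2 <- multivariate_transform(Y, Y)
  expect_equal(out2, rowMeans(Y) + sqrt(J / (J + 1)) * (Y - rowMeans(Y)),
               tolerance = 1e-7)

  # sample mean of the output is exactly the pseudo-bulk mean
  X <- matrix(rlnorm(G * I, 3, 0.6), G, dimnames = list(paste0("g", 1:G), NULL))
  out3 <- multivariate_transform(X, Y)
  expect_equal(rowMeans(out3), rowMeans(Y), tolerance = 1e-9)
  expect_equal(ncol(out3), I)
})

test_that("in one dimension the multivariate transform reduces to the univariate one", {
  set.seed(31)
  Y <- matrix(rnorm(8, 100, 10), 1, dimnames = list("g", NULL))
  X <- matrix(rnorm(12, 60, 4), 1, dimnames = list("g", NULL))
  # in 1-D the shrinkage target nu equals the variance itself, so the shrunk
  # variance is the raw variance and the two transforms coincide
  expect_equal(multivariate_transform(X, Y), univariate_transform(X, Y),
               tolerance = 1e-9)
})

test_that("with intensity 0 the transform recolors to (J/(J+1)) * S_Y", {
  set.seed(37)
  G <- 3; J <- 40; I <- 60
  A <- matrix(rnorm(G * G), G); Sy <- crossprod(A) + diag(G)
  B <- matrix(rnorm(G * G), G); Sx <- crossprod(B) + diag(G)
  Y <- t(chol(Sy)) %*% matrix(rnorm(G * J), G) + 50
  X <- t(chol(Sx)) %*% matrix(rnorm(G * I), G) + 20
  rownames(Y) <- rownames(X) <- paste0("g", 1:G)
  out <- multivariate_transform(X, Y, intensity = 0)
  expect_equal(moments(out)$cov, (J / (J + 1)) * moments(Y)$cov,
               tolerance = 1e-6)
})
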