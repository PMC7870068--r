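test_that("scheme_g applies identity, absolute value and square", {
  expect_equal(scheme_g(-0.3, "centroid"), 0.3)
  expect_equal(scheme_g(-0.3, "factorial"), 0.09)
  expect_equal(scheme_g(0.3, "horst"), 0.3)
})

test_that("two identical blocks reach perfect component correlation", {
  set.seed(20)
  x <- scale2(matrix(rnorm(40 * 5), 40, 5))
  bs <- assemble_blockset(list(a = x, b = x))
  for (scheme in c("horst", "centroid", "factorial")) {
    fit <- fit_rgcca(bs, tau = 1, scheme = scheme)
    expect_equal(abs(cor(fit$components$a[, 1], fit$components$b[, 1])), 1,
                 tolerance = 1e-8)
  }
})

test_that("tau = 0 two-block fit recovers the classical first canonical correlation", {
  set.seed(21)
  n <- 50
  x <- matrix(rnorm(n * 3), n, 3)
  y <- x %*% matrix(rnorm(9), 3, 3) + matrix(rnorm(n * 3, sd = 0.8), n, 3)
  bs <- assemble_blockset(list(a = scale2(x), b = scale2(y)))
  fit <- fit_rgcca(bs, tau = c(0, 0), scheme = "factorial",
                   tol = 1e-14, max_iter = 5000)
  got <- abs(cor(fit$components$a[, 1], fit$components$b[, 1]))

  # generalized-eigenproblem oracle on population covariances
  Xa <- bs$blocks$a
  Xb <- bs$blocks$b
  Saa <- crossprod(Xa) / n
  Sbb <- crossprod(Xb) / n
  Sab <- crossprod(Xa, Xb) / n
  M <- solve(Saa, Sab) %*% solve(Sbb, t(Sab))
  rho <- sqrt(max(Re(eigen(M)$values)))
  expect_equal(got, rho, tolerance = 1e-6)
})

test_that("tau = 1 horst fit equals the leading cross-covariance singular pair", {
  set.seed(22)
  n <- 40
  x <- matrix(rnorm(n * 4), n, 4)
  y <- x[, 1:2] %*% matrix(rnorm(6), 2, 3) + matrix(rnorm(n * 3, sd = 0.5), n, 3)
  bs <- assemble_blockset(list(a = scale2(x), b = scale2(y)))
  fit <- fit_rgcca(bs, tau = 1, scheme = "horst", tol = 1e-14, max_iter = 5000)
  s <- svd(crossprod(bs$blocks$a, bs$blocks$b))
  u <- s$u[, 1] * sign(s$u[which.max(abs(s$u[, 1])), 1])
  v <- s$v[, 1] * sign(s$v[which.max(abs(s$v[, 1])), 1])
  expect_equal(unname(fit$loadings$a[, 1]), u, tolerance = 1e-6)
  expect_equal(unname(fit$loadings$b[, 1]), v, tolerance = 1e-6)
})

test_that("objective trace is non-decreasing across schemes, taus and designs", {
  set.seed(23)
  for (i in 1:40) {
    J <- sample(2:3, 1)
    bs <- random_blockset(n = 15, p = sample(2:4, J, replace = TRUE))
    C <- random_connected_design(J, diagonal = runif(1) < 0.3)
    scheme <- sample(c("horst", "centroid", "factorial"), 1)
    tau <- sample(c(0, 0.5, 1), J, replace = TRUE)
    fit <- fit_rgcca(bs, C, scheme = scheme, tau = tau, ncomp = 2)
    for (tr in fit$objective_trace) {
      expect_true(all(diff(tr) >= -1e-10))
    }
  }
})

test_that("loading norms satisfy the regularized constraint a' M a = 1", {
  set.seed(24)
  bs <- random_blockset(n = 30, p = c(4, 5))
  for (tau in list(c(0, 0), c(0.4, 0.7), c(1, 1))) {
    fit <- fit_rgcca(bs, tau = tau)
    for (j in 1:2) {
      X <- bs$blocks[[j]]
      a <- fit$loadings[[j]][, 1]
      M <- tau[j] * diag(ncol(X)) + (1 - tau[j]) * crossprod(X) / nrow(X)
      expect_equal(drop(t(a) %*% M %*% a), 1, tolerance = 1e-8)
    }
  }
})

test_that("horst and centroid coincide when component covariances stay positive", {
  set.seed(25)
  # strong shared signal keeps all covariances positive through the iterations
  bs <- random_blockset(n = 40, p = c(4, 4, 4), signal = TRUE)
  C <- matrix(1, 3, 3) - diag(3)
  fh <- fit_rgcca(bs, C, scheme = "horst", tau = 1, tol = 1e-14, max_iter = 5000)
  fc <- fit_rgcca(bs, C, scheme = "centroid", tau = 1, tol = 1e-14, max_iter = 5000)
  covs <- combn(3, 2, function(jk) {
    cov_pop(fh$components[[jk[1]]][, 1], fh$components[[jk[2]]][, 1])
  })
  expect_true(all(covs > 0))
  for (j in 1:3) {
    expect_equal(fh$loadings[[j]][, 1], fc$loadings[[j]][, 1], tolerance = 1e-6)
  }
})

test_that("reported loadings follow the positive-max sign convention", {
  set.seed(26)
  bs <- random_blockset(n = 25, p = c(3, 3))
  fit <- fit_rgcca(bs, tau = 1)
  for (j in 1:2) {
    a <- fit$loadings[[j]][, 1]
    expect_gt(a[which.max(abs(a))], 0)
  }
})

test_that("a common row permutation leaves objective and AVEs unchanged", {
  set.seed(27)
  bs <- random_blockset(n = 30, p = c(3, 4, 2))
  C <- random_connected_design(3)
  fit <- fit_rgcca(bs, C, tau = 0.5)
  perm <- sample(30)
  bs2 <- bs
  bs2$blocks <- lapply(bs$blocks, function(b) b[perm, , drop = FALSE])
  fit2 <- fit_rgcca(bs2, C, tau = 0.5)
  expect_equal(fit2$objective, fit$objective, tolerance = 1e-10)
  expect_equal(fit2$ave$summary$ave_inner, fit$ave$summary$ave_inner,
               tolerance = 1e-10)
  expect_equal(fit2$ave$summary$ave_outer, fit$ave$summary$ave_outer,
               tolerance = 1e-10)
})

test_that("deflation removes a component's contribution exactly", {
  set.seed(28)
  x <- matrix(rnorm(100), 20, 5)
  y <- x %*% rnorm(5)
  res <- deflate(x, y)
  expect_lt(max(abs(crossprod(y, res))), 1e-8)
  # independent projection-matrix oracle
  P <- diag(20) - tcrossprod(y) / sum(y^2)
  expect_equal(res, P %*% x, tolerance = 1e-10)
  # rank-1 block deflated by its only direction vanishes
  r1 <- tcrossprod(rnorm(20), rnorm(4))
  expect_lt(max(abs(deflate(r1, r1 %*% rnorm(4)))), 1e-10)
  expect_error(deflate(x, rep(0, 20)), "zero-norm")
})

test_that("multi-component fits deflate each block against its own components", {
  set.seed(29)
  bs <- random_blockset(n = 30, p = c(5, 6))
  fit <- fit_rgcca(bs, tau = 1, ncomp = 2)
  for (j in 1:2) {
    y <- fit$components[[j]]
    # second component orthogonal to the first within each block
    expect_lt(abs(cov_pop(y[, 1], y[, 2])), 1e-6)
  }
})

test_that("disconnected designs and bad inputs are rejected", {
  set.seed(30)
  bs <- random_blockset(n = 20, p = c(2, 2, 2))
  C <- matrix(0, 3, 3)
  C[1, 2] <- C[2, 1] <- 1
  expect_error(fit_rgcca(bs, C, tau = 1), "not a single connected network")
  expect_error(fit_rgcca(bs, tau = 2), "\\[0, 1\\]")
})
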