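test_that("the generator is bitwise deterministic under a fixed seed", {
  a <- generate_blockset(n = 30, p = c(5, 6), seed = 42,
                         covariates = list(g = list(levels = 2, effect = 1)))
  b <- generate_blockset(n = 30, p = c(5, 6), seed = 42,
                         covariates = list(g = list(levels = 2, effect = 1)))
  expect_identical(a$tables, b$tables)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$truth$factors, b$truth$factors)
})

test_that("a full-strength edge with no noise gives perfectly shared factors", {
  sim <- generate_blockset(n = 50, p = c(4, 4),
                           design = matrix(c(0, 1, 1, 0), 2),
                           cor_scale = 1, noise_sd = 0, seed = 1)
  f <- sim$truth$factors[[1]]
  expect_equal(abs(cor(f[, 1], f[, 2])), 1, tolerance = 1e-8)
})

test_that("realized factor correlations track the design targets", {
  sim <- generate_blockset(n = 2000, p = c(5, 5),
                           design = matrix(c(0, 0.75, 0.75, 0), 2),
                           cor_scale = 0.8, seed = 2)
  f <- sim$truth$factors[[1]]
  expect_lt(abs(cor(f[, 1], f[, 2]) - 0.6), 0.05)
})

test_that("infeasible correlation targets are rejected with named entries", {
  # blocks 2 and 3 each perfectly tied to block 1 but unrelated to each
  # other: no correlation matrix can realize that
  V <- rbind(c(0, 1, 1), c(1, 0, 0), c(1, 0, 0))
  expect_error(generate_blockset(n = 20, p = c(3, 3, 3), design = V,
                                 cor_scale = 1, seed = 1),
               "non-positive-definite.*\\(1,2\\)")
  # the planted correlation matrix is PSD whenever generation succeeds
  sim <- generate_blockset(n = 20, p = c(3, 3, 3), design = V,
                           cor_scale = 0.6, seed = 1)
  ev <- eigen(sim$truth$cor_target, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > 0))
})

test_that("covariates shift factors and emit the right dummy widths", {
  sim <- generate_blockset(n = 400, p = c(5, 5), seed = 3,
                           covariates = list(g = list(levels = 2, effect = 2)))
  expect_equal(sort(unique(sim$metadata$g)), c("l1", "l2"))
  f <- sim$truth$factors[[1]][, 1]
  sep <- mean(f[sim$metadata$g == "l2"]) - mean(f[sim$metadata$g == "l1"])
  expect_lt(abs(sep - 2), 0.35)
  d <- encode_categorical(sim$metadata$g, name = "g")
  expect_equal(ncol(d), 1)
  bs <- as_scaled_blockset(sim)
  expect_equal(names(bs$blocks), c("block1", "block2", "g"))
  expect_equal(unname(bs$kind["g"]), "categorical-dummy")
})

test_that("loading supports are sparse with unit norm", {
  sim <- generate_blockset(n = 30, p = c(40, 40), loading_sparsity = 0.2,
                           seed = 4)
  for (W in sim$truth$loadings) {
    expect_equal(sum(W[, 1] != 0), 8)
    expect_equal(sum(W[, 1]^2), 1, tolerance = 1e-12)
  }
})

test_that("sparse fits recover the planted loading support", {
  jaccard <- function(a, b) length(intersect(a, b)) / length(union(a, b))
  hits <- sapply(1:20, function(s) {
    sim <- generate_blockset(n = 200, p = c(50, 50),
                             design = matrix(c(0, 1, 1, 0), 2),
                             loading_sparsity = 0.3, noise_sd = 0.5,
                             seed = 1000 + s)
    bs <- assemble_blockset(lapply(sim$tables, scale2))
    fit <- fit_sgcca(bs, sparsity = sqrt(15) / sqrt(50))  # matching support size
    mean(sapply(1:2, function(j) {
      jaccard(which(fit$loadings[[j]][, 1] != 0),
              which(sim$truth$loadings[[j]][, 1] != 0))
    }))
  })
  expect_gte(sum(hits >= 0.6), 18)
})

test_that("heavy-tail transform yields nonnegative skewed counts", {
  sim <- generate_blockset(n = 30, p = c(5, 5), heavy_tail = TRUE, seed = 5)
  counts <- sim$tables_counts$block1
  expect_true(all(counts >= 0))
  expect_true(all(counts == round(counts)))
})

test_that("the confounded scenario behaves as a null when the effect is zero", {
  set.seed(84)
  diffs <- sapply(1:20, function(s) {
    sc <- make_confounded_scenario(n = 120, p = c(15, 15), effect = 0,
                                   seed = 2000 + s)
    f0 <- fit_rgcca(sc$blocks0, sc$design0, tau = 1)
    fc <- fit_rgcca(sc$blocks_cov, sc$design_cov, tau = 1)
    fc$ave$summary$ave_inner[1] - f0$ave$summary$ave_inner[1]
  })
  ci <- mean(diffs) + c(-1, 1) * qt(0.975, 19) * sd(diffs) / sqrt(20)
  # with no covariate effect the covariate model gains nothing: the paired
  # difference must not be significantly positive (the extra edges dilute
  # the weighted mean, so a mildly negative gap is expected)
  expect_lt(ci[1], 0)
})

test_that("a strong shared covariate lifts the covariate model's inner AVE", {
  wins <- sapply(1:20, function(s) {
    sc <- make_confounded_scenario(n = 120, p = c(15, 15), effect = 2,
                                   seed = 3000 + s)
    f0 <- fit_rgcca(sc$blocks0, sc$design0, tau = 1)
    fc <- fit_rgcca(sc$blocks_cov, sc$design_cov, tau = 1)
    fc$ave$summary$ave_inner[1] > f0$ave$summary$ave_inner[1]
  })
  expect_gte(sum(wins), 18)
})
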