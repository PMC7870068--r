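test_that("identity resamples reproduce the full-data AVE", {
  set.seed(70)
  bs <- random_blockset(n = 30, p = c(4, 5))
  C <- design_matrix(matrix(c(0, 1, 1, 0), 2), names(bs$blocks))
  full <- fit_rgcca(bs, C, tau = 1)
  idn <- lapply(1:2, function(i) 1:30)
  bt <- bootstrap_model(bs, C, tau = 1, B = 2, seed = 1, indices = idn)
  expect_equal(bt$replicates$ave_inner,
               rep(full$ave$summary$ave_inner[1], 2), tolerance = 1e-10)
  expect_equal(bt$replicates$ave_outer,
               rep(full$ave$summary$ave_outer[1], 2), tolerance = 1e-10)
  expect_equal(bt$summary$sd, c(0, 0), tolerance = 1e-12)
})

test_that("bootstrap runs are deterministic given the master seed", {
  set.seed(71)
  bs <- random_blockset(n = 25, p = c(3, 3))
  C <- design_matrix(matrix(c(0, 1, 1, 0), 2), names(bs$blocks))
  b1 <- bootstrap_model(bs, C, tau = 1, B = 10, seed = 99)
  b2 <- bootstrap_model(bs, C, tau = 1, B = 10, seed = 99)
  expect_identical(b1$replicates, b2$replicates)
  expect_identical(b1$summary, b2$summary)
})

test_that("growing B extends the replicate stream without perturbing it", {
  set.seed(72)
  bs <- random_blockset(n = 25, p = c(3, 3))
  C <- design_matrix(matrix(c(0, 1, 1, 0), 2), names(bs$blocks))
  b5 <- bootstrap_model(bs, C, tau = 1, B = 5, seed = 7)
  b10 <- bootstrap_model(bs, C, tau = 1, B = 10, seed = 7)
  expect_identical(b10$replicates[1:5, ], b5$replicates)
})

test_that("one common index vector is applied to every block", {
  # identical blocks stay identical under joint resampling, so the inner AVE
  # of every replicate is exactly 1; independent resampling would break this
  set.seed(73)
  x <- scale2(matrix(rnorm(25 * 4), 25, 4))
  bs <- assemble_blockset(list(a = x, b = x))
  C <- design_matrix(matrix(c(0, 1, 1, 0), 2), c("a", "b"))
  bt <- bootstrap_model(bs, C, tau = 1, B = 20, seed = 3)
  expect_equal(bt$replicates$ave_inner, rep(1, nrow(bt$replicates)),
               tolerance = 1e-8)
})

test_that("replicates with degenerate blocks are dropped and counted", {
  set.seed(74)
  # a dummy column with a single positive sample collapses whenever the
  # resample misses that sample
  g <- c("b", rep("a", 19))
  d <- encode_categorical(g, name = "g")
  x <- matrix(rnorm(20 * 4), 20, 4)
  bs <- assemble_blockset(list(omic = scale2(x), g = scale2(d)))
  C <- design_matrix(matrix(c(0, 1, 1, 0), 2), c("omic", "g"))
  good <- 1:20
  bad <- c(2:20, 2)                       # sample 1 never drawn
  bt <- bootstrap_model(bs, C, tau = 1, B = 4, seed = 5,
                        indices = list(good, bad, good, bad))
  expect_equal(bt$n_failed, 2L)
  expect_equal(nrow(bt$replicates), 2)
  expect_error(bootstrap_model(bs, C, tau = 1, B = 2, seed = 5,
                               indices = list(bad, bad)),
               "more than half")
})

test_that("summary statistics do not depend on replicate order", {
  set.seed(75)
  bs <- random_blockset(n = 30, p = c(3, 4))
  C <- design_matrix(matrix(c(0, 1, 1, 0), 2), names(bs$blocks))
  bt <- bootstrap_model(bs, C, tau = 1, B = 16, seed = 2)
  perm <- sample(nrow(bt$replicates))
  expect_equal(mean(bt$replicates$ave_inner[perm]),
               bt$summary$mean[bt$summary$metric == "inner"], tolerance = 1e-12)
  expect_equal(sd(bt$replicates$ave_inner[perm]),
               bt$summary$sd[bt$summary$metric == "inner"], tolerance = 1e-12)
})

test_that("dispersion summaries sort by mean inner AVE with sd tie-break", {
  fake_boot <- function(id, inner, outer) {
    structure(list(
      replicates = tibble::tibble(replicate = seq_along(inner),
                                  ave_inner = inner, ave_outer = outer,
                                  converged = TRUE),
      summary = tibble::tibble(model_id = id, metric = c("inner", "outer"),
                               mean = c(mean(inner), mean(outer)),
                               sd = c(sd(inner), sd(outer)),
                               n = length(inner)),
      B = length(inner), n_failed = 0L, seed = 1, model_id = id,
      design = NULL, scheme = "centroid"), class = "cca_boot")
  }
  # ordering ground truth: means 0.785 vs 0.550 rank the stronger model first
  a <- fake_boot("weak", c(0.50, 0.60), c(0.10, 0.11))
  b <- fake_boot("strong", c(0.78, 0.79), c(0.10, 0.11))
  tab <- summarize_dispersion(list(a, b))
  expect_equal(tab$model_id, c("strong", "weak"))
  expect_true(tab$dominant[1])

  # equal means: lower sd wins
  c1 <- fake_boot("tight", c(0.6, 0.6001), c(0.1, 0.1))
  c2 <- fake_boot("loose", c(0.5, 0.7001), c(0.1, 0.1))
  tab2 <- summarize_dispersion(list(c2, c1))
  expect_equal(tab2$model_id[1], "tight")

  single <- summarize_dispersion(list(a))
  expect_equal(nrow(single), 1)
  expect_false(single$dominant[1])
})

test_that("bootstrapped inner AVE tightens as the sample size grows", {
  sds <- sapply(c(50, 200), function(n) {
    set.seed(76)
    sim <- generate_blockset(n = n, p = c(10, 10),
                             design = matrix(c(0, 1, 1, 0), 2),
                             noise_sd = 0.5, seed = 76)
    bs <- assemble_blockset(lapply(sim$tables, scale2))
    C <- design_matrix(matrix(c(0, 1, 1, 0), 2), names(bs$blocks))
    bt <- bootstrap_model(bs, C, tau = 1, B = 40, seed = 76)
    bt$summary$sd[bt$summary$metric == "inner"]
  })
  expect_lt(sds[2], sds[1])
})
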