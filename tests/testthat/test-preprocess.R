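test_that("scale2 centers, scales by sample sd and divides by sqrt(p)", {
  x <- matrix(c(0, 1, 2, 3), nrow = 2)
  expect_equal(unname(scale2(x)),
               matrix(c(-0.5, 0.5, -0.5, 0.5), nrow = 2))

  # single z-scored feature is unchanged (division by sqrt(1))
  set.seed(4)
  z <- matrix(as.vector(scale(rnorm(15))), ncol = 1)
  expect_equal(unname(scale2(z)), unname(z), tolerance = 1e-12)

  set.seed(5)
  m <- matrix(rnorm(60), 10, 6)
  s <- scale2(m)
  expect_lt(max(abs(colMeans(s))), 1e-10)
  expect_equal(unname(apply(s, 2, sd)), rep(1 / sqrt(6), 6), tolerance = 1e-10)
  # column variance times p is 1
  expect_equal(unname(apply(s, 2, var)) * 6, rep(1, 6), tolerance = 1e-8)
})

test_that("scale2 is scale invariant and idempotent up to the sqrt(p) factor", {
  set.seed(6)
  m <- matrix(rnorm(50), 10, 5)
  expect_equal(scale2(m * 37.2), scale2(m), tolerance = 1e-12)
  once <- scale2(m)
  expect_equal(scale2(once), once, tolerance = 1e-12)
})

test_that("scale2 rejects constant columns unless dropping is requested", {
  m <- cbind(a = rnorm(10), b = rep(2, 10))
  expect_error(scale2(m), "constant feature.*b")
  expect_warning(s <- scale2(m, drop_constant = TRUE), "dropping 1")
  expect_equal(colnames(s), "a")
  expect_error(scale2(matrix(1, 1, 2)), "at least 2 samples")
})

test_that("encode_categorical drops the first sorted level and keeps row sums in {0,1}", {
  e <- encode_categorical(c("colon", "ileum", "colon"), name = "loc")
  expect_equal(unname(e[, 1]), c(0, 1, 0))
  expect_equal(colnames(e), "loc.ileum")
  expect_identical(attr(e, "block_kind"), "categorical-dummy")

  e3 <- encode_categorical(c("a", "b", "c"), name = "v")
  expect_equal(unname(e3), matrix(c(0, 1, 0, 0, 0, 1), nrow = 3),
               ignore_attr = TRUE)

  set.seed(7)
  x <- sample(letters[1:4], 10, replace = TRUE)
  while (length(unique(x)) < 4) x <- sample(letters[1:4], 10, replace = TRUE)
  e4 <- encode_categorical(x, name = "v")
  expect_equal(ncol(e4), 3)
  expect_true(all(rowSums(e4) %in% c(0, 1)))

  # explicit reference level
  er <- encode_categorical(c("colon", "ileum"), levels_order = c("ileum", "colon"),
                           name = "loc")
  expect_equal(colnames(er), "loc.colon")

  expect_error(encode_categorical(c("x", "x")), "single observed level")
  expect_error(encode_categorical(c("x", NA, "y")), "missing values")
})

test_that("dummy encoding then scale2 yields centered contrast columns", {
  e <- encode_categorical(c("a", "b", "a", "b", "b"), name = "v")
  s <- scale2(e)
  expect_lt(max(abs(colMeans(s))), 1e-10)
})

test_that("cv_filter removes the top-CV features deterministically", {
  set.seed(8)
  m <- matrix(rnorm(200, mean = 5), 20, 10)
  colnames(m) <- sprintf("f%02d", 1:10)
  expect_identical(cv_filter(m, 0), m)

  cv <- apply(m, 2, sd) / abs(colMeans(m))   # independent ranking
  worst <- names(which.max(cv))
  out <- cv_filter(m, 0.1)
  expect_equal(ncol(out), 9)
  expect_false(worst %in% colnames(out))
  expect_identical(colnames(out), setdiff(colnames(m), worst))

  # tie at the cutoff: equal CVs resolved by feature name, ascending
  base <- rnorm(20)
  tied <- cbind(z1 = base + 5, z2 = base + 5, low = rnorm(20, 50, 0.01))
  out2 <- cv_filter(tied, 1 / 3)
  expect_identical(colnames(out2), c("z2", "low"))

  expect_error(cv_filter(cbind(a = c(-1, 1, 0, 0)), 0.5), "zero mean")
})

test_that("repeated cv filtering removes at least as much as the single stronger filter", {
  set.seed(9)
  for (rep in 1:20) {
    m <- matrix(rnorm(30 * 12, mean = 3), 30, 12)
    colnames(m) <- sprintf("f%02d", 1:12)
    f1 <- runif(1, 0, 0.4)
    f2 <- runif(1, 0, 0.4)
    twice <- cv_filter(cv_filter(m, f1), f2)
    once <- cv_filter(m, max(f1, f2))
    expect_lte(ncol(twice), ncol(once))
  }
})

test_that("assemble_blockset aligns samples by id and reports mismatches", {
  set.seed(10)
  x <- matrix(rnorm(20), 5, 4, dimnames = list(paste0("s", 1:5), paste0("f", 1:4)))
  y <- matrix(rnorm(15), 5, 3, dimnames = list(paste0("s", 5:1), paste0("g", 1:3)))
  bs <- assemble_blockset(list(a = scale2(x), b = scale2(y)))
  expect_equal(rownames(bs$blocks$b), rownames(bs$blocks$a))
  expect_equal(bs$blocks$b["s3", ], scale2(y)["s3", ])
  expect_equal(bs$p, c(a = 4L, b = 3L))

  y2 <- y
  rownames(y2) <- paste0("t", 1:5)
  expect_error(assemble_blockset(list(a = x, b = y2)), "sample mismatch")

  y3 <- y[1:4, ]
  expect_error(assemble_blockset(list(a = x, b = y3, c = x)),
               "missing \\{s1\\}")
})
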