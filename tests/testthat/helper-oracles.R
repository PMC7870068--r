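# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: breadth-first search instead of igraph, direct
# summation formulas, exhaustive grids instead of the block-coordinate
# optimizer.

# BFS connectivity on the off-diagonal zero pattern of a weight matrix.
bfs_connected <- function(C) {
  J <- nrow(C)
  if (J == 1) return(TRUE)
  A <- C > 0
  diag(A) <- FALSE
  seen <- rep(FALSE, J)
  queue <- 1L
  seen[1] <- TRUE
  while (length(queue)) {
    v <- queue[1]
    queue <- queue[-1]
    nb <- which(A[v, ] & !seen)
    seen[nb] <- TRUE
    queue <- c(queue, nb)
  }
  all(seen)
}

# Direct triple-loop transcription of the shrinkage-intensity formula:
# w_kij = x_ki x_kj on standardized columns, r_ij = n/(n-1) mean_k(w),
# Var(r_ij) = n/(n-1)^3 sum_k (w - mean(w))^2, lambda = sum Var / sum r^2.
shrinkage_oracle <- function(x) {
  n <- nrow(x)
  p <- ncol(x)
  xs <- scale(x, center = TRUE, scale = TRUE)
  num <- 0
  den <- 0
  for (i in seq_len(p)) {
    for (j in seq_len(p)) {
      if (i == j) next
      w <- xs[, i] * xs[, j]
      wbar <- mean(w)
      r <- n / (n - 1) * wbar
      num <- num + n / (n - 1)^3 * sum((w - wbar)^2)
      den <- den + r^2
    }
  }
  min(max(num / den, 0), 1)
}

# Population covariance, denominator n.
cov_pop <- function(a, b) mean(a * b) - mean(a) * mean(b)

scheme_fun <- function(scheme) {
  switch(scheme, horst = identity, centroid = abs,
         factorial = function(x) x^2)
}

rgcca_objective_oracle <- function(Y, C, scheme) {
  g <- scheme_fun(scheme)
  J <- length(Y)
  obj <- 0
  for (j in seq_len(J)) {
    for (k in j:J) {
      if (C[j, k] > 0) obj <- obj + C[j, k] * g(cov_pop(Y[[j]], Y[[k]]))
    }
  }
  obj
}

# Exhaustive unit-sphere grid search over the constraint ellipses for 2-3
# blocks of width 2: the best objective over n_angles directions per block.
grid_best_objective <- function(X, C, scheme, tau, n_angles = 721) {
  g <- scheme_fun(scheme)
  J <- length(X)
  n <- nrow(X[[1]])
  theta <- seq(0, 2 * pi, length.out = n_angles)
  U <- rbind(cos(theta), sin(theta))
  Ys <- lapply(seq_len(J), function(j) {
    M <- tau[j] * diag(2) + (1 - tau[j]) * crossprod(X[[j]]) / n
    q <- colSums(U * (M %*% U))
    X[[j]] %*% sweep(U, 2, sqrt(q), "/")
  })
  cg <- function(j, k) {
    if (C[j, k] > 0) C[j, k] * g(crossprod(Ys[[j]], Ys[[k]]) / n)
    else matrix(0, n_angles, n_angles)
  }
  dg <- function(j) {
    if (C[j, j] > 0) C[j, j] * g(colMeans(Ys[[j]]^2)) else numeric(n_angles)
  }
  G12 <- cg(1, 2) + dg(1)
  G12 <- sweep(G12, 2, dg(2), "+")
  if (J == 2) return(max(G12))
  stopifnot(J == 3)
  G13 <- sweep(cg(1, 3), 2, dg(3), "+")
  # join the three pairwise surfaces over all angle triples (compiled
  # max-plus kernel; transposed so the reduction index is contiguous)
  blockcca:::maxplus3_max(G12, t(G13), t(cg(2, 3)))
}

# Small random standardized blockset for property tests.
random_blockset <- function(n = 20, p = c(3, 4), seed = NULL, signal = TRUE) {
  if (!is.null(seed)) set.seed(seed)
  z <- rnorm(n)
  blocks <- lapply(seq_along(p), function(j) {
    x <- matrix(rnorm(n * p[j]), n, p[j])
    if (signal) x <- x + z %*% t(rnorm(p[j]))
    colnames(x) <- paste0("b", j, "f", seq_len(p[j]))
    scale2(x)
  })
  names(blocks) <- paste0("block", seq_along(p))
  assemble_blockset(blocks)
}

# Random connected symmetric design over a weight grid.
random_connected_design <- function(J, grid = c(0, 0.3, 0.7, 1),
                                    diagonal = FALSE) {
  repeat {
    C <- matrix(0, J, J)
    w <- sample(grid, J * (J - 1) / 2, replace = TRUE)
    C[upper.tri(C)] <- w
    C <- C + t(C)
    if (diagonal) diag(C) <- sample(grid, J, replace = TRUE)
    if (bfs_connected(C)) return(C)
  }
}

# Three score vectors with roughly the requested pairwise correlations.
make_components_with_cors <- function(r, n = 1000, seed = 1) {
  set.seed(seed)
  R <- diag(3)
  R[1, 2] <- R[2, 1] <- r[1]
  R[1, 3] <- R[3, 1] <- r[2]
  R[2, 3] <- R[3, 2] <- r[3]
  Z <- matrix(rnorm(n * 3), n, 3) %*% chol(R)
  lapply(1:3, function(j) Z[, j])
}
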