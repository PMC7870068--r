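#' Fit regularized generalized canonical correlation analysis
#'
#' Block-coordinate ascent on the multiblock objective
#' \deqn{\sum_{j \le k} c_{jk}\, g\!\left(\mathrm{cov}(X_j a_j, X_k a_k)\right)}
#' subject to the regularized norm constraint
#' \eqn{a_j^\top M_j a_j = 1} with
#' \eqn{M_j = \tau_j I + (1 - \tau_j) X_j^\top X_j / n}. The scheme
#' determines `g`: identity (`horst`), absolute value (`centroid`, the
#' default, which counts negative component correlations as evidence too), or
#' square (`factorial`). `tau_j = 0` recovers a correlation criterion
#' (classical CCA for two blocks), `tau_j = 1` a covariance criterion
#' (PLS-like). Diagonal design entries `c_jj` add a within-block term
#' `c_jj * g(var(Y_j))`.
#'
#' Further components are extracted by deflating each block by its own
#' component (`X <- X - y (y'X) / (y'y)`) and refitting. Covariances inside
#' the objective use the population denominator `n`, matching the block
#' standardization of [scale2()].
#'
#' @param blocks A `blockset` (see [assemble_blockset()]) of standardized
#'   blocks, or a named list of matrices.
#' @param design Symmetric J x J weight matrix in `[0, 1]`; defaults to all
#'   off-diagonal weights 1. Must be a single connected network (see
#'   [is_connected()]).
#' @param scheme `"centroid"`, `"horst"` or `"factorial"`.
#' @param tau `"estimate"` (Schaefer-Strimmer shrinkage per block, see
#'   [estimate_tau()]), a scalar, or a per-block vector. Categorical-dummy
#'   blocks are always fitted with tau = 1.
#' @param ncomp Number of components, scalar or per-block vector.
#' @param init `"svd"` (deterministic: first right singular vector of each
#'   block) or `"random"` (standard normal; set the RNG seed yourself).
#' @param tol Convergence tolerance on the absolute objective gain per sweep.
#' @param max_iter Maximum sweeps per component.
#' @param n_starts Number of starts. The objective is multimodal in general
#'   (notably under the `horst` scheme when component covariances have mixed
#'   signs); with `n_starts > 1` the deterministic SVD start is followed by
#'   `n_starts - 1` seeded random restarts and the fit with the best
#'   first-component objective is kept.
#' @return An object of class `cca_fit` with elements `loadings` and
#'   `components` (named lists of per-block matrices, one column per
#'   component), `ave` (`$blocks` and `$summary` tibbles, see [ave_inner()]),
#'   `objective_trace` (list per component), `n_iter`, `converged`, and the
#'   settings used. Loadings follow a deterministic sign convention: the
#'   largest-magnitude loading of each block is positive.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(60), 20); y <- x[, 1:2] + matrix(rnorm(40, sd = .5), 20)
#' bs <- blockset(a = scale2(x), b = scale2(y))
#' fit <- fit_rgcca(bs, tau = 1)
#' glance(fit)
#' @export
fit_rgcca <- function(blocks, design = NULL,
                      scheme = c("centroid", "horst", "factorial"),
                      tau = "estimate", ncomp = 1L,
                      init = c("svd", "random"),
                      tol = 1e-8, max_iter = 1000L, n_starts = 1L) {
  scheme <- match.arg(scheme)
  init <- match.arg(init)
  blocks <- as_blockset(blocks)
  tau <- resolve_tau(blocks, tau)
  fit_multistart(blocks, design, scheme, ncomp, init, tol, max_iter,
                 tau = tau, sparsity = NULL, n_starts = n_starts)
}

#' Fit sparse generalized canonical correlation analysis
#'
#' The sparse variant replaces the regularized norm constraint by the
#' intersection of the unit L2 sphere with an L1 ball of radius
#' `s_j * sqrt(p_j)`: loadings are obtained by soft-thresholding the inner
#' gradient and renormalizing, with the threshold found by bisection so the
#' L1 bound is active. `s_j = 1` makes the constraint inactive and reproduces
#' [fit_rgcca()] with tau = 1; `s_j = 1 / sqrt(p_j)` selects exactly one
#' feature. Sparsity is the natural choice for feature-rich assays (RNA-seq,
#' 16S) where only a subset of features carries the inter-block signal.
#'
#' @inheritParams fit_rgcca
#' @param sparsity Scalar or per-block vector of `s_j` in `(0, 1]`, with
#'   `s_j * sqrt(p_j) >= 1` (the constraint set must contain a unit vector).
#' @return A `cca_fit`; see [fit_rgcca()].
#' @export
fit_sgcca <- function(blocks, design = NULL,
                      scheme = c("centroid", "horst", "factorial"),
                      sparsity = 1, ncomp = 1L,
                      init = c("svd", "random"),
                      tol = 1e-8, max_iter = 1000L, n_starts = 1L) {
  scheme <- match.arg(scheme)
  init <- match.arg(init)
  blocks <- as_blockset(blocks)
  J <- length(blocks$blocks)
  stopifnot(is.numeric(sparsity), all(sparsity > 0 & sparsity <= 1))
  if (length(sparsity) == 1) sparsity <- rep(sparsity, J)
  if (!is.null(names(sparsity))) sparsity <- sparsity[names(blocks$blocks)]
  if (length(sparsity) != J) stop("sparsity must have one value per block", call. = FALSE)
  budgets <- sparsity * sqrt(blocks$p)
  if (any(budgets < 1 - 1e-12)) {
    bad <- names(blocks$blocks)[budgets < 1 - 1e-12]
    stop("infeasible sparsity for block(s) ", paste(bad, collapse = ", "),
         ": s_j * sqrt(p_j) must be >= 1", call. = FALSE)
  }
  fit <- fit_multistart(blocks, design, scheme, ncomp, init, tol, max_iter,
                        tau = stats::setNames(rep(1, J), names(blocks$blocks)),
                        sparsity = stats::setNames(sparsity, names(blocks$blocks)),
                        n_starts = n_starts)
  fit$sparsity <- stats::setNames(sparsity, names(blocks$blocks))
  fit
}

# Best-of-n_starts wrapper around fit_core: one deterministic start (or the
# requested init), then seeded random restarts, keeping the highest
# first-component objective.
fit_multistart <- function(blocks, design, scheme, ncomp, init, tol, max_iter,
                           tau, sparsity, n_starts) {
  stopifnot(n_starts >= 1)
  best <- fit_core(blocks, design, scheme, ncomp, init, tol, max_iter,
                   tau = tau, sparsity = sparsity)
  for (s in seq_len(n_starts - 1)) {
    cand <- fit_core(blocks, design, scheme, ncomp, "random", tol, max_iter,
                     tau = tau, sparsity = sparsity)
    if (cand$objective[1] > best$objective[1]) best <- cand
  }
  best
}

# ---- internal optimizer ----------------------------------------------------

scheme_funs <- function(scheme) {
  switch(scheme,
    horst     = list(g = identity,          w = function(x) rep(1, length(x))),
    centroid  = list(g = abs,               w = function(x) ifelse(x >= 0, 1, -1)),
    factorial = list(g = function(x) x^2,   w = function(x) 2 * x)
  )
}

#' Scheme function g applied to a component covariance
#'
#' @param x Covariance value(s).
#' @param scheme `"horst"` (identity), `"centroid"` (absolute value) or
#'   `"factorial"` (square).
#' @return `g(x)`.
#' @export
scheme_g <- function(x, scheme = c("centroid", "horst", "factorial")) {
  scheme <- match.arg(scheme)
  scheme_funs(scheme)$g(x)
}

# population covariance (denominator n) of two centered-ish vectors
cov_n <- function(a, b) mean(a * b) - mean(a) * mean(b)

rgcca_objective <- function(Y, C, g) {
  J <- ncol(Y)
  obj <- 0
  for (j in seq_len(J)) {
    for (k in j:J) {
      if (C[j, k] > 0) obj <- obj + C[j, k] * g(cov_n(Y[, j], Y[, k]))
    }
  }
  obj
}

# Factor M_j = tau I + (1-tau) X'X / n once per (block, component).
# Returns a solver a(v) giving M^{-1} v, or NULL for tau = 1 (identity).
make_m_solver <- function(X, tau, block_name) {
  if (tau >= 1) return(NULL)
  p <- ncol(X)
  M <- (1 - tau) * crossprod(X) / nrow(X)
  diag(M) <- diag(M) + tau
  R <- tryCatch(chol(M), error = function(e) NULL)
  if (is.null(R) || min(diag(R))^2 / max(diag(R))^2 < 1e-24) {
    # near-singular: jitter, then retry
    diag(M) <- diag(M) + 1e-12 * mean(diag(M))
    R <- tryCatch(chol(M), error = function(e) NULL)
    if (is.null(R)) {
      stop("regularized metric is singular for block '", block_name,
           "' (tau = ", signif(tau, 3), "); increase tau", call. = FALSE)
    }
  }
  function(v) backsolve(R, backsolve(R, v, transpose = TRUE))
}

# Projection onto {||a||_2 = 1, ||a||_1 <= budget} by soft-thresholding with
# a bisection on the threshold (budget >= 1 guarantees feasibility).
project_l1 <- function(v, budget) {
  nv <- sqrt(sum(v^2))
  if (nv == 0) stop("cannot project a zero gradient", call. = FALSE)
  a <- v / nv
  if (sum(abs(a)) <= budget + 1e-12) return(a)
  if (budget <= 1 + 1e-12) {
    i <- which.max(abs(v))          # first index on exact ties
    a <- numeric(length(v))
    a[i] <- sign(v[i])
    return(a)
  }
  a <- l1_bisect(v, budget)
  if (!all(is.finite(a)) || sum(abs(a)) > budget + 1e-6) {
    # exact-|v| ties break the soft-threshold path (for instance, the leading
    # singular vector of a standardized two-feature block is exactly
    # (1,1)/sqrt(2), and the optimum then weights the tied coordinates
    # asymmetrically); an infinitesimal ordered perturbation restores it
    a <- l1_bisect(v * (1 + 1e-12 * seq_along(v)), budget)
    if (!all(is.finite(a)) || sum(abs(a)) > budget + 1e-5) {
      i <- which.max(abs(v))
      a <- numeric(length(v))
      a[i] <- sign(v[i])
    }
  }
  a
}

l1_bisect <- function(v, budget) {
  soft <- function(x, l) sign(x) * pmax(abs(x) - l, 0)
  lo <- 0
  hi <- max(abs(v))
  for (it in 1:100) {
    lam <- (lo + hi) / 2
    s <- soft(v, lam)
    ratio <- sum(abs(s)) / sqrt(sum(s^2))
    # an overshot threshold (s identically zero) must shrink lam
    if (is.finite(ratio) && ratio > budget) lo <- lam else hi <- lam
  }
  s <- soft(v, (lo + hi) / 2)
  s / sqrt(sum(s^2))
}

fit_core <- function(blocks, design, scheme, ncomp, init, tol, max_iter,
                     tau, sparsity) {
  X <- blocks$blocks
  J <- length(X)
  nm <- names(X)
  n <- blocks$n
  if (is.null(design)) {
    design <- matrix(1, J, J) - diag(J)
    dimnames(design) <- list(nm, nm)
  }
  design <- design_matrix(design, nm)
  if (nrow(design) != J) stop("design dimension does not match block count", call. = FALSE)
  if (!is_connected(design)) {
    stop("design is not a single connected network; restrict candidates with ",
         "is_connected() / enumerate_designs()", call. = FALSE)
  }
  if (length(ncomp) == 1) ncomp <- rep(as.integer(ncomp), J)
  stopifnot(length(ncomp) == J, all(ncomp >= 1))
  H <- max(ncomp)
  funs <- scheme_funs(scheme)
  sparse <- !is.null(sparsity)

  Xd <- lapply(X, identity)             # deflated working copies
  loadings <- lapply(X, function(x) matrix(NA_real_, ncol(x), H,
                                           dimnames = list(colnames(x), NULL)))
  comps <- lapply(X, function(x) matrix(NA_real_, n, H,
                                        dimnames = list(rownames(x), NULL)))
  traces <- vector("list", H)
  n_iter <- integer(H)
  converged <- logical(H)
  ave_blocks <- vector("list", H)
  ave_summary <- vector("list", H)

  for (h in seq_len(H)) {
    solvers <- lapply(seq_len(J), function(j) {
      if (sparse) NULL else make_m_solver(Xd[[j]], tau[j], nm[j])
    })
    A <- vector("list", J)
    Y <- matrix(0, n, J)
    for (j in seq_len(J)) {
      v <- if (init == "svd") {
        first_right_sv(Xd[[j]])
      } else {
        stats::rnorm(ncol(Xd[[j]]))
      }
      A[[j]] <- normalize_loading(v, Xd[[j]], solvers[[j]], tau[j],
                                  if (sparse) sparsity[j] * sqrt(ncol(Xd[[j]])) else NULL)
      Y[, j] <- Xd[[j]] %*% A[[j]]
    }
    obj <- rgcca_objective(Y, design, funs$g)
    trace <- obj
    iter <- 0L
    repeat {
      iter <- iter + 1L
      for (j in seq_len(J)) {
        covs <- vapply(seq_len(J), function(k) cov_n(Y[, j], Y[, k]), numeric(1))
        wts <- design[j, ] * funs$w(covs)
        # the within-block term g(var(Y_j)) is quadratic in a_j, so its
        # linear ascent surrogate carries a factor 2 (cf. power iteration)
        wts[j] <- 2 * wts[j]
        if (all(wts == 0)) next
        z <- Y %*% wts
        v <- crossprod(Xd[[j]], z)
        if (sparse) {
          if (sqrt(sum(v^2)) < 1e-300) next
          A[[j]] <- project_l1(drop(v), sparsity[j] * sqrt(ncol(Xd[[j]])))
        } else {
          b <- if (is.null(solvers[[j]])) v else solvers[[j]](v)
          denom2 <- sum(v * b)
          if (denom2 < 1e-300) next
          A[[j]] <- drop(b) / sqrt(denom2)
        }
        Y[, j] <- Xd[[j]] %*% A[[j]]
      }
      obj_new <- rgcca_objective(Y, design, funs$g)
      trace <- c(trace, obj_new)
      gain <- obj_new - obj
      obj <- obj_new
      if (gain < tol || iter >= max_iter) break
    }
    # deterministic sign convention: largest-|loading| entry positive
    for (j in seq_len(J)) {
      i_max <- which.max(abs(A[[j]]))
      if (length(i_max) && A[[j]][i_max] < 0) {
        A[[j]] <- -A[[j]]
        Y[, j] <- -Y[, j]
      }
      loadings[[j]][, h] <- A[[j]]
      comps[[j]][, h] <- Y[, j]
    }
    traces[[h]] <- trace
    n_iter[h] <- iter
    converged[h] <- iter < max_iter

    ab <- vapply(seq_len(J), function(j) ave_block(Xd[[j]], Y[, j]), numeric(1))
    ave_blocks[[h]] <- tibble::tibble(component = h, block = nm, ave_block = ab)
    keep_outer <- if (is.null(blocks$superblock)) rep(TRUE, J) else nm != blocks$superblock
    ave_summary[[h]] <- tibble::tibble(
      component = h,
      ave_inner = ave_inner(lapply(seq_len(J), function(j) Y[, j]), design),
      ave_outer = sum(blocks$p[keep_outer] * ab[keep_outer]) / sum(blocks$p[keep_outer])
    )
    if (h < H) {
      for (j in seq_len(J)) {
        if (sum(Y[, j]^2) > 1e-12) Xd[[j]] <- deflate(Xd[[j]], Y[, j])
      }
    }
  }

  # trim per-block components to requested ncomp
  for (j in seq_len(J)) {
    loadings[[j]] <- loadings[[j]][, seq_len(ncomp[j]), drop = FALSE]
    comps[[j]] <- comps[[j]][, seq_len(ncomp[j]), drop = FALSE]
  }
  structure(
    list(loadings = stats::setNames(loadings, nm),
         components = stats::setNames(comps, nm),
         ave = list(blocks = dplyr::bind_rows(ave_blocks),
                    summary = dplyr::bind_rows(ave_summary)),
         objective_trace = traces,
         objective = vapply(traces, function(t) t[length(t)], numeric(1)),
         n_iter = n_iter,
         converged = converged,
         scheme = scheme,
         tau = tau,
         design = design,
         ncomp = stats::setNames(ncomp, nm),
         n = n,
         p = blocks$p,
         kind = blocks$kind,
         superblock = blocks$superblock),
    class = "cca_fit"
  )
}

first_right_sv <- function(x) {
  s <- svd(x, nu = 0, nv = 1)
  drop(s$v)
}

# Scale v onto the constraint set of its variant.
normalize_loading <- function(v, X, solver, tau, budget) {
  if (!is.null(budget)) return(project_l1(drop(v), budget))
  if (is.null(solver)) return(drop(v) / sqrt(sum(v^2)))
  # a = v / sqrt(v' M v); M-norm via the solver is wrong here (need forward
  # product), so compute v' M v directly.
  v <- drop(v)
  mv <- tau * v + (1 - tau) * drop(crossprod(X, X %*% v)) / nrow(X)
  v / sqrt(sum(v * mv))
}

#' Remove a component's contribution from a block
#'
#' @param x Numeric matrix (samples by features).
#' @param y Component vector of length `nrow(x)` with nonzero norm.
#' @return `x - y (y'x) / (y'y)`, whose columns are orthogonal to `y`.
#' @export
deflate <- function(x, y) {
  ny2 <- sum(y^2)
  if (ny2 < 1e-300) stop("cannot deflate by a zero-norm component", call. = FALSE)
  x - y %*% (crossprod(y, x) / ny2)
}

#' @export
print.cca_fit <- function(x, ...) {
  cat("<cca_fit> ", length(x$loadings), " blocks, scheme = ", x$scheme,
      if (!is.null(x$sparsity)) " (sparse)", "\n", sep = "")
  cat("  tau: ", paste(sprintf("%s=%.3g", names(x$tau), x$tau), collapse = ", "),
      "\n", sep = "")
  s <- x$ave$summary
  cat(sprintf("  component %d: inner AVE %.4f, outer AVE %.4f (%s, %d sweeps)\n",
              s$component, s$ave_inner, s$ave_outer,
              ifelse(x$converged, "converged", "max_iter"), x$n_iter))
  invisible(x)
}
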