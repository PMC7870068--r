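#' Schaefer-Strimmer shrinkage estimate of the regularization parameter
#'
#' Estimates the per-block shrinkage intensity tau that interpolates the
#' loading-norm constraint between the correlation criterion (tau = 0) and
#' the covariance criterion (tau = 1). The estimate is the classic
#' Schaefer-Strimmer optimal shrinkage of the sample correlation matrix
#' toward the identity:
#' \deqn{\hat\lambda^* = \sum_{i \ne j} \widehat{Var}(\hat r_{ij}) \Big/
#'       \sum_{i \ne j} \hat r_{ij}^2,}
#' clipped to `[0, 1]`, with `w_kij = x_ki x_kj` computed on internally
#' standardized columns, `r_ij = n/(n-1) * mean_k(w_kij)` and
#' `Var(r_ij) = n/(n-1)^3 * sum_k (w_kij - mean(w))^2`. Blocks with many
#' noisy features shrink more (tau near 1); blocks whose correlations are
#' well determined shrink little.
#'
#' @param x Numeric matrix, samples by features (standardization is done
#'   internally; the result is scale invariant).
#' @return A single value in `[0, 1]`. A single-feature block returns 1 by
#'   convention (there are no off-diagonal correlations to shrink).
#' @references Schaefer & Strimmer (2005), "A shrinkage approach to
#'   large-scale covariance matrix estimation".
#' @export
estimate_tau <- function(x) {
  x <- as_values_matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (p == 1) return(1)
  if (n < 3) stop("estimate_tau() needs at least 3 samples", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant feature(s) in block: ",
         paste(utils::head(colnames(x)[sds == 0], 5), collapse = ", "),
         call. = FALSE)
  }
  xs <- scale(x, center = TRUE, scale = TRUE)
  cp <- crossprod(xs)                              # sum_k x_ki x_kj
  v <- n / ((n - 1)^3) * (crossprod(xs^2) - cp^2 / n)
  diag(v) <- 0
  r2 <- (cp / (n - 1))^2                           # squared sample correlations
  diag(r2) <- 0
  denom <- sum(r2)
  if (denom == 0) return(1)
  min(max(sum(v) / denom, 0), 1)
}

# Resolve a tau specification against a blockset: "estimate", a scalar, or a
# per-block (optionally named) numeric vector. Categorical-dummy blocks are
# forced to tau = 1: for 0/1 indicator variables only covariance with the
# other blocks is meaningful.
resolve_tau <- function(blocks, tau) {
  J <- length(blocks$blocks)
  nm <- names(blocks$blocks)
  if (is.character(tau)) {
    if (!all(tau == "estimate")) stop("tau must be numeric or \"estimate\"", call. = FALSE)
    out <- vapply(blocks$blocks, estimate_tau, numeric(1))
  } else {
    stopifnot(is.numeric(tau))
    if (length(tau) == 1) tau <- rep(tau, J)
    if (!is.null(names(tau))) tau <- tau[nm]
    if (length(tau) != J || anyNA(tau)) {
      stop("tau must have one value per block", call. = FALSE)
    }
    if (any(tau < 0 | tau > 1)) stop("tau values must lie in [0, 1]", call. = FALSE)
    out <- tau
  }
  out[blocks$kind == "categorical-dummy"] <- 1
  names(out) <- nm
  out
}
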