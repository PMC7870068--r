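#' Generate a multi-block dataset with planted latent structure
#'
#' Simulates the kind of data the integration pipeline targets: several
#' sample-by-feature blocks sharing low-rank latent structure whose
#' inter-block factor correlations follow a planted design graph. Per-sample
#' latent factor vectors `(t_1, ..., t_J)` are drawn from a multivariate
#' normal whose correlation matrix has off-diagonal entries
#' `cor_scale * D_jk` (the design-to-correlation map; positive-definiteness
#' is checked on every call). Each block is then
#' `X_j = sum_d t_jd w_jd' + noise`, with sparse unit-norm loading vectors
#' `w_jd` and i.i.d. Gaussian noise. Categorical covariates shift the latent
#' factors by centered, equally spaced level effects, so a two-level
#' covariate with effect `e` separates its groups by `e` latent standard
#' deviations.
#'
#' @param n Number of samples (default 200).
#' @param p Per-block feature counts (default `c(50, 50)`); `length(p)`
#'   defines the number of blocks.
#' @param design Planted symmetric J x J design `D*` in `[0, 1]`; defaults
#'   to all off-diagonal entries 1.
#' @param latent_dim Number of latent factors per block (default 1).
#' @param loading_sparsity Fraction of nonzero entries per loading vector,
#'   in `(0, 1]` (default 0.3).
#' @param noise_sd Standard deviation of the additive feature noise
#'   (default 0.5; the latent signal has unit scale).
#' @param cor_scale Map from design weight to target factor correlation
#'   (default 0.8, keeping strong designs comfortably positive definite).
#' @param covariates Optional named list of covariate specs, each
#'   `list(levels = k or character vector, effect = e)` with `effect` a
#'   scalar or per-block vector of latent-scale shifts. Covariate level
#'   assignments are uniform.
#' @param heavy_tail If `TRUE`, one extra microbiome-like version of each
#'   block is returned in `tables_counts`, exponentiated and rounded to
#'   mimic skewed count data.
#' @param seed RNG seed; identical seeds give bitwise-identical output.
#' @return A list of class `synthetic_blockset`:
#'   * `tables`: named list of raw `n x p_j` matrices (`block1`, ...),
#'   * `metadata`: tibble of `sample_id` plus covariate columns,
#'   * `truth`: factors (`n x J` per latent dim), loadings, the planted
#'     design, the target and realized factor correlation matrices, and the
#'     covariate assignments.
#' @export
generate_blockset <- function(n = 200, p = c(50, 50), design = NULL,
                              latent_dim = 1, loading_sparsity = 0.3,
                              noise_sd = 0.5, cor_scale = 0.8,
                              covariates = NULL, heavy_tail = FALSE,
                              seed = NULL) {
  J <- length(p)
  stopifnot(n >= 2, J >= 1, latent_dim >= 1,
            loading_sparsity > 0, loading_sparsity <= 1, noise_sd >= 0)
  if (is.null(design)) design <- matrix(1, J, J) - diag(J)
  design <- design_matrix(design)
  if (nrow(design) != J) stop("design dimension must match length(p)", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)

  R <- cor_scale * design
  diag(R) <- 1
  ed <- eigen(R, symmetric = TRUE)
  if (min(ed$values) < -1e-8) {
    hot <- which(design > 0 & upper.tri(design), arr.ind = TRUE)
    stop("infeasible factor correlation targets (non-positive-definite); ",
         "reduce cor_scale or the weights of entries ",
         paste(sprintf("(%d,%d)=%.2f", hot[, 1], hot[, 2],
                       design[hot]), collapse = ", "), call. = FALSE)
  }
  # square root factor; semidefinite targets (perfectly shared factors) allowed
  L <- diag(sqrt(pmax(ed$values, 0)), nrow = J) %*% t(ed$vectors)

  block_names <- paste0("block", seq_len(J))
  meta <- tibble::tibble(sample_id = sprintf("s%04d", seq_len(n)))
  shift <- matrix(0, n, J)
  cov_assign <- list()
  if (!is.null(covariates)) {
    for (cn in names(covariates)) {
      spec <- covariates[[cn]]
      levs <- spec$levels
      if (length(levs) == 1 && is.numeric(levs)) levs <- paste0("l", seq_len(levs))
      k <- length(levs)
      stopifnot(k >= 2)
      eff <- spec$effect
      if (length(eff) == 1) eff <- rep(eff, J)
      stopifnot(length(eff) == J)
      g <- sample(seq_len(k), n, replace = TRUE)
      codes <- seq(-0.5, 0.5, length.out = k)         # centered, spaced by 1/(k-1)
      shift <- shift + outer(codes[g], eff)
      meta[[cn]] <- levs[g]
      cov_assign[[cn]] <- levs[g]
    }
  }

  factors <- vector("list", latent_dim)
  loadings <- vector("list", J)
  names(loadings) <- block_names
  tables <- vector("list", J)
  names(tables) <- block_names
  for (d in seq_len(latent_dim)) {
    Z <- matrix(stats::rnorm(n * J), n, J)
    factors[[d]] <- Z %*% L + shift
    colnames(factors[[d]]) <- block_names
  }
  for (j in seq_len(J)) {
    W <- matrix(0, p[j], latent_dim)
    n_nz <- max(1L, ceiling(loading_sparsity * p[j]))
    for (d in seq_len(latent_dim)) {
      # equal-magnitude random-sign loadings: every support feature carries
      # the same signal strength, so "support" is a well-posed target
      supp <- sample.int(p[j], n_nz)
      w <- numeric(p[j])
      w[supp] <- sample(c(-1, 1), n_nz, replace = TRUE)
      W[, d] <- w / sqrt(sum(w^2))
    }
    signal <- matrix(0, n, p[j])
    for (d in seq_len(latent_dim)) {
      signal <- signal + factors[[d]][, j] %*% t(W[, d])
    }
    X <- signal + matrix(stats::rnorm(n * p[j], sd = noise_sd), n, p[j])
    dimnames(X) <- list(meta$sample_id, sprintf("%s_f%03d", block_names[j],
                                                seq_len(p[j])))
    loadings[[j]] <- W
    tables[[j]] <- X
  }
  realized <- stats::cor(factors[[1]])
  out <- list(
    tables = tables,
    metadata = meta,
    truth = list(factors = factors, loadings = loadings, design = design,
                 cor_target = R, cor_realized = realized,
                 covariates = cov_assign,
                 params = list(n = n, p = p, latent_dim = latent_dim,
                               loading_sparsity = loading_sparsity,
                               noise_sd = noise_sd, cor_scale = cor_scale,
                               seed = seed))
  )
  if (heavy_tail) {
    out$tables_counts <- lapply(tables, function(X) round(exp(X)))
  }
  class(out) <- "synthetic_blockset"
  out
}

#' @export
print.synthetic_blockset <- function(x, ...) {
  pr <- x$truth$params
  cat("<synthetic_blockset> ", pr$n, " samples, ",
      length(x$tables), " blocks (p = ", paste(pr$p, collapse = ", "),
      "), latent_dim ", pr$latent_dim, ", noise_sd ", pr$noise_sd, "\n", sep = "")
  if (length(x$truth$covariates)) {
    cat("  covariates:", paste(names(x$truth$covariates), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Standardize a synthetic dataset into an analysis-ready blockset
#'
#' Applies [scale2()] to every simulated block and optionally appends
#' dummy-encoded covariate blocks from the metadata.
#'
#' @param sim A `synthetic_blockset`.
#' @param covariate_blocks Character vector of covariate names to include as
#'   categorical-dummy blocks (default: all simulated covariates).
#' @return A `blockset`.
#' @export
as_scaled_blockset <- function(sim, covariate_blocks = NULL) {
  stopifnot(inherits(sim, "synthetic_blockset"))
  blocks <- lapply(sim$tables, scale2)
  if (is.null(covariate_blocks)) covariate_blocks <- names(sim$truth$covariates)
  for (cn in covariate_blocks) {
    dummies <- encode_categorical(sim$metadata[[cn]], name = cn)
    rownames(dummies) <- sim$metadata$sample_id
    blocks[[cn]] <- scale2(dummies)
  }
  assemble_blockset(blocks, sample_ids = sim$metadata$sample_id)
}

#' Generate a confounded two-omic scenario
#'
#' A scenario generator for the model-family experiments: a categorical
#' covariate (think sample location or sex) drives the latent factors of
#' both omic blocks, on top of a weak direct inter-block interaction. A
#' model that includes the covariate as its own block should then reach a
#' higher inner AVE than the two-block "model 0" that ignores it — and be
#' more stable under resampling.
#'
#' @param n,p,noise_sd,seed As in [generate_blockset()] (two omic blocks).
#' @param effect Latent-scale group separation induced by the covariate on
#'   both omic blocks (default 2, a strong confounder; 0 gives the null
#'   scenario).
#' @param base_weight Planted direct design weight between the two omic
#'   blocks (default 0: pure confounding, the inter-block association exists
#'   only through the shared covariate; set it above 0 to add a direct
#'   latent interaction on top).
#' @return A list: `sim` (the `synthetic_blockset`), `blocks0` (two-block
#'   blockset), `blocks_cov` (three-block blockset including the
#'   dummy-encoded covariate), `design0` and `design_cov` (all declared
#'   interactions at weight 1).
#' @export
make_confounded_scenario <- function(n = 200, p = c(50, 50), effect = 2,
                                     base_weight = 0, noise_sd = 0.5,
                                     seed = NULL) {
  D <- matrix(c(0, base_weight, base_weight, 0), 2)
  sim <- generate_blockset(
    n = n, p = p, design = D, latent_dim = 1, noise_sd = noise_sd,
    covariates = list(group = list(levels = 2, effect = effect)),
    seed = seed
  )
  blocks_cov <- as_scaled_blockset(sim)
  blocks0 <- assemble_blockset(blocks_cov$blocks[c("block1", "block2")])
  J3 <- matrix(1, 3, 3) - diag(3)
  list(
    sim = sim,
    blocks0 = blocks0,
    blocks_cov = blocks_cov,
    design0 = design_matrix(matrix(c(0, 1, 1, 0), 2),
                            c("block1", "block2")),
    design_cov = design_matrix(J3, c("block1", "block2", "group"))
  )
}
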