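#' Bootstrap the stability of a model's AVE
#'
#' Draws `B` bootstrap resamples of the samples (with replacement), applies
#' the same index vector to every block so sample linkage is preserved,
#' re-standardizes each resampled block with [scale2()] (resampling changes
#' column means and variances), refits the model with fixed scheme, tau and
#' sparsity, and records the first component's inner and outer AVE. The
#' dispersion of these values measures how robust a model is: a model that
#' truly captures the block relationships keeps a high inner AVE with a
#' small standard deviation across resamples.
#'
#' Each replicate draws its indices from its own RNG stream derived from the
#' master seed by a counter (`seed + b`), so increasing `B` extends the
#' replicate set without perturbing earlier replicates.
#'
#' @param blocks A `blockset`.
#' @param design The model's design matrix.
#' @param scheme,tau,sparsity,ncomp,init,tol,max_iter As in [fit_rgcca()] /
#'   [fit_sgcca()]. `tau = "estimate"` is resolved once on the full data and
#'   held fixed across replicates unless `re_estimate_tau = TRUE`.
#' @param B Number of bootstrap replicates.
#' @param seed Master seed for the replicate streams.
#' @param re_estimate_tau Re-run [estimate_tau()] inside every replicate.
#' @param model_id Label carried into the summary.
#' @param indices Optional list of `B` index vectors overriding the random
#'   resampling (e.g. for validation against the full-data fit).
#' @return An object of class `cca_boot`: list with `replicates` (tibble:
#'   `replicate`, `ave_inner`, `ave_outer`, `converged`), `summary` (tibble:
#'   `model_id`, `metric`, `mean`, `sd`, `n`), `B`, `n_failed`, `seed`.
#'   Replicates whose resample produces a degenerate block (e.g. a constant
#'   dummy column) are dropped and counted in `n_failed`; more than 50%
#'   failures is an error.
#' @export
bootstrap_model <- function(blocks, design,
                            scheme = c("centroid", "horst", "factorial"),
                            tau = "estimate", sparsity = NULL, ncomp = 1L,
                            B = 1000L, seed = 1L, re_estimate_tau = FALSE,
                            model_id = "model", indices = NULL,
                            init = "svd", tol = 1e-8, max_iter = 1000L) {
  scheme <- match.arg(scheme)
  blocks <- as_blockset(blocks)
  stopifnot(B >= 1)
  if (!is.null(indices)) stopifnot(length(indices) >= B)
  n <- blocks$n
  if (!re_estimate_tau && is.null(sparsity)) tau <- resolve_tau(blocks, tau)

  reps <- vector("list", B)
  n_failed <- 0L
  for (b in seq_len(B)) {
    if (is.null(indices)) {
      set.seed((seed + b) %% .Machine$integer.max)
      idx <- sample.int(n, n, replace = TRUE)
    } else {
      idx <- indices[[b]]
    }
    res <- tryCatch({
      rb <- blockset_rows(blocks, idx)
      rb$blocks <- lapply(rb$blocks, scale2)
      fit <- if (is.null(sparsity)) {
        fit_rgcca(rb, design, scheme = scheme, tau = tau, ncomp = ncomp,
                  init = init, tol = tol, max_iter = max_iter)
      } else {
        fit_sgcca(rb, design, scheme = scheme, sparsity = sparsity,
                  ncomp = ncomp, init = init, tol = tol, max_iter = max_iter)
      }
      s1 <- fit$ave$summary[1, ]
      tibble::tibble(replicate = b, ave_inner = s1$ave_inner,
                     ave_outer = s1$ave_outer, converged = fit$converged[1])
    }, error = function(e) NULL)
    if (is.null(res)) n_failed <- n_failed + 1L else reps[[b]] <- res
  }
  if (n_failed > B / 2) {
    stop("more than half of the bootstrap replicates failed (", n_failed,
         " of ", B, "); check for near-constant features or tiny n", call. = FALSE)
  }
  replicates <- dplyr::bind_rows(reps)
  sd_or_zero <- function(x) {
    if (length(x) < 2) {
      warning("fewer than 2 successful replicates; sd reported as 0", call. = FALSE)
      0
    } else {
      stats::sd(x)
    }
  }
  summary <- tibble::tibble(
    model_id = model_id,
    metric = c("inner", "outer"),
    mean = c(mean(replicates$ave_inner), mean(replicates$ave_outer)),
    sd = c(sd_or_zero(replicates$ave_inner), sd_or_zero(replicates$ave_outer)),
    n = nrow(replicates)
  )
  structure(
    list(replicates = replicates, summary = summary, B = B,
         n_failed = n_failed, seed = seed, model_id = model_id,
         design = design, scheme = scheme),
    class = "cca_boot"
  )
}

#' Compare bootstrap summaries across models
#'
#' Orders models by mean inner AVE (descending; ties go to the smaller
#' standard deviation) and flags a dominant model: one that simultaneously
#' has the highest mean and the lowest sd of the inner AVE, i.e. is both the
#' best-explaining and the most stable model.
#'
#' @param summaries List of `cca_boot` objects on the same data.
#' @param model_ids Optional labels overriding each object's `model_id`.
#' @return A tibble with one row per model: `model_id`, `inner_mean`,
#'   `inner_sd`, `outer_mean`, `outer_sd`, `n`, `dominant`.
#' @export
summarize_dispersion <- function(summaries, model_ids = NULL) {
  if (inherits(summaries, "cca_boot")) summaries <- list(summaries)
  stopifnot(all(vapply(summaries, inherits, logical(1), "cca_boot")))
  if (is.null(model_ids)) {
    model_ids <- vapply(summaries, function(s) s$model_id, character(1))
  }
  tab <- purrr::map2_dfr(summaries, model_ids, function(s, id) {
    sm <- s$summary
    tibble::tibble(
      model_id = id,
      inner_mean = sm$mean[sm$metric == "inner"],
      inner_sd = sm$sd[sm$metric == "inner"],
      outer_mean = sm$mean[sm$metric == "outer"],
      outer_sd = sm$sd[sm$metric == "outer"],
      n = sm$n[1]
    )
  })
  tab <- tab[order(-tab$inner_mean, tab$inner_sd), ]
  tab$dominant <- FALSE
  if (nrow(tab) > 1) {
    tab$dominant[1] <- tab$inner_mean[1] >= max(tab$inner_mean) &
      tab$inner_sd[1] <= min(tab$inner_sd)
  }
  tab
}

#' @export
print.cca_boot <- function(x, ...) {
  cat("<cca_boot> ", x$model_id, ": ", nrow(x$replicates), " of ", x$B,
      " replicates (", x$n_failed, " failed), seed ", x$seed, "\n", sep = "")
  print(x$summary)
  invisible(x)
}
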