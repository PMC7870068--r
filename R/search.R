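#' Search candidate designs and rank them by inner AVE
#'
#' The central model-discovery procedure: expand the template's weight grid
#' over its free edges, keep only designs forming a single connected network,
#' fit every survivor with identical settings, and rank by the first
#' component's inner AVE (higher is better). Two stages mirror common
#' practice: a `coarse` stage over `{0, 0.5, 1}` to find the promising
#' interaction pattern, then a `fine` stage over `0, 0.1, ..., 1` —
#' optionally restricted to a window around the coarse optimum — to pin down
#' the weights.
#'
#' Ties in inner AVE (within 1e-12) are broken toward the design with fewer
#' nonzero edges, then toward the lexicographically smaller weight vector,
#' so rankings are deterministic.
#'
#' @param blocks A `blockset`.
#' @param template A [model_template()]. For the `fine` stage the template's
#'   grid is replaced by `seq(0, 1, 0.1)`.
#' @param scheme,tau,ncomp,init,tol,max_iter Passed to [fit_rgcca()].
#'   `tau = "estimate"` is resolved once per block on the full data and then
#'   shared by every candidate.
#' @param sparsity If non-`NULL`, candidates are fitted with [fit_sgcca()]
#'   at this sparsity instead.
#' @param stage `"coarse"` (template grid, default `{0, 0.5, 1}`) or
#'   `"fine"` (`0` to `1` by `0.1`).
#' @param around Optional design matrix (e.g. the coarse winner); with
#'   `stage = "fine"` each free edge's grid is restricted to within
#'   `local_window` of this design's weight.
#' @param local_window Half-width of the restriction window (default 0.2).
#' @param cap Passed to [enumerate_designs()].
#' @return An object of class `cca_search`: list with `ranking` (a tibble,
#'   one row per candidate, sorted), `designs` (named by `model_id`),
#'   `best_fit` (the refitted top candidate), `n_enumerated`,
#'   `n_filtered_disconnected`, and the settings used.
#' @examples
#' \donttest{
#' sim <- generate_blockset(n = 100, p = c(20, 20),
#'                          design = matrix(c(0, 1, 1, 0), 2), seed = 1)
#' bs <- blockset(a = scale2(sim$tables$block1), b = scale2(sim$tables$block2))
#' sr <- search_models(bs, model_template(bs), tau = 1)
#' sr$ranking
#' }
#' @export
search_models <- function(blocks, template,
                          scheme = c("centroid", "horst", "factorial"),
                          tau = "estimate", sparsity = NULL, ncomp = 1L,
                          stage = c("coarse", "fine"), around = NULL,
                          local_window = 0.2, init = "svd",
                          tol = 1e-8, max_iter = 1000L, cap = 1e6) {
  scheme <- match.arg(scheme)
  stage <- match.arg(stage)
  blocks <- as_blockset(blocks)
  stopifnot(inherits(template, "model_template"))
  tau <- resolve_tau(blocks, tau)

  grids <- NULL
  if (stage == "fine") {
    fine_grid <- seq(0, 1, by = 0.1)
    if (is.null(around)) {
      template$grid <- fine_grid
    } else {
      idx <- free_edges(template)
      grids <- lapply(seq_len(nrow(idx)), function(e) {
        w0 <- around[idx[e, 1], idx[e, 2]]
        g <- fine_grid[fine_grid >= w0 - local_window - 1e-9 &
                       fine_grid <= w0 + local_window + 1e-9]
        if (length(g) == 0) fine_grid else g
      })
    }
  }
  designs <- enumerate_designs(template, grids = grids, cap = cap)
  if (length(designs) == 0) stop("no connected candidate designs", call. = FALSE)
  W <- attr(designs, "weights")
  labs <- attr(designs, "edge_labels")

  fit_one <- function(C) {
    if (is.null(sparsity)) {
      fit_rgcca(blocks, C, scheme = scheme, tau = tau, ncomp = ncomp,
                init = init, tol = tol, max_iter = max_iter)
    } else {
      fit_sgcca(blocks, C, scheme = scheme, sparsity = sparsity, ncomp = ncomp,
                init = init, tol = tol, max_iter = max_iter)
    }
  }
  rows <- vector("list", length(designs))
  for (i in seq_along(designs)) {
    C <- designs[[i]]
    res <- tryCatch(fit_one(C), error = function(e) e)
    if (inherits(res, "error")) {
      rows[[i]] <- tibble::tibble(
        candidate = i, ave_inner = NA_real_, ave_outer = NA_real_,
        objective = NA_real_, converged = NA, n_iter = NA_integer_,
        error = conditionMessage(res))
    } else {
      s1 <- res$ave$summary[1, ]
      rows[[i]] <- tibble::tibble(
        candidate = i, ave_inner = s1$ave_inner, ave_outer = s1$ave_outer,
        objective = res$objective[1], converged = res$converged[1],
        n_iter = res$n_iter[1], error = NA_character_)
    }
  }
  ranking <- dplyr::bind_rows(rows)
  if (all(is.na(ranking$ave_inner))) {
    stop("all candidate fits failed; first error: ",
         ranking$error[!is.na(ranking$error)][1], call. = FALSE)
  }
  n_edges <- vapply(designs, function(C) {
    sum(C[upper.tri(C, diag = TRUE)] > 0)
  }, numeric(1))
  wkey <- apply(W, 1, function(w) paste(sprintf("%.3f", w), collapse = ","))
  ord <- order(-ifelse(is.na(ranking$ave_inner), -Inf, ranking$ave_inner),
               n_edges, wkey)
  ranking <- ranking[ord, ]
  Wtib <- tibble::as_tibble(as.data.frame(W[ord, , drop = FALSE]))
  names(Wtib) <- labs
  ranking <- dplyr::bind_cols(
    tibble::tibble(model_id = sprintf("m%04d", seq_along(ord))),
    Wtib,
    ranking[, c("ave_inner", "ave_outer", "objective", "converged",
                "n_iter", "candidate", "error")]
  )
  designs_sorted <- stats::setNames(designs[ord], ranking$model_id)
  best_fit <- fit_one(designs_sorted[[1]])
  structure(
    list(ranking = ranking,
         designs = designs_sorted,
         best_fit = best_fit,
         n_enumerated = attr(designs, "n_enumerated"),
         n_filtered_disconnected = attr(designs, "n_filtered_disconnected"),
         template = template, stage = stage, scheme = scheme,
         tau = tau, sparsity = sparsity, ncomp = ncomp),
    class = "cca_search"
  )
}

#' @export
print.cca_search <- function(x, ...) {
  cat("<cca_search> ", x$stage, " stage: ", x$n_enumerated, " enumerated, ",
      x$n_filtered_disconnected, " disconnected, ",
      nrow(x$ranking), " fitted\n", sep = "")
  print(utils::head(x$ranking, 5))
  invisible(x)
}
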