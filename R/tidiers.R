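#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fitted multiblock model into a loading table
#'
#' @param x A `cca_fit`.
#' @param ... Unused.
#' @return Tibble with columns `block`, `feature`, `component`, `loading`,
#'   `selected` (nonzero loading).
#' @method tidy cca_fit
#' @export
tidy.cca_fit <- function(x, ...) {
  purrr::map_dfr(names(x$loadings), function(nm) {
    L <- x$loadings[[nm]]
    tidyr::pivot_longer(
      dplyr::mutate(tibble::as_tibble(L, .name_repair = ~paste0("comp", seq_along(.))),
                    block = nm, feature = rownames(L)),
      cols = dplyr::starts_with("comp"),
      names_to = "component", names_prefix = "comp",
      names_transform = list(component = as.integer),
      values_to = "loading"
    )
  }) |>
    dplyr::mutate(selected = .data$loading != 0) |>
    dplyr::select("block", "feature", "component", "loading", "selected")
}

#' One-row summary of a fitted multiblock model
#'
#' @param x A `cca_fit`.
#' @param ... Unused.
#' @return Tibble with the first component's inner and outer AVE, final
#'   objective, convergence and settings.
#' @method glance cca_fit
#' @export
glance.cca_fit <- function(x, ...) {
  s1 <- x$ave$summary[1, ]
  tibble::tibble(
    n = x$n, n_blocks = length(x$loadings), scheme = x$scheme,
    sparse = !is.null(x$sparsity), ncomp = max(x$ncomp),
    ave_inner = s1$ave_inner, ave_outer = s1$ave_outer,
    objective = x$objective[1], n_iter = x$n_iter[1],
    converged = all(x$converged)
  )
}

#' @describeIn search_models Tidy the ranking table of a design search.
#' @param x A `cca_search`.
#' @param ... Unused.
#' @method tidy cca_search
#' @export
tidy.cca_search <- function(x, ...) x$ranking

#' @describeIn search_models One-row summary of a design search.
#' @method glance cca_search
#' @export
glance.cca_search <- function(x, ...) {
  tibble::tibble(
    stage = x$stage, scheme = x$scheme,
    n_enumerated = x$n_enumerated,
    n_filtered_disconnected = x$n_filtered_disconnected,
    n_fitted = nrow(x$ranking),
    best_model = x$ranking$model_id[1],
    best_ave_inner = x$ranking$ave_inner[1],
    best_ave_outer = x$ranking$ave_outer[1]
  )
}

#' @describeIn bootstrap_model Per-replicate AVE values as a tibble.
#' @param x A `cca_boot`.
#' @param ... Unused.
#' @method tidy cca_boot
#' @export
tidy.cca_boot <- function(x, ...) x$replicates

#' @describeIn bootstrap_model One-row bootstrap summary.
#' @method glance cca_boot
#' @export
glance.cca_boot <- function(x, ...) {
  sm <- x$summary
  tibble::tibble(
    model_id = x$model_id, B = x$B, n_failed = x$n_failed,
    inner_mean = sm$mean[sm$metric == "inner"],
    inner_sd = sm$sd[sm$metric == "inner"],
    outer_mean = sm$mean[sm$metric == "outer"],
    outer_sd = sm$sd[sm$metric == "outer"]
  )
}

#' Rank the variables a model selected from one block
#'
#' Lists the nonzero loadings of a block, with sign and magnitude, sorted by
#' magnitude — the per-block variable-selection report. For dense
#' (non-sparse) fits a magnitude threshold controls inclusion.
#'
#' @param fit A `cca_fit`.
#' @param block Block name.
#' @param component Component index (default 1).
#' @param threshold Minimum absolute loading to include (default 0: all
#'   nonzero loadings).
#' @return Tibble with columns `block`, `feature`, `loading`, `sign`,
#'   `magnitude`, `rank`. Empty (with a warning) if every loading is zero.
#' @export
select_variables <- function(fit, block, component = 1, threshold = 0) {
  stopifnot(inherits(fit, "cca_fit"))
  if (!block %in% names(fit$loadings)) {
    stop("unknown block '", block, "'; available: ",
         paste(names(fit$loadings), collapse = ", "), call. = FALSE)
  }
  a <- fit$loadings[[block]][, component]
  keep <- abs(a) > max(threshold, 0)
  if (!any(keep)) {
    warning("no variables selected in block '", block, "'", call. = FALSE)
    return(tibble::tibble(block = character(), feature = character(),
                          loading = numeric(), sign = integer(),
                          magnitude = numeric(), rank = integer()))
  }
  a <- a[keep]
  ord <- order(-abs(a), names(a))
  tibble::tibble(
    block = block,
    feature = names(a)[ord],
    loading = unname(a[ord]),
    sign = as.integer(sign(a[ord])),
    magnitude = abs(unname(a[ord])),
    rank = seq_along(ord)
  )
}
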