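#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot sample scores of a fitted multiblock model
#'
#' Scatter of the first two components of one block (or, for single-component
#' fits, the first components of two blocks against each other), optionally
#' colored by a grouping variable.
#'
#' @param object A `cca_fit`.
#' @param block Block whose components are plotted (default: first block).
#'   If the fit has a single component, provide two block names.
#' @param color Optional per-sample grouping vector.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cca_fit
#' @export
autoplot.cca_fit <- function(object, block = NULL, color = NULL, ...) {
  if (is.null(block)) block <- names(object$components)[1]
  if (length(block) == 1 && ncol(object$components[[block]]) >= 2) {
    df <- tibble::tibble(
      x = object$components[[block]][, 1],
      y = object$components[[block]][, 2]
    )
    labs <- paste(block, c("component 1", "component 2"))
  } else {
    if (length(block) == 1) block <- utils::head(names(object$components), 2)
    df <- tibble::tibble(
      x = object$components[[block[1]]][, 1],
      y = object$components[[block[2]]][, 1]
    )
    labs <- paste(block, "component 1")
  }
  p <- if (is.null(color)) {
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
      ggplot2::geom_point()
  } else {
    df$group <- color
    ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                     color = .data$group)) +
      ggplot2::geom_point()
  }
  p + ggplot2::labs(x = labs[1], y = labs[2]) + ggplot2::theme_minimal()
}

#' Plot a design search ranking
#'
#' Inner (and outer) AVE of every fitted candidate design, in rank order.
#'
#' @param object A `cca_search`.
#' @param top Show at most this many candidates (default 50).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cca_search
#' @export
autoplot.cca_search <- function(object, top = 50, ...) {
  df <- utils::head(object$ranking, top)
  df <- tidyr::pivot_longer(df[, c("model_id", "ave_inner", "ave_outer")],
                            cols = c("ave_inner", "ave_outer"),
                            names_to = "metric", values_to = "ave")
  df$model_id <- factor(df$model_id, levels = unique(df$model_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_id, y = .data$ave,
                                   color = .data$metric, group = .data$metric)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "candidate model (ranked)", y = "AVE") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' Plot bootstrap AVE dispersion
#'
#' Distribution of inner and outer AVE over bootstrap replicates; pass
#' several `cca_boot` objects to compare the stability of competing models.
#'
#' @param object A `cca_boot`, or list of them.
#' @param ... Further `cca_boot` objects.
#' @return A ggplot.
#' @method autoplot cca_boot
#' @export
autoplot.cca_boot <- function(object, ...) {
  boots <- c(list(object), Filter(function(o) inherits(o, "cca_boot"), list(...)))
  df <- purrr::map_dfr(boots, function(b) {
    dplyr::mutate(b$replicates, model_id = b$model_id)
  })
  df <- tidyr::pivot_longer(df, cols = c("ave_inner", "ave_outer"),
                            names_to = "metric", values_to = "ave")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model_id, y = .data$ave)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "bootstrapped AVE") +
    ggplot2::theme_minimal()
}
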