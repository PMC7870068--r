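#' Average variance explained of a block by a component
#'
#' The variance-weighted mean of squared correlations between a block's
#' features and a component:
#' `sum_k var(x_k) cor^2(x_k, y) / sum_k var(x_k)`. After [scale2()] all
#' features have equal variance and this reduces to the plain mean of
#' squared correlations. Features with zero variance (possible in deflated
#' data) contribute nothing.
#'
#' @param block Numeric matrix, samples by features.
#' @param component Numeric score vector, one value per sample; must not be
#'   constant.
#' @return A value in `[0, 1]`.
#' @export
ave_block <- function(block, component) {
  block <- as.matrix(block)
  if (stats::sd(component) == 0) {
    stop("component is constant; AVE undefined", call. = FALSE)
  }
  v <- apply(block, 2, stats::var)
  ok <- v > 0
  if (!any(ok)) return(0)
  r2 <- as.vector(stats::cor(block[, ok, drop = FALSE], component))^2
  sum(v[ok] * r2) / sum(v)
}

#' Inner average variance explained
#'
#' The model-selection criterion: how well the blocks' components correlate
#' with one another, averaged over the declared interactions with the design
#' weights as multipliers:
#' `sum_{j<k} c_jk cor^2(y_j, y_k) / sum_{j<k} c_jk`. Diagonal (within-block)
#' design entries are excluded — `cor(y_j, y_j) = 1` would inflate the
#' criterion trivially. Higher is better: among connected candidate designs
#' the one maximizing the inner AVE best represents the block relationships.
#'
#' @param components List of per-block component vectors (or a matrix with
#'   one column per block).
#' @param design Symmetric weight matrix.
#' @param mask If `TRUE`, weights are used only as a 0/1 interaction mask
#'   (unweighted mean over declared edges), for sensitivity checks.
#' @return A value in `[0, 1]`.
#' @export
ave_inner <- function(components, design, mask = FALSE) {
  if (is.matrix(components)) {
    components <- lapply(seq_len(ncol(components)), function(j) components[, j])
  }
  J <- length(components)
  stopifnot(nrow(design) == J)
  num <- 0
  den <- 0
  for (j in seq_len(J)) {
    for (k in seq_len(J)) {
      if (k <= j) next
      w <- design[j, k]
      if (w <= 0) next
      if (mask) w <- 1
      num <- num + w * stats::cor(components[[j]], components[[k]])^2
      den <- den + w
    }
  }
  if (den == 0) {
    stop("all off-diagonal design weights are zero; inner AVE undefined",
         call. = FALSE)
  }
  num / den
}

#' Outer average variance explained
#'
#' Size-weighted mean of the block AVEs, `sum_j p_j ave_j / sum_j p_j`: how
#' well the features of every block correlate with their own component.
#'
#' @param blocks A `blockset` or named list of matrices.
#' @param components List of per-block component vectors, same order.
#' @param exclude Block names excluded from the total (used for the
#'   superblock, whose features duplicate the other blocks').
#' @return A value in `[0, 1]`.
#' @export
ave_outer <- function(blocks, components, exclude = character()) {
  if (inherits(blocks, "blockset")) {
    if (!is.null(blocks$superblock)) exclude <- union(exclude, blocks$superblock)
    blocks <- blocks$blocks
  }
  stopifnot(length(blocks) == length(components))
  keep <- !(names(blocks) %in% exclude)
  p <- vapply(blocks, ncol, numeric(1))
  aves <- vapply(seq_along(blocks), function(j) {
    ave_block(blocks[[j]], components[[j]])
  }, numeric(1))
  sum(p[keep] * aves[keep]) / sum(p[keep])
}
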