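#' Area under the ROC curve (Mann-Whitney form)
#'
#' The probability that a randomly drawn positive scores above a randomly
#' drawn negative, ties counted one half — computed from rank sums, which is
#' exactly equivalent to counting concordant pairs.
#'
#' @param scores Numeric score vector (e.g. a latent component).
#' @param labels Binary labels: logical, 0/1 numeric, or a two-level
#'   factor/character (the lexicographically larger level is "positive").
#'   Both classes must be present.
#' @param orientation If `TRUE`, returns `max(AUC, 1 - AUC)`: latent
#'   components have an arbitrary sign, so their discriminative value is
#'   direction-free.
#' @return A value in `[0, 1]`.
#' @examples
#' auc(c(3, 1, 2, 4), c(0, 0, 1, 1)) # 0.75
#' @export
auc <- function(scores, labels, orientation = FALSE) {
  stopifnot(length(scores) == length(labels))
  if (anyNA(scores) || anyNA(labels)) stop("missing values in scores or labels", call. = FALSE)
  pos <- as_binary_labels(labels)
  n1 <- sum(pos)
  n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute an AUC", call. = FALSE)
  }
  r <- rank(scores)
  a <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  if (orientation) max(a, 1 - a) else a
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels) && all(labels %in% c(0, 1))) return(labels == 1)
  u <- sort(unique(as.character(labels)))
  if (length(u) != 2) {
    stop("labels must have exactly two levels, got ", length(u), call. = FALSE)
  }
  as.character(labels) == u[2]
}

#' Evaluate a fitted component as a classifier of sample labels
#'
#' Extracts one block's latent component from a fit and scores how well it
#' separates sample labels by orientation-corrected AUC. Multi-level labels
#' are handled one-vs-rest with a macro average. External score vectors (e.g.
#' from another integration method) can be evaluated with [auc()] directly
#' for side-by-side tables.
#'
#' @param fit A `cca_fit`.
#' @param block Block name whose component is evaluated.
#' @param labels Per-sample labels (two or more levels).
#' @param component Component index (default 1).
#' @param method Label for the `method` column of the output.
#' @return A tibble with columns `method`, `block`, `component`, `label`,
#'   `auc`; one row per label level (one-vs-rest) plus a `"macro"` row when
#'   there are more than two levels.
#' @export
evaluate_fit <- function(fit, block, labels, component = 1, method = "sgcca") {
  stopifnot(inherits(fit, "cca_fit"))
  if (!block %in% names(fit$components)) {
    stop("unknown block '", block, "'; available: ",
         paste(names(fit$components), collapse = ", "), call. = FALSE)
  }
  comp <- fit$components[[block]]
  if (component > ncol(comp)) {
    stop("component ", component, " not available for block '", block,
         "' (fit has ", ncol(comp), ")", call. = FALSE)
  }
  scores <- comp[, component]
  if (length(labels) != length(scores)) {
    stop("labels length does not match sample count", call. = FALSE)
  }
  lv <- sort(unique(as.character(labels)))
  if (length(lv) < 2) stop("labels must have at least two levels", call. = FALSE)
  if (length(lv) == 2) {
    res <- tibble::tibble(label = lv[2],
                          auc = auc(scores, labels == lv[2], orientation = TRUE))
  } else {
    per <- vapply(lv, function(l) auc(scores, labels == l, orientation = TRUE),
                  numeric(1))
    res <- tibble::tibble(label = c(lv, "macro"),
                          auc = unname(c(per, mean(per))))
  }
  tibble::tibble(method = method, block = block, component = component,
                 label = res$label, auc = res$auc)
}
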