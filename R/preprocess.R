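#' Standardize a block for multiblock canonical correlation
#'
#' Centers every feature to mean zero, scales it to unit sample variance
#' (denominator `n - 1`), and then divides the whole block by the square root
#' of its number of features. After this transformation every column has
#' variance `1 / p`, so each block contributes total variance 1 to the joint
#' analysis regardless of how many features it carries. This is the block
#' standardization assumed by [fit_rgcca()] and [fit_sgcca()].
#'
#' @param x A numeric matrix or data frame, samples in rows and features in
#'   columns. Row names (sample identifiers) and column names (feature
#'   identifiers) are preserved.
#' @param drop_constant If `TRUE`, features with zero variance are removed
#'   with a warning instead of raising an error. Dropping changes the number
#'   of features and therefore the `1 / sqrt(p)` factor.
#' @return A numeric matrix of the same orientation. The attribute
#'   `block_kind` of the input (set by [encode_categorical()]) is preserved.
#' @examples
#' x <- matrix(c(0, 1, 2, 3), nrow = 2)
#' scale2(x) # each column becomes c(-0.5, 0.5)
#' @export
scale2 <- function(x, drop_constant = FALSE) {
  kind <- attr(x, "block_kind")
  x <- as_values_matrix(x)
  n <- nrow(x)
  if (n < 2) {
    stop("scale2() needs at least 2 samples, got ", n, call. = FALSE)
  }
  sds <- apply(x, 2, stats::sd)
  constant <- sds == 0 | !is.finite(sds)
  if (any(constant)) {
    bad <- colnames(x)[constant]
    if (drop_constant) {
      warning("dropping ", sum(constant), " constant feature(s): ",
              paste(utils::head(bad, 5), collapse = ", "),
              if (length(bad) > 5) ", ..." else "", call. = FALSE)
      x <- x[, !constant, drop = FALSE]
      sds <- sds[!constant]
      if (ncol(x) == 0) stop("all features were constant", call. = FALSE)
    } else {
      stop("constant feature(s) with zero variance: ",
           paste(utils::head(bad, 5), collapse = ", "),
           "; use drop_constant = TRUE to remove them", call. = FALSE)
    }
  }
  centers <- colMeans(x)
  out <- sweep(x, 2, centers, "-")
  out <- sweep(out, 2, sds, "/")
  out <- out / sqrt(ncol(out))
  if (!is.null(kind)) attr(out, "block_kind") <- kind
  out
}

#' Dummy-encode a categorical variable, omitting one level
#'
#' A factor with `k` observed levels becomes `k - 1` binary indicator columns
#' (1 = level present, 0 = absent). One reference level is omitted so the
#' encoding is full rank; by default the reference is the first level in
#' lexicographic order.
#'
#' @param x A character vector or factor. Missing values are an error:
#'   imputation is the caller's responsibility.
#' @param levels_order Optional explicit level ordering; the first element
#'   becomes the omitted reference level.
#' @param name Prefix for the generated column names (`name.level`); defaults
#'   to the deparsed argument.
#' @return An `n x (k - 1)` numeric 0/1 matrix with attribute
#'   `block_kind = "categorical-dummy"`, so that downstream fitting forces
#'   tau = 1 for blocks built from it. Every row sum is 0 or 1.
#' @examples
#' encode_categorical(c("colon", "ileum", "colon"))
#' @export
encode_categorical <- function(x, levels_order = NULL, name = NULL) {
  if (is.null(name)) name <- deparse(substitute(x))[1]
  if (anyNA(x)) {
    stop("missing values in categorical variable; impute or drop before encoding",
         call. = FALSE)
  }
  x <- as.character(x)
  lev <- if (is.null(levels_order)) sort(unique(x)) else levels_order
  if (!all(x %in% lev)) {
    stop("values not covered by levels_order: ",
         paste(setdiff(unique(x), lev), collapse = ", "), call. = FALSE)
  }
  if (length(unique(x)) < 2) {
    stop("categorical variable has a single observed level ('", x[1],
         "'); at least 2 are required", call. = FALSE)
  }
  keep <- lev[-1]
  out <- vapply(keep, function(l) as.numeric(x == l), numeric(length(x)))
  out <- matrix(out, nrow = length(x), ncol = length(keep),
                dimnames = list(names(x), paste(name, keep, sep = ".")))
  attr(out, "block_kind") <- "categorical-dummy"
  out
}

#' Remove the most variable features by coefficient of variation
#'
#' Ranks features by their coefficient of variation (sample sd divided by the
#' absolute mean) and removes the top fraction, a standard guard against
#' features whose apparent variance is dominated by noise or outliers.
#'
#' @param x Numeric matrix, samples by features.
#' @param top_fraction Fraction in `[0, 1)` of highest-CV features to remove;
#'   `ceiling(top_fraction * p)` features are dropped. Ties in CV are broken
#'   by feature name, ascending, so the survivor set is deterministic.
#' @return The matrix restricted to surviving features, original column order
#'   preserved.
#' @export
cv_filter <- function(x, top_fraction) {
  x <- as_values_matrix(x)
  stopifnot(length(top_fraction) == 1, top_fraction >= 0, top_fraction < 1)
  if (top_fraction == 0) return(x)
  m <- colMeans(x)
  if (any(m == 0)) {
    stop("feature(s) with zero mean (CV undefined): ",
         paste(utils::head(colnames(x)[m == 0], 5), collapse = ", "),
         "; shift or drop them before filtering", call. = FALSE)
  }
  cv <- apply(x, 2, stats::sd) / abs(m)
  n_drop <- ceiling(top_fraction * ncol(x))
  ord <- order(-cv, colnames(x))
  drop_idx <- ord[seq_len(n_drop)]
  x[, sort(setdiff(seq_len(ncol(x)), drop_idx)), drop = FALSE]
}

# Coerce data frames / tibbles (first column may be sample ids) to a numeric
# matrix with rownames. Internal.
as_values_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (ncol(x) >= 1 && (is.character(x[[1]]) || is.factor(x[[1]]))) {
      rn <- as.character(x[[1]])
      x <- x[, -1, drop = FALSE]
      x <- as.matrix(x)
      rownames(x) <- rn
    } else {
      x <- as.matrix(x)
    }
  }
  if (!is.numeric(x)) stop("block values must be numeric", call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x))) {
    stop("duplicated feature identifiers in block", call. = FALSE)
  }
  if (!is.null(rownames(x)) && anyDuplicated(rownames(x))) {
    stop("duplicated sample identifiers in block", call. = FALSE)
  }
  if (anyNA(x)) {
    stop("missing values are not supported; impute or drop before analysis",
         call. = FALSE)
  }
  x
}
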