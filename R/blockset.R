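#' Assemble standardized blocks into an aligned block set
#'
#' A block set is the unit of analysis for all fitting functions: a named list
#' of sample-by-feature matrices sharing the same samples in the same order.
#' Blocks are aligned by row names; blocks without row names are assumed to be
#' already aligned and must have equal row counts.
#'
#' @param blocks Named list of numeric matrices (typically output of
#'   [scale2()]). Alternatively pass matrices as `...` to [blockset()].
#' @param sample_ids Optional character vector giving the common sample order;
#'   defaults to the first block's row order.
#' @param kind Optional named character vector overriding the per-block kind
#'   (`"quantitative"` or `"categorical-dummy"`); by default taken from the
#'   `block_kind` attribute left by [encode_categorical()].
#' @return An object of class `blockset`: a list with elements `blocks`,
#'   `kind`, `n`, `p` (named feature counts) and `superblock` (name of the
#'   superblock, if [add_superblock()] was used).
#' @seealso [blockset()] for the `...` form, [add_superblock()]
#' @export
assemble_blockset <- function(blocks, sample_ids = NULL, kind = NULL) {
  if (is.null(names(blocks)) || any(names(blocks) == "")) {
    stop("all blocks must be named", call. = FALSE)
  }
  if (anyDuplicated(names(blocks))) stop("block names must be unique", call. = FALSE)
  kinds <- vapply(blocks, function(b) {
    k <- attr(b, "block_kind")
    if (is.null(k)) "quantitative" else k
  }, character(1))
  if (!is.null(kind)) kinds[names(kind)] <- kind
  blocks <- lapply(blocks, as_values_matrix)

  has_ids <- vapply(blocks, function(b) !is.null(rownames(b)), logical(1))
  if (all(has_ids)) {
    ids <- if (is.null(sample_ids)) rownames(blocks[[1]]) else sample_ids
    for (nm in names(blocks)) {
      missing_ids <- setdiff(ids, rownames(blocks[[nm]]))
      extra_ids <- setdiff(rownames(blocks[[nm]]), ids)
      if (length(missing_ids) || length(extra_ids)) {
        stop("sample mismatch in block '", nm, "': missing {",
             paste(missing_ids, collapse = ", "), "}, extra {",
             paste(extra_ids, collapse = ", "), "}", call. = FALSE)
      }
      blocks[[nm]] <- blocks[[nm]][ids, , drop = FALSE]
    }
  } else {
    ns <- vapply(blocks, nrow, integer(1))
    if (length(unique(ns)) != 1) {
      stop("blocks without sample ids must have equal row counts; got ",
           paste(ns, collapse = ", "), call. = FALSE)
    }
  }
  structure(
    list(blocks = blocks,
         kind = kinds,
         n = nrow(blocks[[1]]),
         p = vapply(blocks, ncol, integer(1)),
         superblock = NULL),
    class = "blockset"
  )
}

#' @rdname assemble_blockset
#' @param ... Named matrices, e.g. `blockset(rna = scale2(x), otu = scale2(y))`.
#' @export
blockset <- function(..., sample_ids = NULL, kind = NULL) {
  assemble_blockset(list(...), sample_ids = sample_ids, kind = kind)
}

as_blockset <- function(x) {
  if (inherits(x, "blockset")) return(x)
  if (is.list(x)) return(assemble_blockset(x))
  stop("expected a blockset or a named list of matrices", call. = FALSE)
}

#' @export
print.blockset <- function(x, ...) {
  cat("<blockset> ", length(x$blocks), " blocks, ", x$n, " samples\n", sep = "")
  for (nm in names(x$blocks)) {
    cat("  ", format(nm, width = max(nchar(names(x$blocks)))), " ",
        x$p[[nm]], " features (", x$kind[[nm]], ")",
        if (identical(x$superblock, nm)) " [superblock]" else "", "\n", sep = "")
  }
  invisible(x)
}

# Subset samples (rows) of every block jointly; no re-standardization here.
# Row names are dropped: resampling with replacement duplicates sample ids,
# and linkage is positional from here on.
blockset_rows <- function(bs, idx) {
  bs$blocks <- lapply(bs$blocks, function(b) {
    b <- b[idx, , drop = FALSE]
    rownames(b) <- NULL
    b
  })
  bs$n <- length(idx)
  bs
}
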