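#' Build and validate a block-interaction design matrix
#'
#' The design (the "model") is a symmetric J x J matrix of weights
#' `c_jk` in `[0, 1]`: `c_jk > 0` declares an interaction between blocks j and
#' k, with larger weights counting more both in the fitting objective and in
#' the inner AVE. Diagonal entries encode within-block interaction
#' (e.g. gene-gene interaction inside a transcriptome block).
#'
#' @param C Square numeric matrix of weights in `[0, 1]`.
#' @param block_names Optional names for rows/columns.
#' @return The validated matrix with dimnames set.
#' @export
design_matrix <- function(C, block_names = NULL) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("design must be square", call. = FALSE)
  if (any(C < 0 | C > 1)) stop("design weights must lie in [0, 1]", call. = FALSE)
  if (max(abs(C - t(C))) > 1e-12) stop("design must be symmetric", call. = FALSE)
  if (!is.null(block_names)) dimnames(C) <- list(block_names, block_names)
  C
}

#' Is a design a single connected network?
#'
#' Blocks are the nodes; every strictly positive off-diagonal weight is an
#' edge (diagonal self-edges are ignored). Only connected designs are
#' meaningful models: a disconnected design splits the analysis into
#' independent subproblems.
#'
#' @param design Symmetric weight matrix.
#' @return `TRUE` if the interaction graph is connected (trivially so for a
#'   single block).
#' @export
is_connected <- function(design) {
  J <- nrow(design)
  if (J == 1) return(TRUE)
  A <- (design > 0) * 1
  diag(A) <- 0
  g <- igraph::graph_from_adjacency_matrix(A, mode = "undirected")
  igraph::is_connected(g)
}

#' Declare the model space to search over
#'
#' A template fixes some design entries and leaves others free to vary over a
#' weight grid. [enumerate_designs()] expands the template into concrete
#' candidate designs; [search_models()] fits and ranks them.
#'
#' @param block_names Character vector of block names (J >= 2), or a
#'   `blockset` whose names are used.
#' @param fixed Optional J x J matrix of fixed weights used for entries that
#'   are not free (default all zero). May also be a named list
#'   `list("a|b" = w)` of individual fixed entries.
#' @param free Either the string `"offdiag"` (all off-diagonal entries free,
#'   the default), `"all"` (including the diagonal), a J x J logical matrix,
#'   or a character vector of edges like `"rna|otu"` (use `"rna|rna"` for a
#'   diagonal entry).
#' @param grid Ordered numeric vector of allowed weights for free entries;
#'   defaults to the coarse grid `c(0, 0.5, 1)`.
#' @param diagonal If `TRUE` and `free = "offdiag"`, diagonal entries are
#'   also freed. Shorthand for `free = "all"`.
#' @return An object of class `model_template`.
#' @export
model_template <- function(block_names, fixed = NULL, free = "offdiag",
                           grid = c(0, 0.5, 1), diagonal = FALSE) {
  if (inherits(block_names, "blockset")) block_names <- names(block_names$blocks)
  J <- length(block_names)
  if (J < 1) stop("need at least one block", call. = FALSE)
  if (is.character(free) && length(free) == 1 && free %in% c("offdiag", "all")) {
    fm <- matrix(TRUE, J, J)
    if (free == "offdiag" && !diagonal) diag(fm) <- FALSE
  } else if (is.matrix(free)) {
    fm <- free
    stopifnot(is.logical(fm), nrow(fm) == J, ncol(fm) == J)
    if (any(fm != t(fm))) stop("free mask must be symmetric", call. = FALSE)
  } else {
    fm <- matrix(FALSE, J, J, dimnames = list(block_names, block_names))
    for (e in free) {
      ab <- strsplit(e, "|", fixed = TRUE)[[1]]
      if (length(ab) != 2 || !all(ab %in% block_names)) {
        stop("unknown edge '", e, "'; use 'block1|block2'", call. = FALSE)
      }
      fm[ab[1], ab[2]] <- fm[ab[2], ab[1]] <- TRUE
    }
  }
  dimnames(fm) <- list(block_names, block_names)
  if (is.null(fixed)) {
    fx <- matrix(0, J, J, dimnames = dimnames(fm))
  } else if (is.list(fixed)) {
    fx <- matrix(0, J, J, dimnames = dimnames(fm))
    for (e in names(fixed)) {
      ab <- strsplit(e, "|", fixed = TRUE)[[1]]
      fx[ab[1], ab[2]] <- fx[ab[2], ab[1]] <- fixed[[e]]
    }
  } else {
    fx <- design_matrix(fixed, block_names)
  }
  if (any(fx < 0 | fx > 1)) stop("fixed weights must lie in [0, 1]", call. = FALSE)
  stopifnot(is.numeric(grid), all(grid >= 0 & grid <= 1))
  structure(
    list(block_names = block_names, free = fm, fixed = fx,
         grid = sort(unique(grid))),
    class = "model_template"
  )
}

#' @export
print.model_template <- function(x, ...) {
  nf <- sum(x$free[upper.tri(x$free, diag = TRUE)])
  cat("<model_template> ", length(x$block_names), " blocks, ", nf,
      " free edge(s), grid {", paste(x$grid, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

# Symmetric upper-triangle (incl. diagonal) positions of free entries.
free_edges <- function(template) {
  fm <- template$free
  idx <- which(upper.tri(fm, diag = TRUE) & fm, arr.ind = TRUE)
  idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
}

edge_labels <- function(template) {
  idx <- free_edges(template)
  bn <- template$block_names
  paste0(bn[idx[, 1]], "|", bn[idx[, 2]])
}

#' Enumerate candidate designs from a template
#'
#' Expands the Cartesian product of the weight grid over the template's free
#' edges, symmetrizes, fills fixed entries, and removes designs whose
#' interaction graph is not a single connected network. Connectivity depends
#' only on the zero pattern of the weights, never on their magnitude.
#'
#' @param template A [model_template()].
#' @param grids Optional list of per-edge grids (same order as the template's
#'   free edges, or named by edge label `"a|b"`), overriding the common grid.
#' @param cap Maximum number of grid combinations allowed before erroring
#'   (guards against combinatorial explosion).
#' @return A list of design matrices, with attributes `n_enumerated` (all
#'   grid combinations) and `n_filtered_disconnected` (combinations removed
#'   by the connectivity filter), plus `edge_labels` and `weights` (a matrix
#'   of the surviving free-edge weight vectors).
#' @export
enumerate_designs <- function(template, grids = NULL, cap = 1e6) {
  stopifnot(inherits(template, "model_template"))
  idx <- free_edges(template)
  labs <- edge_labels(template)
  ne <- nrow(idx)
  if (is.null(grids)) {
    grids <- rep(list(template$grid), ne)
  } else if (!is.null(names(grids))) {
    grids <- grids[labs]
  }
  stopifnot(length(grids) == ne)
  n_comb <- prod(vapply(grids, length, numeric(1)))
  if (n_comb > cap) {
    stop("grid expansion would produce ", format(n_comb, big.mark = ","),
         " designs (cap ", format(cap, big.mark = ","),
         "); coarsen the grid or fix more edges", call. = FALSE)
  }
  combos <- as.matrix(do.call(expand.grid, c(grids, KEEP.OUT.ATTRS = FALSE)))
  colnames(combos) <- labs
  base <- template$fixed
  base[template$free] <- 0
  designs <- vector("list", nrow(combos))
  keep <- logical(nrow(combos))
  for (i in seq_len(nrow(combos))) {
    C <- base
    for (e in seq_len(ne)) {
      C[idx[e, 1], idx[e, 2]] <- combos[i, e]
      C[idx[e, 2], idx[e, 1]] <- combos[i, e]
    }
    keep[i] <- is_connected(C)
    designs[[i]] <- C
  }
  out <- designs[keep]
  attr(out, "n_enumerated") <- nrow(combos)
  attr(out, "n_filtered_disconnected") <- sum(!keep)
  attr(out, "edge_labels") <- labs
  attr(out, "weights") <- combos[keep, , drop = FALSE]
  out
}

#' Append a superblock to a block set
#'
#' The superblock is the column-concatenation of every existing
#' (standardized) block, connected to each individual block; it supports a
#' hierarchical reading of the model in which each block relates to the whole
#' system. Its columns are bitwise-identical copies of the source columns.
#' The superblock is flagged so that [ave_outer()] can exclude its features
#' from the size-weighted total (they would otherwise be double counted).
#'
#' @param blocks A `blockset` with at least 2 blocks.
#' @param template Optional [model_template()] to extend with free edges
#'   between the superblock and every block.
#' @param grid Grid for the new superblock edges when `template` is given.
#' @return If `template` is `NULL`, the extended `blockset`; otherwise a list
#'   `list(blocks =, template =)`.
#' @export
add_superblock <- function(blocks, template = NULL, grid = c(0, 0.5, 1)) {
  blocks <- as_blockset(blocks)
  if (length(blocks$blocks) < 2) stop("need >= 2 blocks", call. = FALSE)
  if (!is.null(blocks$superblock)) stop("blockset already has a superblock", call. = FALSE)
  sb <- do.call(cbind, unname(blocks$blocks))
  colnames(sb) <- unlist(lapply(names(blocks$blocks), function(nm) {
    paste(nm, colnames(blocks$blocks[[nm]]), sep = ".")
  }), use.names = FALSE)
  blocks$blocks$superblock <- sb
  blocks$kind["superblock"] <- "quantitative"
  blocks$p <- vapply(blocks$blocks, ncol, integer(1))
  blocks$superblock <- "superblock"
  if (is.null(template)) return(blocks)
  bn <- c(template$block_names, "superblock")
  J <- length(bn)
  fm <- matrix(FALSE, J, J, dimnames = list(bn, bn))
  fm[seq_len(J - 1), seq_len(J - 1)] <- template$free
  fm[J, seq_len(J - 1)] <- fm[seq_len(J - 1), J] <- TRUE
  fx <- matrix(0, J, J, dimnames = list(bn, bn))
  fx[seq_len(J - 1), seq_len(J - 1)] <- template$fixed
  tpl <- model_template(bn, fixed = fx, free = fm,
                        grid = sort(unique(c(template$grid, grid))))
  list(blocks = blocks, template = tpl)
}
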