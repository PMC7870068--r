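#' Read a sample-by-feature matrix from delimited text
#'
#' Expects a header of feature identifiers and a first column of sample
#' identifiers (TSV by default; comma-delimited files are detected from the
#' `.csv` extension). Use `transpose = TRUE` for features-in-rows files.
#'
#' @param path File path.
#' @param transpose If `TRUE`, the file is features x samples and is
#'   transposed after reading.
#' @return Numeric matrix with sample row names.
#' @export
read_block_matrix <- function(path, transpose = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  m <- as_values_matrix(as.data.frame(df))
  if (transpose) m <- t(m)
  m
}

#' Read a sample metadata table
#'
#' One row per sample; the first column is taken as the sample identifier.
#'
#' @param path File path (TSV, or CSV by extension).
#' @return A tibble whose first column is named `sample_id`.
#' @export
read_metadata <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  delim <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  names(df)[1] <- "sample_id"
  df
}

#' Write a matrix as TSV with a sample-id first column
#'
#' @param x Matrix with row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_block_matrix <- function(x, path) {
  df <- tibble::as_tibble(x, rownames = "sample_id")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Read and validate a pipeline configuration
#'
#' The YAML configuration declares blocks (file, orientation, kind, tau
#' policy, sparsity), optional metadata covariate blocks, the model template
#' (fixed weights, free edges, grid, diagonal), scheme, component count,
#' bootstrap size and seed. Validation runs before any computation and
#' reports every problem found.
#'
#' @param path Path to a YAML file, or an already-parsed list.
#' @return The validated configuration list, with defaults filled in and an
#'   attribute `config_hash` (MD5 of the file, when read from disk).
#' @export
read_run_config <- function(path) {
  if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
    config <- yaml::read_yaml(path)
    attr(config, "config_hash") <- unname(tools::md5sum(path))
  } else {
    config <- path
  }
  problems <- character()
  note <- function(msg) problems <<- c(problems, msg)

  if (is.null(config$blocks) || !length(config$blocks)) {
    note("'blocks' must list at least one block")
  } else {
    nms <- vapply(config$blocks, function(b) b$name %||% "", character(1))
    if (any(nms == "")) note("every block needs a 'name'")
    if (anyDuplicated(nms)) note("block names must be unique")
    for (b in config$blocks) {
      if (is.null(b$file)) {
        note(paste0("block '", b$name, "' needs a 'file'"))
      } else if (!file.exists(b$file)) {
        note(paste0("block file not found: ", b$file))
      }
      if (!is.null(b$kind) &&
          !b$kind %in% c("quantitative", "categorical-dummy")) {
        note(paste0("block '", b$name, "': unknown kind '", b$kind, "'"))
      }
    }
  }
  if (!is.null(config$metadata)) {
    if (is.null(config$metadata$file)) {
      note("'metadata' needs a 'file'")
    } else if (!file.exists(config$metadata$file)) {
      note(paste0("metadata file not found: ", config$metadata$file))
    }
  }
  config$scheme <- config$scheme %||% "centroid"
  if (!config$scheme %in% c("horst", "centroid", "factorial")) {
    note(paste0("unknown scheme '", config$scheme, "'"))
  }
  config$ncomp <- config$ncomp %||% 1L
  config$seed <- config$seed %||% 1L
  config$template <- config$template %||% list()
  config$template$grid <- config$template$grid %||% c(0, 0.5, 1)
  config$template$diagonal <- isTRUE(config$template$diagonal)
  config$bootstrap <- config$bootstrap %||% list(B = 0)
  config$bootstrap$B <- config$bootstrap$B %||% 0
  if (length(problems)) {
    stop("invalid configuration:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  }
  config
}

`%||%` <- function(a, b) if (is.null(a)) b else a
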