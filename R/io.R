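#' Read an expression matrix from TSV/CSV
#'
#' Expects a header row of sample ids and a first column of feature ids
#' (set `transpose = TRUE` for samples in rows). The separator is inferred
#' from the file extension (`.csv` = comma, otherwise tab). Non-numeric or
#' missing cells and duplicated ids are rejected with their coordinates.
#'
#' @param path Path to the file.
#' @param transpose Input has samples in rows (default FALSE).
#' @return Numeric feature-by-sample matrix with dimnames.
#' @export
read_expression <- function(path, transpose = FALSE) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.table(path, header = TRUE, sep = sep, row.names = NULL,
                   check.names = FALSE, stringsAsFactors = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicated row ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)])[1:3], collapse = ", "))
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(array(as.numeric(m), dim(m)))) &
                   !is.na(m), arr.ind = TRUE)
    if (nrow(bad))
      stop("non-numeric cell at row '", ids[bad[1L, 1L]], "', column '",
           colnames(m)[bad[1L, 2L]], "' in ", path)
    storage.mode(m) <- "numeric"
  }
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)
    stop("missing value at row '", ids[bad[1L, 1L]], "', column '",
         colnames(m)[bad[1L, 2L]], "' in ", path)
  }
  rownames(m) <- ids
  if (transpose) m <- t(m)
  as_expression_matrix(m)
}

#' Write an expression matrix as TSV
#'
#' Feature-by-sample layout with an `id` header column, the inverse of
#' [read_expression()].
#'
#' @param x Feature-by-sample matrix.
#' @param path Output path.
#' @export
write_expression <- function(x, path) {
  df <- data.frame(id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write clustering results to files
#'
#' Writes `<prefix>_labels.tsv` (sample id, cluster), a diagnostics table
#' `<prefix>_diagnostics.tsv` (candidate K with eigengap or dip drop), a
#' config snapshot `<prefix>_config.yml` sufficient to reproduce the run,
#' and optionally the fused similarity matrix.
#'
#' @param fit A `spectral_cluster` fit.
#' @param prefix Output path prefix.
#' @param similarity Also write the fused similarity matrix (default
#'   FALSE; quadratic in sample number).
#' @return Invisibly, the paths written.
#' @export
write_clustering <- function(fit, prefix, similarity = FALSE) {
  stopifnot(inherits(fit, "spectral_cluster"))
  paths <- character()
  p <- paste0(prefix, "_labels.tsv")
  write.table(data.frame(sample_id = names(fit$labels), cluster = fit$labels),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_diagnostics.tsv")
  write.table(fit$diagnostics, p, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, p)
  p <- paste0(prefix, "_config.yml")
  cfg <- fit$params
  writeLines(paste0(names(cfg), ": ", vapply(cfg, format, character(1L))), p)
  paths <- c(paths, p)
  if (similarity) {
    p <- paste0(prefix, "_similarity.tsv")
    write_expression(fit$similarity, p)
    paths <- c(paths, p)
  }
  invisible(paths)
}

#' Write simulated data and truth labels as TSV
#'
#' One matrix file per view plus a `truth.tsv` with the generating labels.
#'
#' @param sim A `cluster_sim` object.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "cluster_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  for (i in seq_along(sim$views)) {
    nm <- if (!is.null(names(sim$views)) && nzchar(names(sim$views)[i]))
      names(sim$views)[i] else paste0("view", i)
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_expression(sim$views[[i]], p)
    paths <- c(paths, p)
  }
  p <- file.path(dir, "truth.tsv")
  write.table(data.frame(sample_id = names(sim$labels),
                         cluster = sim$labels),
              p, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, p))
}

#' Read a labels TSV (sample_id, cluster)
#'
#' @param path Path to a two-column TSV as written by [write_clustering()].
#' @return Named vector of labels.
#' @export
read_labels <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  labs <- df[[2L]]
  names(labs) <- as.character(df[[1L]])
  labs
}
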