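#' Compress samples to k-means centroids (FASP)
#'
#' Fast approximate spectral clustering: because spectral clustering scales
#' cubically in the number of samples while k-means scales linearly, large
#' datasets are first compressed to m centroids by k-means; the spectral
#' pipeline then runs on the centroids only and labels are propagated back
#' with [fasp_expand()].
#'
#' @param views List of feature-by-sample matrices over a common sample set
#'   (a single matrix is also accepted). Samples are compressed jointly
#'   across views so each centroid represents the same samples in every
#'   view.
#' @param m Number of centroids (must be smaller than the number of
#'   samples; default 900).
#' @param seed Integer seed for the k-means restarts.
#' @return List with \code{views} (per-view feature-by-centroid matrices),
#'   \code{assignment} (named integer vector mapping sample to centroid)
#'   and \code{m}.
#' @export
fasp_compress <- function(views, m = 900L, seed = 1L) {
  if (!is.list(views)) views <- list(views)
  views <- lapply(views, as_expression_matrix)
  n <- ncol(views[[1L]])
  if (m >= n) stop("m must be smaller than the number of samples (", n, ")")
  stacked <- t(do.call(rbind, views))    # samples x all features
  km <- NULL
  for (attempt in 0:4) {                 # re-seed on rare degenerate starts
    set.seed(seed + attempt)
    km <- tryCatch(suppressWarnings(kmeans(stacked, centers = m,
                                           nstart = 10L, iter.max = 100L)),
                   error = function(e) NULL)
    if (!is.null(km) && all(km$size > 0)) break
  }
  if (is.null(km)) stop("k-means compression failed")
  ids <- paste0("c", seq_len(m))
  offsets <- c(0L, cumsum(vapply(views, nrow, integer(1L))))
  cviews <- lapply(seq_along(views), function(v) {
    rows <- (offsets[v] + 1L):offsets[v + 1L]
    cm <- t(km$centers[, rows, drop = FALSE])
    rownames(cm) <- rownames(views[[v]])
    colnames(cm) <- ids
    cm
  })
  names(cviews) <- names(views)
  assignment <- km$cluster
  names(assignment) <- colnames(views[[1L]])
  list(views = cviews, assignment = assignment, m = m)
}

#' Propagate centroid labels back to samples
#'
#' @param centroid_labels Integer vector of cluster labels, one per
#'   centroid.
#' @param compression Result of [fasp_compress()].
#' @return Named integer vector of per-sample cluster labels.
#' @export
fasp_expand <- function(centroid_labels, compression) {
  if (anyNA(centroid_labels) || length(centroid_labels) < compression$m)
    stop("every centroid must be labelled")
  labs <- centroid_labels[compression$assignment]
  names(labs) <- names(compression$assignment)
  labs
}
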