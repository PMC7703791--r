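#' Eigengap selection of the number of clusters
#'
#' Chooses K as the position of the largest gap between consecutive
#' eigenvalues of the normalised graph Laplacian,
#' \deqn{k^* = \arg\max_{n = 2..maxK} (\lambda_n - \lambda_{n+1}),}
#' the classical heuristic for near-block-diagonal affinity graphs. Ties go
#' to the smaller candidate.
#'
#' @param values Eigenvalues sorted in descending order (at least maxK + 1).
#' @param max_k Largest K considered (default 10).
#' @return List with \code{k} and a \code{diagnostics} data frame of
#'   candidate K and eigengap.
#' @export
eigengap_k <- function(values, max_k = 10L) {
  if (length(values) < max_k + 1L)
    stop("need at least max_k + 1 eigenvalues (max_k = ", max_k, ")")
  cand <- 2:max_k
  gaps <- values[cand] - values[cand + 1L]
  k <- cand[which.max(gaps)]
  list(k = k, diagnostics = data.frame(k = cand, eigengap = gaps))
}

#' Hartigan dip statistic
#'
#' Departure of a sample's distribution from unimodality: the smallest
#' sup-norm distance between the empirical CDF and any unimodal CDF,
#' computed with the iterative greatest-convex-minorant /
#' least-concave-majorant algorithm. Values lie in (0, 0.25], are invariant
#' under affine transformations of the data, and grow with the strength of
#' multimodality (0.25 is attained by two equal point masses).
#'
#' @param x Numeric vector (length at least 4 for a meaningful value).
#' @return The dip statistic. A constant vector returns 0 with a warning.
#' @export
dip_stat <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("missing values in x")
  if (length(x) < 4L) warning("dip statistic of fewer than 4 points")
  if (length(unique(x)) == 1L) {
    warning("constant sample: dip is 0 in the limit")
    return(0)
  }
  dip_stat_cpp(x)
}

#' Dip statistics of successive eigenvectors and their differences
#'
#' Computes the dip statistic z_j for each of the leading maxK + 1
#' eigenvectors (ordered by descending eigenvalue) and the consecutive
#' differences d_j = z_{j+1} - z_j. Informative eigenvectors are multimodal
#' (high dip); d_j is therefore the drop in multimodality between
#' eigenvectors j and j + 1, and a chosen drop at position j corresponds to
#' K = j clusters.
#'
#' @param es Eigen system from [laplacian_eigen()].
#' @param max_k Largest K considered.
#' @return List with \code{z} (length maxK + 1) and \code{d} (length maxK).
#' @export
dip_series <- function(es, max_k = 10L) {
  v <- es$vectors
  if (ncol(v) < max_k + 1L)
    stop("need at least max_k + 1 eigenvectors (max_k = ", max_k, ")")
  z <- vapply(seq_len(max_k + 1L), function(j) dip_stat_cpp(v[, j]),
              numeric(1L))
  list(z = z, d = diff(z))
}

#' Last substantial drop in eigenvector multimodality
#'
#' Scans the consecutive dip differences for the last drop that is
#' substantially (at least f-fold) deeper than the deepest drop stored so
#' far, looking at most cmax positions beyond it. The first difference is
#' skipped: the change from the first to the second eigenvector is
#' uninformative because the leading eigenvector is near-constant. This
#' guards the simple arg-min rule against shallow local minima early in the
#' series.
#'
#' @param d Numeric vector of consecutive dip differences (d_j is the drop
#'   between eigenvectors j and j + 1; chosen position j gives K = j).
#' @param cmax Look-ahead window before the search stops (default 7).
#' @param f Replacement factor: a later drop replaces the stored one when it
#'   is at least f-fold more negative (default 2).
#' @return List with \code{k} and a \code{diagnostics} data frame of
#'   candidate K and drop.
#' @export
last_substantial_drop <- function(d, cmax = 7L, f = 2) {
  if (length(d) < 2L) stop("need at least 2 differences")
  idx <- 2L
  dmin <- d[2L]
  if (length(d) >= 3L) {
    for (j in 3:length(d)) {
      if (j - idx > cmax) break
      if (dmin * f > d[j]) {
        dmin <- d[j]
        idx <- j
      }
    }
  }
  if (dmin >= 0) {
    warning("no drop in multimodality found; defaulting to K = 2")
    idx <- 2L
  }
  list(k = idx, diagnostics = data.frame(k = seq_along(d), drop = d))
}

#' Tune the kernel neighbour parameter by the multimodality gap
#'
#' Rebuilds the fused graph for each candidate local-scale parameter P,
#' computes the dip-statistic differences of the Laplacian eigenvectors and
#' records the deepest drop min(D^P). The selected P is the one with the
#' most negative deepest drop, i.e. the kernel whose eigenvectors show the
#' sharpest transition from multimodal to unimodal. Ties go to the smaller
#' P.
#'
#' @param dists List of per-view distance matrices.
#' @param p_grid Candidate values of P (default 1:10).
#' @param s Common-nearest-neighbour set size (held fixed, default 7).
#' @param z,iters,diffuse Graph fusion settings (see [knn_sparsify()],
#'   [diffuse_graph()]); diffusion before the dip analysis defaults to on.
#' @param max_k Largest K considered.
#' @return List with the selected \code{p}, and \code{diagnostics} data
#'   frame with min(D^P) per candidate.
#' @export
tune_kernel_p <- function(dists, p_grid = 1:10, s = 7L, z = 10L,
                          iters = 5L, diffuse = TRUE, max_k = 10L) {
  stats <- vapply(p_grid, function(p) {
    a <- build_fused_graph(dists, p = p, s = s, z = z, iters = iters,
                           diffuse = diffuse)
    es <- laplacian_eigen(graph_laplacian(a))
    min(dip_series(es, max_k)$d)
  }, numeric(1L))
  list(p = p_grid[which.min(stats)],
       diagnostics = data.frame(p = p_grid, min_drop = stats))
}
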