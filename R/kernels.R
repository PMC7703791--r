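#' Euclidean distances between samples
#'
#' Computes the Euclidean distance between all pairs of samples (columns) of
#' an expression matrix. No centring or scaling is applied; the matrix is
#' used as given, so any standardisation is the caller's choice.
#'
#' @param x Numeric matrix, features in rows and samples in columns. Column
#'   names identify samples.
#' @return A symmetric N x N matrix of distances with zero diagonal.
#' @examples
#' x <- matrix(c(0, 0, 3, 4), nrow = 2, dimnames = list(NULL, c("a", "b")))
#' pairwise_dist(x)["a", "b"]  # 5
#' @export
pairwise_dist <- function(x) {
  x <- as_expression_matrix(x)
  d <- as.matrix(dist(t(x)))
  dimnames(d) <- list(colnames(x), colnames(x))
  d
}

# validate a features x samples matrix, naming offenders on failure
as_expression_matrix <- function(x) {
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("expression matrix must be numeric")
  if (ncol(x) < 3L) stop("need at least 3 samples, got ", ncol(x))
  if (is.null(colnames(x))) colnames(x) <- paste0("s", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x)))
    stop("duplicated sample ids: ",
         paste(unique(colnames(x)[duplicated(colnames(x))]), collapse = ", "))
  if (anyNA(x)) {
    idx <- which(is.na(x), arr.ind = TRUE)[1L, ]
    rn <- if (is.null(rownames(x))) idx[1L] else rownames(x)[idx[1L]]
    stop("missing value at feature '", rn, "', sample '",
         colnames(x)[idx[2L]], "'")
  }
  x
}

#' Local scale of each sample
#'
#' The local scale sigma_i of sample i is its distance to its P-th nearest
#' neighbour (self excluded), the self-tuning bandwidth of Zelnik-Manor
#' kernels. If that distance is zero (duplicated points) the smallest
#' strictly positive neighbour distance is used instead, and if all
#' neighbour distances are zero, sigma_i = 1.
#'
#' @param d Symmetric distance matrix.
#' @param p Neighbour index (positive integer, at most N - 1).
#' @return Numeric vector of N positive scales.
#' @export
local_scale <- function(d, p = 3L) {
  n <- nrow(d)
  if (p < 1L || p > n - 1L)
    stop("p must be between 1 and N-1 (N = ", n, ")")
  vapply(seq_len(n), function(i) {
    di <- d[i, -i]
    # ties broken by ascending sample index (order() is stable)
    ds <- di[order(di, seq_along(di))]
    s <- ds[p]
    if (s <= 0) {
      pos <- ds[ds > 0]
      s <- if (length(pos)) pos[1L] else 1
    }
    s
  }, numeric(1L))
}

#' Common-nearest-neighbour counts
#'
#' For every pair of samples, the number of points shared by their
#' S-nearest-neighbour sets (self excluded from each set). Pairs lying in a
#' dense shared neighbourhood obtain high counts.
#'
#' @param d Symmetric distance matrix.
#' @param s Neighbourhood size (positive integer, at most N - 1).
#' @return Symmetric integer N x N matrix with entries in 0..S.
#' @export
cnn_counts <- function(d, s = 7L) {
  n <- nrow(d)
  if (s < 1L || s > n - 1L)
    stop("s must be between 1 and N-1 (N = ", n, ")")
  nn <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    di <- d[i, ]
    di[i] <- Inf
    nn[i, order(di, seq_len(n))[seq_len(s)]] <- TRUE
  }
  cnt <- tcrossprod(nn * 1)
  storage.mode(cnt) <- "integer"
  dimnames(cnt) <- dimnames(d)
  cnt
}

#' Adaptive density-aware similarity kernel
#'
#' Similarity between samples i and j is
#' \deqn{A_{ij} = \exp\left(\frac{-d^2(s_i, s_j)}{\sigma_i \sigma_j
#'   (CNN(s_i, s_j) + 1)}\right)}
#' where sigma_i is the local scale (distance to the P-th nearest
#' neighbour) and CNN counts common members of the two samples'
#' S-nearest-neighbour sets. Shared neighbourhoods therefore inflate the
#' bandwidth and strengthen within-cluster similarity; with no shared
#' neighbours the kernel reduces exactly to the Zelnik-Manor kernel.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param p Local-scale neighbour index (default 3).
#' @param s Neighbourhood size for the common-neighbour count (default 7).
#' @return Symmetric similarity matrix with unit diagonal, entries in (0, 1].
#' @seealso [zm_kernel()] for the non-density-aware form.
#' @export
adaptive_kernel <- function(d, p = 3L, s = 7L) {
  sig <- local_scale(d, p)
  cnn <- cnn_counts(d, s)
  a <- exp(-(d * d) / (outer(sig, sig) * (cnn + 1)))
  if (!all(is.finite(a))) stop("non-finite kernel entries")
  diag(a) <- 1
  dimnames(a) <- dimnames(d)
  a
}

#' Zelnik-Manor self-tuning kernel
#'
#' \deqn{A_{ij} = \exp\left(-d^2(s_i, s_j) / (\sigma_i \sigma_j)\right)}
#' with per-sample bandwidths sigma_i equal to the distance to the P-th
#' nearest neighbour. Adapts to scale but not to local density.
#'
#' @inheritParams adaptive_kernel
#' @return Symmetric similarity matrix with unit diagonal, entries in (0, 1].
#' @export
zm_kernel <- function(d, p = 3L) {
  sig <- local_scale(d, p)
  a <- exp(-(d * d) / outer(sig, sig))
  if (!all(is.finite(a))) stop("non-finite kernel entries")
  diag(a) <- 1
  dimnames(a) <- dimnames(d)
  a
}
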