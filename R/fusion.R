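#' Combine per-view similarity graphs
#'
#' Element-wise sum of the per-view similarity matrices over a common sample
#' set, the unweighted linear combination used before sparsification and
#' diffusion. A single graph is returned unchanged.
#'
#' @param graphs List of square similarity matrices with identical sample
#'   ids in identical order.
#' @return A single combined similarity matrix.
#' @export
combine_graphs <- function(graphs) {
  if (!is.list(graphs)) graphs <- list(graphs)
  if (!length(graphs)) stop("no graphs supplied")
  ids <- colnames(graphs[[1L]])
  for (g in graphs[-1L]) {
    if (!identical(colnames(g), ids)) {
      bad <- union(setdiff(colnames(g), ids), setdiff(ids, colnames(g)))
      stop("sample ids differ between views: ",
           paste(utils::head(bad, 5L), collapse = ", "))
    }
  }
  Reduce(`+`, graphs)
}

#' Sparsify a similarity graph to k nearest neighbours
#'
#' Keeps, per row, the Z largest off-diagonal similarities together with the
#' diagonal, zeroing everything else. The result is a kNN graph and is in
#' general asymmetric. Retaining the diagonal guarantees strictly positive
#' row sums for the subsequent row normalisation.
#'
#' @param a Square similarity matrix.
#' @param z Number of neighbours to retain per row (at most N - 1).
#' @return Sparsified matrix of the same dimension.
#' @export
knn_sparsify <- function(a, z = 10L) {
  n <- nrow(a)
  if (z < 1L || z > n - 1L)
    stop("z must be between 1 and N-1 (N = ", n, ")")
  out <- matrix(0, n, n, dimnames = dimnames(a))
  for (i in seq_len(n)) {
    ai <- a[i, ]
    ai[i] <- -Inf
    keep <- order(-ai, seq_len(n))[seq_len(z)]   # ties to the lower index
    out[i, keep] <- a[i, keep]
    out[i, i] <- a[i, i]
  }
  out
}

#' Row-normalise a non-negative matrix
#'
#' Divides each row by its sum so rows sum to one (a row-stochastic
#' transition matrix). Rows must have strictly positive sums.
#'
#' @param a Non-negative matrix.
#' @return Row-stochastic matrix.
#' @export
row_normalize <- function(a) {
  rs <- rowSums(a)
  if (any(rs <= 0)) stop("zero or negative row sum at row ",
                         which(rs <= 0)[1L])
  a / rs
}

#' Graph diffusion iterations
#'
#' Iterative smoothing of a row-stochastic affinity matrix,
#' \deqn{Q_1 = A, \qquad Q_t = A Q_{t-1} A^\top + I,}
#' returning the final iterate. This is the computationally efficient form
#' of tensor-product-graph diffusion: it propagates affinity mass along
#' shared neighbourhoods, reinforcing coherent structure and suppressing
#' unshared noise. With \code{iters = 1} the input is returned unchanged.
#'
#' @param a Row-normalised affinity matrix.
#' @param iters Number of diffusion iterations (default 5).
#' @return The diffused affinity matrix (generally asymmetric).
#' @export
diffuse_graph <- function(a, iters = 5L) {
  if (iters < 1L) stop("iters must be >= 1")
  q <- a
  if (iters > 1L) {
    eye <- diag(nrow(a))
    for (t in 2:iters) {
      q <- a %*% q %*% t(a) + eye
      if (!all(is.finite(q))) stop("non-finite values during diffusion")
    }
  }
  dimnames(q) <- dimnames(a)
  q
}

# combined graph-building path: kernels -> combine -> sparsify ->
# row-normalise -> diffuse -> symmetrise.  `dists` is a list of per-view
# distance matrices.
build_fused_graph <- function(dists, p, s, z, iters, diffuse = TRUE,
                              kernel = "adaptive") {
  graphs <- if (kernel == "adaptive")
    lapply(dists, adaptive_kernel, p = p, s = s)
  else
    lapply(dists, zm_kernel, p = p)
  fuse_graphs(graphs, z, iters, diffuse)
}

fuse_graphs <- function(graphs, z, iters, diffuse = TRUE) {
  a <- combine_graphs(graphs)
  a <- knn_sparsify(a, z)
  a <- row_normalize(a)
  if (diffuse) a <- diffuse_graph(a, iters)
  (a + t(a)) / 2     # symmetrise for the eigendecomposition
}
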