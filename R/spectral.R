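#' Normalised graph Laplacian
#'
#' \deqn{L = D^{-1/2} A D^{-1/2}} where D is the diagonal matrix of row sums
#' of the (symmetric, non-negative) affinity matrix A. The leading
#' eigenvectors of this operator carry the cluster structure of the graph;
#' its eigenvalues lie in [-1, 1].
#'
#' @param a Symmetric non-negative affinity matrix with positive row sums.
#' @return Symmetric matrix of the same dimension.
#' @export
graph_laplacian <- function(a) {
  rs <- rowSums(a)
  if (any(rs <= 0)) stop("zero row sum at row ", which(rs <= 0)[1L])
  a / sqrt(outer(rs, rs))
}

#' Eigendecomposition of a symmetric operator
#'
#' Eigenvalues in descending order with eigenvectors in matching columns.
#' Eigenvector signs are fixed deterministically (the largest-magnitude
#' component of each vector is made positive) so downstream distribution
#' analysis is reproducible.
#'
#' @param l Symmetric matrix.
#' @return List with components \code{values} (descending) and
#'   \code{vectors} (orthonormal columns).
#' @export
laplacian_eigen <- function(l) {
  if (max(abs(l - t(l))) > 1e-10) stop("matrix is not symmetric")
  e <- eigen(l, symmetric = TRUE)
  v <- e$vectors
  for (j in seq_len(ncol(v))) {
    i0 <- which.max(abs(v[, j]))
    if (v[i0, j] < 0) v[, j] <- -v[, j]
  }
  rownames(v) <- rownames(l)
  list(values = e$values, vectors = v)
}

#' Unit-row eigenvector embedding
#'
#' Stacks the leading k eigenvectors as columns and renormalises each row to
#' unit Euclidean length, mapping every sample onto the unit sphere in R^k.
#' All-zero rows (only possible on degenerate graphs) are replaced by the
#' first basis vector.
#'
#' @param es Eigen system from [laplacian_eigen()].
#' @param k Number of leading eigenvectors to use.
#' @return N x k matrix with unit-norm rows.
#' @export
embed_rows <- function(es, k) {
  v <- es$vectors
  if (k < 1L || k > ncol(v)) stop("k must be between 1 and N")
  x <- v[, seq_len(k), drop = FALSE]
  nrm <- sqrt(rowSums(x * x))
  zero <- nrm == 0
  if (any(zero)) {
    x[zero, ] <- 0
    x[zero, 1L] <- 1
    nrm[zero] <- 1
  }
  x / nrm
}

#' Gaussian-mixture clustering of an embedding
#'
#' Fits a k-component Gaussian mixture by EM (via \pkg{mclust}, full
#' covariance with a conjugate prior for regularisation, deterministic
#' model-based hierarchical initialisation) and assigns each row to the
#' component of maximum posterior responsibility. If the full-covariance fit
#' degenerates, diagonal and spherical models are tried, then k-means.
#'
#' @param y Numeric matrix of embedded samples (rows).
#' @param k Number of mixture components.
#' @param seed Integer seed (used by the k-means fallback and any
#'   stochastic initialisation).
#' @return Integer vector of cluster labels in 1..k, named by row names.
#' @export
gmm_cluster <- function(y, k, seed = 1L) {
  y <- as.matrix(y)
  if (k < 1L || k > nrow(y)) stop("k must be between 1 and N")
  if (anyNA(y) || !all(is.finite(y))) stop("embedding has non-finite values")
  labs <- if (k == 1L) rep(1L, nrow(y)) else {
    cl <- NULL
    set.seed(seed)
    for (model in c("VVV", "VVI", "EII")) {
      fit <- tryCatch(
        suppressWarnings(mclust::Mclust(y, G = k, modelNames = model,
                                        prior = mclust::priorControl(),
                                        verbose = FALSE)),
        error = function(e) NULL)
      if (!is.null(fit) && length(unique(fit$classification)) == k) {
        cl <- as.integer(fit$classification)
        break
      }
    }
    if (is.null(cl)) {
      set.seed(seed)
      cl <- as.integer(suppressWarnings(
        kmeans(y, centers = k, nstart = 10L, iter.max = 100L))$cluster)
    }
    cl
  }
  names(labs) <- rownames(y)
  labs
}
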