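#' Density-aware spectral clustering
#'
#' Fits the full clustering pipeline to one or more feature-by-sample
#' matrices: adaptive density-aware kernel per view, graph combination,
#' kNN sparsification, row normalisation, graph diffusion, normalised
#' Laplacian eigendecomposition, automatic selection of the number of
#' clusters, and Gaussian-mixture clustering of the unit-row eigenvector
#' embedding.
#'
#' Two selection heuristics are available: `"eigengap"` (largest gap
#' between consecutive Laplacian eigenvalues; suited to Gaussian-like
#' clusters) and `"dip"` (the multimodality gap: the last substantial drop
#' in the dip statistic across successive eigenvectors; also detects
#' non-convex structures, and can additionally tune the kernel
#' neighbourhood parameter P via `tune = TRUE`). `method = "fixed"`
#' clusters at a user-chosen `k`.
#'
#' For multi-view input the sample sets must match; views are aligned by
#' sample id to the first view. With `fasp = TRUE` samples are first
#' compressed to `centroids` k-means centroids, the pipeline runs on
#' centroids, and labels are propagated back (fast approximate spectral
#' clustering, for large sample numbers).
#'
#' @param x Feature-by-sample numeric matrix, or list of such matrices
#'   (one per view), or a `cluster_sim` object.
#' @param method Cluster-number selection: `"eigengap"`, `"dip"` or
#'   `"fixed"`.
#' @param k Number of clusters when `method = "fixed"`.
#' @param kernel Similarity kernel: the density-aware
#'   common-nearest-neighbour kernel (`"adaptive"`, default) or the
#'   Zelnik-Manor self-tuning kernel (`"zm"`), provided for comparison.
#' @param kernel_p Local-scale neighbour index P of the kernel (default 3).
#' @param kernel_s Common-nearest-neighbour set size S (default 7).
#' @param knn Sparsification neighbourhood Z (default 10).
#' @param diffusion_iters Graph diffusion iterations (default 5).
#' @param max_k Largest K considered by either heuristic (default 10).
#' @param tune Tune P over `tune_grid` by the multimodality gap
#'   (`method = "dip"` only; default FALSE).
#' @param tune_grid Candidate P values for tuning (default 1:10).
#' @param dip_diffuse Apply diffusion on the dip path (default TRUE).
#' @param fasp Compress to k-means centroids first (default FALSE).
#' @param centroids Number of FASP centroids (default 900).
#' @param cluster Fit the final GMM and return labels (default TRUE; set
#'   FALSE to run model selection only).
#' @param seed Integer seed controlling all randomised steps.
#' @return An object of class `spectral_cluster` with components `labels`
#'   (named integer vector), `k`, `method`, `diagnostics` (per-candidate
#'   eigengaps or dip drops), `eigenvalues`, `embedding`, `similarity`
#'   (fused graph), `tuning` (when tuned), `fasp` (compression info) and
#'   `params`.
#' @examples
#' sim <- sim_blobs(3, n_per = 30, separation = 12, seed = 1)
#' fit <- spectral_cluster(sim, method = "eigengap", max_k = 6)
#' fit$k
#' table(fit$labels, sim$labels)
#' @export
spectral_cluster <- function(x,
                             method = c("eigengap", "dip", "fixed"),
                             k = NULL,
                             kernel = c("adaptive", "zm"),
                             kernel_p = 3L, kernel_s = 7L,
                             knn = 10L, diffusion_iters = 5L,
                             max_k = 10L,
                             tune = FALSE, tune_grid = 1:10,
                             dip_diffuse = TRUE,
                             fasp = FALSE, centroids = 900L,
                             cluster = TRUE,
                             seed = 1L) {
  method <- match.arg(method)
  kernel <- match.arg(kernel)
  if (method == "fixed" && is.null(k))
    stop("method = \"fixed\" requires k")
  views <- align_views(x)
  n_samples <- ncol(views[[1L]])

  compression <- NULL
  if (fasp) {
    compression <- fasp_compress(views, m = centroids, seed = seed)
    views <- compression$views
  }
  n <- ncol(views[[1L]])
  if (max_k + 1L > n) stop("max_k + 1 exceeds the number of samples")

  dists <- lapply(views, pairwise_dist)

  tuning <- NULL
  p_used <- kernel_p
  diffuse <- if (method == "dip") dip_diffuse else TRUE
  if (method == "dip" && tune) {
    tuning <- tune_kernel_p(dists, p_grid = tune_grid, s = kernel_s,
                            z = knn, iters = diffusion_iters,
                            diffuse = diffuse, max_k = max_k)
    p_used <- tuning$p
  }

  astar <- build_fused_graph(dists, p = p_used, s = kernel_s, z = knn,
                             iters = diffusion_iters, diffuse = diffuse,
                             kernel = kernel)
  es <- laplacian_eigen(graph_laplacian(astar))

  if (method == "eigengap") {
    sel <- eigengap_k(es$values, max_k)
  } else if (method == "dip") {
    ds <- dip_series(es, max_k)
    sel <- last_substantial_drop(ds$d)
    sel$diagnostics$dip <- ds$z[seq_len(max_k)]
  } else {
    sel <- list(k = as.integer(k),
                diagnostics = data.frame(k = as.integer(k)))
  }

  y <- embed_rows(es, sel$k)
  labels <- NULL
  if (cluster) {
    labels <- gmm_cluster(y, sel$k, seed = seed)
    if (fasp) labels <- fasp_expand(labels, compression)
  }

  structure(list(
    labels = labels,
    k = sel$k,
    method = method,
    diagnostics = sel$diagnostics,
    eigenvalues = es$values,
    embedding = y,
    similarity = astar,
    tuning = tuning,
    fasp = compression,
    n = n_samples,
    params = list(method = method, k = sel$k, kernel = kernel,
                  kernel_p = p_used,
                  kernel_s = kernel_s, knn = knn,
                  diffusion_iters = diffusion_iters, max_k = max_k,
                  tune = tune, dip_diffuse = dip_diffuse, fasp = fasp,
                  centroids = if (fasp) centroids else NA_integer_,
                  seed = seed),
    call = match.call()),
    class = "spectral_cluster")
}

# normalise input to a list of validated, id-aligned views
align_views <- function(x) {
  if (inherits(x, "cluster_sim")) x <- x$views
  if (!is.list(x)) x <- list(x)
  views <- lapply(x, as_expression_matrix)
  ids <- colnames(views[[1L]])
  for (i in seq_along(views)[-1L]) {
    vi <- colnames(views[[i]])
    if (!setequal(vi, ids)) {
      bad <- union(setdiff(vi, ids), setdiff(ids, vi))
      stop("views disagree on samples: ",
           paste(utils::head(bad, 5L), collapse = ", "),
           if (length(bad) > 5L) ", ...")
    }
    views[[i]] <- views[[i]][, ids, drop = FALSE]
  }
  views
}

#' @export
print.spectral_cluster <- function(x, ...) {
  cat("Density-aware spectral clustering\n")
  cat("  samples:", x$n,
      if (!is.null(x$fasp)) paste0("(FASP, ", x$fasp$m, " centroids)"),
      "\n")
  cat("  K =", x$k, "selected by", x$method)
  if (!is.null(x$tuning)) cat(" (kernel tuned: P =", x$params$kernel_p, ")")
  cat("\n")
  if (!is.null(x$labels))
    cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.spectral_cluster <- function(object, ...) {
  print(object)
  cat("\nSelection diagnostics:\n")
  print(object$diagnostics, row.names = FALSE)
  if (!is.null(object$tuning)) {
    cat("\nKernel tuning (deepest multimodality drop per P):\n")
    print(object$tuning$diagnostics, row.names = FALSE)
  }
  invisible(object)
}

#' Cluster labels of a fit
#' @param object A `spectral_cluster` fit.
#' @param ... Unused.
#' @return Factor of cluster labels named by sample id.
#' @export
fitted.spectral_cluster <- function(object, ...) {
  if (is.null(object$labels)) stop("fit was run with cluster = FALSE")
  factor(object$labels)
}

#' Plot a spectral clustering fit
#'
#' Two panels: the model-selection diagnostic (eigenvalues with the chosen
#' gap, or the dip-statistic series) and the first two embedding
#' coordinates coloured by cluster.
#'
#' @param x A `spectral_cluster` fit.
#' @param ... Passed to the scatter panel.
#' @export
plot.spectral_cluster <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  nshow <- min(length(x$eigenvalues), x$params$max_k + 5L)
  if (x$method == "dip" && !is.null(x$diagnostics$dip)) {
    graphics::plot(x$diagnostics$k, x$diagnostics$dip, type = "b",
                   xlab = "eigenvector", ylab = "dip statistic",
                   main = "multimodality of eigenvectors")
    graphics::abline(v = x$k, lty = 2)
  } else {
    graphics::plot(seq_len(nshow), x$eigenvalues[seq_len(nshow)],
                   type = "b", xlab = "index", ylab = "eigenvalue",
                   main = "Laplacian spectrum")
    graphics::abline(v = x$k + 0.5, lty = 2)
  }
  emb <- x$embedding
  if (ncol(emb) == 1L) emb <- cbind(emb, 0)
  col <- if (is.null(x$labels) || !is.null(x$fasp)) 1L else x$labels
  graphics::plot(emb[, 1L], emb[, 2L], col = col, pch = 19,
                 xlab = "embedding 1", ylab = "embedding 2",
                 main = paste0("embedding (K = ", x$k, ")"), ...)
  invisible(x)
}
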