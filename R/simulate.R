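#' Simulate Gaussian cluster data
#'
#' Generates K isotropic Gaussian clusters with centres placed mutually
#' equidistant: on the vertices of a regular simplex when the feature space
#' allows (dims >= K), otherwise on a circle in the first two dimensions.
#' Neighbouring centres are `separation * sd` apart, so `separation` is the
#' centre distance in noise-standard-deviation units and directly controls
#' cluster overlap.
#'
#' @param k Number of clusters.
#' @param n_per Samples per cluster (default 50).
#' @param dims Number of features (default 2).
#' @param separation Centre separation in units of `sd` (default 12, well
#'   separated).
#' @param sd Isotropic within-cluster standard deviation (default 1).
#' @param seed Integer seed; identical seeds give identical data.
#' @return A `cluster_sim` list: `views` (list with one feature-by-sample
#'   matrix), `labels` (named integer vector), `k_true`, `seed`.
#' @export
sim_blobs <- function(k, n_per = 50L, dims = 2L, separation = 12,
                      sd = 1, seed = 1L) {
  if (k < 1L) stop("k must be >= 1")
  if (separation <= 0) stop("separation must be positive")
  if (dims < 2L && k > 1L) stop("need at least 2 dimensions for k > 1")
  edge <- separation * sd
  centres <- matrix(0, k, dims)
  if (k > 1L) {
    if (dims >= k) {
      for (i in seq_len(k)) centres[i, i] <- edge / sqrt(2)
    } else {
      ang <- 2 * pi * (seq_len(k) - 1L) / k
      r <- edge / (2 * sin(pi / k))
      centres[, 1L] <- r * cos(ang)
      centres[, 2L] <- r * sin(ang)
    }
  }
  set.seed(seed)
  labels <- rep(seq_len(k), each = n_per)
  n <- length(labels)
  x <- centres[labels, , drop = FALSE] +
    matrix(rnorm(n * dims, sd = sd), n, dims)
  x <- t(x)
  dimnames(x) <- list(paste0("f", seq_len(dims)), paste0("s", seq_len(n)))
  names(labels) <- colnames(x)
  structure(list(views = list(x), labels = labels, k_true = k, seed = seed),
            class = "cluster_sim")
}

#' Simulate multi-view data with a shared cluster structure
#'
#' All views share one cluster assignment; each view embeds the cluster
#' signal in its own random feature directions (unit-variance centre
#' coordinates) and adds independent Gaussian noise. At the default noise
#' level each single view is too noisy to resolve the cluster number on its
#' own while the fused graph, which averages out the view-specific noise,
#' recovers it.
#'
#' @param k Number of clusters (default 3).
#' @param n Total samples per view (default 300, balanced clusters).
#' @param features Features per view (default 500).
#' @param n_views Number of views (default 2).
#' @param noise_sd Per-view Gaussian noise standard deviation relative to
#'   the unit-variance cluster signal (default 5.5).
#' @param seed Integer seed.
#' @return A `cluster_sim` list with one matrix per view.
#' @export
sim_multiview <- function(k = 3L, n = 300L, features = 500L, n_views = 2L,
                          noise_sd = 5.5, seed = 1L) {
  set.seed(seed)
  labels <- rep(seq_len(k), length.out = n)
  labels <- sort(labels)
  ids <- paste0("s", seq_len(n))
  names(labels) <- ids
  views <- lapply(seq_len(n_views), function(v) {
    centres <- matrix(rnorm(k * features), k, features)
    x <- centres[labels, , drop = FALSE] +
      matrix(rnorm(n * features, sd = noise_sd), n, features)
    x <- t(x)
    dimnames(x) <- list(paste0("f", seq_len(features)), ids)
    x
  })
  names(views) <- paste0("view", seq_len(n_views))
  structure(list(views = views, labels = labels, k_true = k, seed = seed),
            class = "cluster_sim")
}

#' Simulate non-convex two-class shapes
#'
#' `spirals`: two interleaved Archimedean spiral arms (the classic
#' benchmark where Gaussian-cluster assumptions fail). `worms`: two
#' elongated curved bands of different point density running close to each
#' other, the regime in which a density-aware kernel outperforms a kernel
#' that adapts to scale only. Ground truth is the generating arm (K = 2).
#'
#' @param kind `"spirals"` or `"worms"`.
#' @param n Total number of points (default 300).
#' @param noise Jitter standard deviation added to the coordinates
#'   (default 0 for spirals, 0.08 for worms).
#' @param seed Integer seed.
#' @return A `cluster_sim` list with one 2 x n coordinate matrix.
#' @export
sim_shapes <- function(kind = c("spirals", "worms"), n = 300L, noise = NULL,
                       seed = 1L) {
  kind <- match.arg(kind)
  set.seed(seed)
  if (kind == "spirals") {
    if (is.null(noise)) noise <- 0
    n1 <- n %/% 2L
    n2 <- n - n1
    mk_arm <- function(m, phase) {
      t <- seq(0, 1, length.out = m)
      r <- 0.5 + 2 * t
      th <- 3 * pi * t + phase
      cbind(r * cos(th), r * sin(th))
    }
    xy <- rbind(mk_arm(n1, 0), mk_arm(n2, pi))
    labels <- rep(1:2, c(n1, n2))
  } else {
    if (is.null(noise)) noise <- 0.08
    n1 <- round(2 * n / 3)    # dense band
    n2 <- n - n1              # sparse band
    t1 <- seq(0, 1, length.out = n1)
    t2 <- seq(0, 1, length.out = n2)
    band <- function(t, r) cbind(r * cos(pi * t), r * sin(pi * t))
    xy <- rbind(band(t1, 3), band(t2, 3.8))
    labels <- rep(1:2, c(n1, n2))
  }
  xy <- xy + matrix(rnorm(2 * n, sd = noise), n, 2)
  x <- t(xy)
  dimnames(x) <- list(c("f1", "f2"), paste0("s", seq_len(n)))
  names(labels) <- colnames(x)
  structure(list(views = list(x), labels = labels, k_true = 2L, seed = seed),
            class = "cluster_sim")
}

#' Named benchmark presets
#'
#' Fixed generator settings for the simulation regimes used throughout the
#' package's validation: `blobs5` (5 well-separated 2-D Gaussian clusters),
#' `blobs10` / `blobs20` (10 and 20 moderately overlapping isotropic blobs
#' resembling single-cell RNA-seq cell types), `multiview3` (two noisy
#' views sharing a 3-cluster structure that only the fused graph resolves),
#' `spirals` (noiseless interleaved spirals) and `worms` (two curved bands
#' of unequal density).
#'
#' @param name Preset name.
#' @param seed Integer seed.
#' @return A `cluster_sim` list (see [sim_blobs()]).
#' @export
cluster_preset <- function(name = c("blobs5", "blobs10", "blobs20",
                                    "multiview3", "spirals", "worms"),
                           seed = 1L) {
  name <- match.arg(name)
  switch(name,
    blobs5     = sim_blobs(5L, 50L, 2L, separation = 12, sd = 1, seed = seed),
    blobs10    = sim_blobs(10L, 50L, 10L, separation = 8, sd = 1, seed = seed),
    blobs20    = sim_blobs(20L, 50L, 20L, separation = 8, sd = 1, seed = seed),
    multiview3 = sim_multiview(seed = seed),
    spirals    = sim_shapes("spirals", 300L, seed = seed),
    worms      = sim_shapes("worms", 300L, seed = seed))
}

#' @export
print.cluster_sim <- function(x, ...) {
  cat("Simulated cluster data: ", length(x$views), " view(s), ",
      ncol(x$views[[1L]]), " samples, K_true = ", x$k_true,
      " (seed ", x$seed, ")\n", sep = "")
  invisible(x)
}
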