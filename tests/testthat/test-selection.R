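test_that("eigengap picks the largest consecutive gap from n = 2", {
  ev <- c(1, 1, 1, 1, 1, .2, .1, .08, .05, .03, .01)
  expect_equal(eigengap_k(ev, 10)$k, 5)
  ev3 <- c(1, 1, 1, .1, .05, .04, .03, .02, .015, .012, .01)
  expect_equal(eigengap_k(ev3, 10)$k, 3)

  set.seed(17)
  for (i in 1:20) {
    v <- sort(runif(15), decreasing = TRUE)
    got <- eigengap_k(v, 10)$k
    gaps <- sapply(2:10, function(n) v[n] - v[n + 1])   # exhaustive scan
    expect_equal(got, (2:10)[which.max(gaps)])
  }
  expect_error(eigengap_k(c(1, .5), 10), "eigenvalues")
})

test_that("dip series indexes drops between consecutive eigenvectors", {
  sim <- cluster_preset("blobs5", seed = 2)
  fit <- spectral_cluster(sim, method = "dip", cluster = FALSE)
  d <- fit$diagnostics$drop
  expect_equal(which.min(d), 5)            # transition at eigenvector 5 -> 6
  expect_equal(length(d), 10)

  # duplicated consecutive eigenvectors give a zero difference
  set.seed(2)
  v <- matrix(rnorm(120), 20, 6)
  v[, 3] <- v[, 2]
  es <- list(values = 6:1, vectors = v)
  ds <- dip_series(es, 5)
  expect_equal(ds$d[2], 0)
  expect_equal(ds$d, diff(ds$z))           # difference-loop identity
})

test_that("last substantial drop follows the published search rules", {
  # single dominant drop at position 5, flat after
  d <- c(.05, -.004, .001, -.002, -.3, .002, -.001, 0, .001)
  expect_equal(last_substantial_drop(d)$k, 5)
  # dominant drop already at position 2
  d2 <- c(.05, -.3, .01, -.02, .001, 0, 0, 0, 0)
  expect_equal(last_substantial_drop(d2)$k, 2)
  # local drop at 3, then a 2.5-fold deeper drop at 6 within the window
  d3 <- c(.05, -.01, -.1, .001, 0, -.25, .001, 0, 0)
  expect_equal(last_substantial_drop(d3)$k, 6)
  expect_equal(last_drop_replay(d3), 6)
  # a drop beyond the look-ahead window is not reached
  d4 <- c(.05, -.1, rep(0, 8), -.5)
  expect_equal(last_substantial_drop(d4)$k, 2)

  set.seed(23)
  for (i in 1:50) {                        # rule-replay oracle
    dr <- rnorm(12, sd = .05)
    expect_equal(suppressWarnings(last_substantial_drop(dr)$k),
                 {
                   r <- last_drop_replay(dr)
                   if (dr[r] >= 0) 2L else r
                 })
  }
  expect_warning(k0 <- last_substantial_drop(c(.1, .2, .3, .4))$k, "no drop")
  expect_equal(k0, 2)
})

test_that("kernel tuning selects P by the deepest multimodality drop", {
  sim <- sim_blobs(3, n_per = 20, separation = 10, seed = 6)
  dists <- list(pairwise_dist(sim$views[[1]]))
  tuned <- tune_kernel_p(dists, p_grid = 1:5, max_k = 6)
  # exhaustive replay over the same grid
  drops <- sapply(1:5, function(p) {
    a <- adaptive_kernel(dists[[1]], p = p, s = 7)
    a <- row_normalize(knn_sparsify(a, 10))
    a <- diffuse_graph(a, 5)
    a <- (a + t(a)) / 2
    es <- laplacian_eigen(graph_laplacian(a))
    min(dip_series(es, 6)$d)
  })
  expect_equal(tuned$p, (1:5)[which.min(drops)])
  expect_equal(tuned$diagnostics$min_drop, drops, tolerance = 1e-12)

  # a single blob still yields a valid choice
  one <- sim_blobs(1, n_per = 25, separation = 5, seed = 1)
  t1 <- tune_kernel_p(list(pairwise_dist(one$views[[1]])), p_grid = 1:3,
                      max_k = 5)
  expect_true(t1$p %in% 1:3)
})

test_that("the arg-min shortcut can differ from the guarded search", {
  # deepest raw minimum sits early; the guarded search walks past it only
  # for a substantially deeper drop, here absent beyond the window
  d <- c(.05, -.2, .01, .0, .001, 0, 0, 0, 0, 0, -.25)
  expect_equal(which.min(d[-1]) + 1L, 11L)
  expect_equal(last_substantial_drop(d, cmax = 7, f = 2)$k, 2)
})
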