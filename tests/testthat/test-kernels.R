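test_that("pairwise distances match geometry and a brute-force loop", {
  x <- matrix(c(0, 0, 3, 4, 0, 0), nrow = 2,
              dimnames = list(NULL, c("a", "b", "c")))
  d <- pairwise_dist(x)
  expect_equal(d["a", "b"], 5)            # 3-4-5 triangle
  expect_equal(d["a", "c"], 0)            # identical samples
  expect_equal(diag(d), setNames(rep(0, 3), c("a", "b", "c")))

  set.seed(11)
  y <- matrix(rnorm(15), nrow = 3, dimnames = list(NULL, paste0("s", 1:5)))
  expect_equal(unname(pairwise_dist(y)), dist_loop(y), tolerance = 1e-12)
  expect_true(isSymmetric(pairwise_dist(y)))
})

test_that("pairwise_dist rejects missing values with coordinates", {
  x <- matrix(1:12, nrow = 3,
              dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
  x[2, 3] <- NA
  expect_error(pairwise_dist(x), "g2.*s3")
})

test_that("local scale is the distance to the P-th neighbour", {
  d <- as.matrix(dist(c(0, 1, 2, 10)))
  expect_equal(local_scale(d, 1), c(1, 1, 1, 8))
  expect_equal(local_scale(d, 2), c(2, 1, 2, 9))
  expect_error(local_scale(d, 4), "between 1 and N-1")
})

test_that("duplicated points fall back to a positive scale", {
  d <- as.matrix(dist(c(0, 0, 5)))
  s <- local_scale(d, 1)
  expect_true(all(s > 0))
  expect_equal(s[3], 5)
  expect_equal(s[1], 5)   # nearest is a duplicate at distance 0
  d0 <- matrix(0, 3, 3)   # fully degenerate: all points identical
  expect_equal(local_scale(d0, 1), c(1, 1, 1))
})

test_that("common-nearest-neighbour counts match a set-intersection loop", {
  # two tight, far-apart blobs of size > S: no shared neighbours across
  x <- rbind(c(0, 0.1, 0.2, 0.15, 50, 50.1, 50.2, 50.15))
  colnames(x) <- paste0("s", 1:8)
  d <- pairwise_dist(x)
  cnn <- cnn_counts(d, s = 3)
  expect_true(all(cnn[1:4, 5:8] == 0))
  expect_true(all(cnn <= 3))
  expect_true(isSymmetric(cnn))

  set.seed(4)
  y <- matrix(rnorm(16), nrow = 2, dimnames = list(NULL, paste0("s", 1:8)))
  dy <- pairwise_dist(y)
  got <- cnn_counts(dy, s = 3)
  nn <- lapply(1:8, function(i) setdiff(order(dy[i, ]), i)[1:3])
  for (i in 1:8) for (j in 1:8)
    expect_equal(got[i, j], length(intersect(nn[[i]], nn[[j]])))
})

test_that("adaptive kernel matches the scalar three-term formula", {
  set.seed(9)
  x <- matrix(rnorm(16), nrow = 2, dimnames = list(NULL, paste0("s", 1:8)))
  d <- pairwise_dist(x)
  a <- adaptive_kernel(d, p = 3, s = 7)
  sig <- local_scale(d, 3)
  cnn <- cnn_counts(d, 7)
  for (i in 1:8) for (j in 1:8)
    expect_equal(a[i, j],
                 exp(-d[i, j]^2 / (sig[i] * sig[j] * (cnn[i, j] + 1))),
                 tolerance = 1e-14)
  expect_equal(unname(diag(a)), rep(1, 8))
  expect_true(all(a > 0 & a <= 1))
  expect_true(isSymmetric(a))
})

test_that("Zelnik-Manor kernel is the CNN = 0 reduction and a lower bound", {
  x <- matrix(c(0, 1), nrow = 1)
  colnames(x) <- c("a", "b")
  d <- rbind(c(0, 1), c(1, 0))            # two points, d = sigma_i = 1
  dimnames(d) <- list(c("a", "b"), c("a", "b"))
  z <- zm_kernel(d, p = 1)
  expect_equal(z["a", "b"], exp(-1))

  set.seed(12)
  y <- matrix(rnorm(16), nrow = 2, dimnames = list(NULL, paste0("s", 1:8)))
  dy <- pairwise_dist(y)
  a <- adaptive_kernel(dy, p = 3, s = 7)
  z <- zm_kernel(dy, p = 3)
  expect_true(all(z <= a + 1e-15))        # CNN + 1 >= 1 inflates bandwidth
  sig <- local_scale(dy, 3)
  for (i in 1:8) for (j in 1:8)
    expect_equal(z[i, j], exp(-dy[i, j]^2 / (sig[i] * sig[j])),
                 tolerance = 1e-14)

  # with empty shared neighbourhoods the kernels coincide exactly
  far <- rbind(c(0, 0.1, 0.2, 0.15, 1e4, 1e4 + 0.1, 1e4 + 0.2, 1e4 + 0.15))
  colnames(far) <- paste0("s", 1:8)
  df <- pairwise_dist(far)
  cn <- cnn_counts(df, 3)
  mask <- cn == 0
  af <- adaptive_kernel(df, 3, 3)
  zf <- zm_kernel(df, 3)
  expect_equal(af[mask], zf[mask], tolerance = 1e-14)
})

test_that("rescaling coordinates leaves neighbour sets and CNN unchanged", {
  set.seed(21)
  x <- matrix(rnorm(30), nrow = 3, dimnames = list(NULL, paste0("s", 1:10)))
  expect_equal(cnn_counts(pairwise_dist(x), 4),
               cnn_counts(pairwise_dist(7.3 * x), 4))
})
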