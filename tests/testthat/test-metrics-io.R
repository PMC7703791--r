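test_that("cv filter ranks by |sd/mean| with stable ties", {
  set.seed(6)
  x <- matrix(rnorm(80, mean = 5), 8, 10,
              dimnames = list(paste0("g", 1:8), paste0("s", 1:10)))
  expect_identical(cv_filter(x, 1), x)

  # features with known CVs 2, 1, .5, .1
  mk <- function(mu, sdv) rnorm(50, mu, sdv)
  set.seed(1)
  y <- rbind(g1 = mk(1, 2), g2 = mk(2, 2), g3 = mk(4, 2), g4 = mk(20, 2))
  colnames(y) <- paste0("s", 1:50)
  kept <- cv_filter(y, 0.5)
  expect_identical(rownames(kept), c("g1", "g2"))

  got <- cv_filter(x, 0.5)
  cv <- abs(apply(x, 1, sd) / rowMeans(x))          # independent ranking
  expect_setequal(rownames(got),
                  names(sort(cv, decreasing = TRUE))[1:4])

  x[1, ] <- c(rep(-1, 5), rep(1, 5))                # zero mean
  expect_warning(kept0 <- cv_filter(x, 0.25), "zero-mean")
  expect_true("g1" %in% rownames(kept0))
})

test_that("NMI matches hand-computed entropies and its limits", {
  a <- c(1, 1, 1, 2, 2, 2)
  b <- c(1, 1, 2, 2, 2, 2)
  # contingency: [2,1;0,3]; H(a)=H(.5,.5), H(b)=H(1/3,2/3)
  mi <- 2/6 * log((2/6) / (.5 * 1/3)) + 1/6 * log((1/6) / (.5 * 2/3)) +
    3/6 * log((3/6) / (.5 * 2/3))
  expect_equal(nmi(a, b), mi / mean(c(log(2), -(1/3) * log(1/3) -
                                        (2/3) * log(2/3))))
  expect_equal(nmi(a, a), 1)
  expect_equal(nmi(a, c(2, 2, 2, 1, 1, 1)), 1)      # label-permutation
  set.seed(30)
  big_a <- sample(1:4, 4000, replace = TRUE)
  big_b <- sample(1:4, 4000, replace = TRUE)
  expect_lt(nmi(big_a, big_b), 0.01)
  expect_warning(z <- nmi(rep(1, 5), c(1, 2, 1, 2, 1)), "degenerate")
  expect_equal(z, 0)
  expect_error(nmi(1:3, 1:4), "length")
})

test_that("ARI agrees with partition identity and chance", {
  expect_equal(ari(c(1, 1, 2, 2), c(5, 5, 9, 9)), 1)
  expect_lt(abs(ari(rep(1:2, 100), rep(c(1, 2, 2, 1), 50))), 0.2)
})

test_that("expression matrices round-trip through TSV and CSV", {
  x <- matrix(round(rnorm(6), 4), 3, 2,
              dimnames = list(paste0("g", 1:3), c("sampleA", "sampleB")))
  x <- cbind(x, sampleC = c(1.5, -2, 0))
  tf <- tempfile(fileext = ".tsv")
  write_expression(x, tf)
  expect_equal(read_expression(tf), x)
  # transpose involution
  tt <- tempfile(fileext = ".tsv")
  write_expression(t(x), tt)
  expect_equal(read_expression(tt, transpose = TRUE), x)
})

test_that("malformed matrix files are rejected with coordinates", {
  tf <- tempfile(fileext = ".tsv")
  writeLines(c("id\ts1\ts2\ts3", "g1\t1\t2\t3", "g2\t4\tNA\t6"), tf)
  expect_error(read_expression(tf), "g2.*s2")
  writeLines(c("id\ts1\ts2\ts3", "g1\t1\t2\t3", "g1\t4\t5\t6"), tf)
  expect_error(read_expression(tf), "duplicated")
  writeLines(c("id\ts1\ts2\ts3", "g1\t1\tx\t3"), tf)
  expect_error(read_expression(tf), "non-numeric|3 samples")
})

test_that("clustering results and simulations write deterministic files", {
  sim <- sim_blobs(2, n_per = 10, separation = 10, seed = 1)
  fit <- spectral_cluster(sim, method = "fixed", k = 2, knn = 5,
                          max_k = 5, seed = 1)
  pre <- tempfile()
  paths <- write_clustering(fit, pre, similarity = TRUE)
  labs <- read_labels(paste0(pre, "_labels.tsv"))
  expect_equal(labs, fit$labels)
  sym <- read_expression(paste0(pre, "_similarity.tsv"))
  expect_lt(max(abs(sym - t(sym))), 1e-12)
  cfg <- readLines(paste0(pre, "_config.yml"))
  expect_true(any(grepl("^knn: 5$", cfg)))

  dir <- tempfile()
  write_simulation(sim, dir)
  expect_equal(read_expression(file.path(dir, "view1.tsv")), sim$views[[1]])
  expect_equal(read_labels(file.path(dir, "truth.tsv")), sim$labels)
})

test_that("misaligned multi-view inputs fail before computation", {
  sim <- sim_blobs(2, n_per = 6, separation = 10, seed = 1)
  v1 <- sim$views[[1]]
  v2 <- v1
  colnames(v2)[1] <- "zz9"
  expect_error(spectral_cluster(list(v1, v2)), "zz9")
})
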