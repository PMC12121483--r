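test_that("Calinski-Harabasz matches hand computation and the textbook oracle", {
  pts <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  expect_equal(calinski_harabasz(pts, c(TRUE, TRUE, FALSE, FALSE)), 200)

  # zero within-group dispersion ranks above everything
  dup <- rbind(c(0, 0), c(0, 0), c(1, 1), c(1, 1))
  expect_identical(calinski_harabasz(dup, c(TRUE, TRUE, FALSE, FALSE)), Inf)

  # scale invariance
  set.seed(10)
  p <- matrix(rnorm(60), ncol = 2)
  grp <- rep(c(TRUE, FALSE), 15)
  expect_equal(calinski_harabasz(p, grp), calinski_harabasz(3.7 * p, grp),
               tolerance = 1e-12)

  expect_error(calinski_harabasz(p, rep(TRUE, 30)), "nonempty")

  # against the loop-based oracle on random 2-group instances
  set.seed(404)
  for (i in 1:100) {
    n <- sample(5:40, 1L)
    pp <- matrix(rnorm(2 * n), ncol = 2)
    g <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2L, replace = TRUE))
    expect_equal(calinski_harabasz(pp, g), ch_oracle(pp, g),
                 tolerance = 1e-9)
  }
})

test_that("events split below/above a boundary path deterministically", {
  coords <- cbind(c(0.1, 0.4, 0.9, 0.6), c(0.2, 0.8, 0.5, 0.5))
  flat <- rep(0.5, 4L)  # flat boundary at y = 0.5 on a 4-bin grid
  below <- appclust:::split_assignment(coords, flat, 4L, "x")
  expect_identical(below, c(TRUE, FALSE, TRUE, TRUE))  # y = 0.5 goes below
  expect_identical(sum(below) + sum(!below), 4L)

  # y-pass transposes the roles of the axes
  below_y <- appclust:::split_assignment(coords, flat, 4L, "y")
  expect_identical(below_y, coords[, 1] <= 0.5)
})

test_that("projection candidates respect the size filter and degeneracy", {
  blobs <- two_blob_data(n_per = 100L, seed = 3L)
  cfg <- list(min_cluster_size = 30L, sigma = 1, beta = 0.1, dq = 0.1,
              bins = NULL, step_limit = 1L)
  # separation lives on column 1: the pair (1, 2) must split it
  cand <- appclust:::candidates_for_projection(blobs$x, 1L, 2L, cfg)
  expect_false(is.null(cand))
  expect_setequal(unique(blobs$label[cand$below]),
                  setdiff(0:1, unique(blobs$label[!cand$below])))
  expect_gte(sum(cand$below), 30L)
  expect_gte(sum(!cand$below), 30L)

  # identical points: degenerate axes, no candidate
  same <- matrix(1, 50, 2)
  expect_null(appclust:::candidates_for_projection(same, 1L, 2L, cfg))

  # min_cluster_size larger than either blob: filtered out
  cfg$min_cluster_size <- 150L
  expect_null(appclust:::candidates_for_projection(blobs$x, 1L, 2L, cfg))

  # a pair of uninformative axes offers no valley
  noise <- appclust:::candidates_for_projection(blobs$x, 2L, 3L, cfg)
  expect_null(noise)
})

test_that("the recursion stops below twice the minimum cluster size", {
  set.seed(6)
  x <- matrix(rnorm(2 * 99), ncol = 2)
  fit <- app(x, min_cluster_size = 50)  # n = 99 = 2 * 50 - 1
  expect_identical(fit$k, 1L)
  expect_identical(unique(fit$cluster), 0L)
})

test_that("well-separated mixtures are recovered exactly", {
  blobs <- two_blob_data(n_per = 200L, seed = 21L)
  fit <- app(blobs$x, min_cluster_size = 50)
  expect_identical(fit$k, 2L)
  expect_equal(adjusted_rand(fit$cluster, blobs$label), 1)

  fb <- make_blobs(four_blob_spec(seed = 2L))
  fit4 <- app(fb$x, min_cluster_size = 50)
  expect_identical(fit4$k, 4L)
  expect_equal(adjusted_rand(fit4$cluster, fb$label), 1)
  # every leaf honours the size floor; labels partition the events
  expect_true(all(fit4$sizes >= 50L))
  expect_identical(sum(fit4$sizes), 2000L)
  expect_identical(sort(unique(fit4$cluster)), 0:3)
})

test_that("clustering is deterministic and column-permutation equivariant", {
  fb <- make_blobs(four_blob_spec(seed = 9L))
  f1 <- app(fb$x, min_cluster_size = 50, keep_data = FALSE)
  f2 <- app(fb$x, min_cluster_size = 50, keep_data = FALSE)
  expect_identical(f1$cluster, f2$cluster)

  perm <- c(3L, 1L, 2L)
  fp <- app(fb$x[, perm], min_cluster_size = 50, keep_data = FALSE)
  expect_equal(adjusted_rand(f1$cluster, fp$cluster), 1)
})

test_that("reducing the minimum cluster size only adds clusters", {
  fb <- make_blobs(four_blob_spec(seed = 4L))
  k_big <- app(fb$x, min_cluster_size = 200, keep_data = FALSE)$k
  k_small <- app(fb$x, min_cluster_size = 50, keep_data = FALSE)$k
  expect_gte(k_small, k_big)
  # leaf count can never exceed n / min_cluster_size
  expect_lte(k_small, 2000L / 50L)
})

test_that("fitted models print, summarise, predict and plot", {
  fb <- make_blobs(four_blob_spec(seed = 13L))
  fit <- app(fb$x, min_cluster_size = 50)
  expect_output(print(fit), "4 clusters")
  s <- summary(fit)
  expect_s3_class(s, "summary.app")
  expect_identical(nrow(s$splits), 3L)  # 4 leaves -> 3 internal nodes
  expect_output(print(s), "splits")

  # training events route back to their own clusters
  expect_identical(predict(fit, fb$x), fit$cluster)
  # new draws from the same components land in the matching clusters
  fb2 <- make_blobs(four_blob_spec(seed = 14L))
  expect_equal(adjusted_rand(predict(fit, fb2$x), fb2$label), 1)

  tmp <- tempfile(fileext = ".png")
  grDevices::png(tmp)
  expect_silent(plot(fit))
  grDevices::dev.off()
  expect_true(file.exists(tmp))
  unlink(tmp)

  expect_error(app(fb$x[, 1, drop = FALSE], min_cluster_size = 10),
               "at least 2")
  expect_error(app(cbind(c(1, Inf), c(1, 2)), min_cluster_size = 1),
               "finite")
  expect_error(app(fb$x), "min_cluster_size")
})
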