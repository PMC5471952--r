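test_that("distortion summary matches hand values and an independent recompute", {
  cloud <- random_cloud(5, 3, seed = 1)
  idrep <- distortion_summary(cloud, cloud, metric = "euclidean")
  expect_equal(idrep$max_distortion, 0)
  expect_equal(idrep$avg_distortion, 0)

  high <- matrix(c(0, 10), ncol = 1)
  low <- matrix(c(0, 7), ncol = 1)
  rep2 <- distortion_summary(high, low, metric = "euclidean")
  expect_equal(rep2$max_distortion, 3)
  expect_equal(rep2$avg_distortion, 3)
  expect_equal(nrow(rep2$pairs), 1L)

  # recomputation oracle over the pair list
  h <- random_cloud(8, 12, seed = 3)
  l <- random_cloud(8, 2, seed = 4)
  rep3 <- distortion_summary(h, l, metric = "manhattan")
  expect_equal(nrow(rep3$pairs), choose(8, 2))
  expect_equal(rep3$max_distortion, max(rep3$pairs$distortion))
  expect_equal(rep3$avg_distortion, mean(rep3$pairs$distortion))
  manual <- abs(sqrt(sum((l[2, ] - l[5, ])^2)) -
                  sum(abs(h[2, ] - h[5, ])))
  expect_equal(rep3$pairs$distortion[rep3$pairs$i == 2 & rep3$pairs$j == 5],
               manual)
  expect_error(distortion_summary(h, l[1:5, ]), "mismatch")
})

test_that("distortion is invariant under rigid motions of the embedding", {
  h <- random_cloud(7, 5, seed = 9)
  l <- random_cloud(7, 2, seed = 10)
  base <- distortion_summary(h, l, metric = "euclidean")
  withr::with_seed(2, {
    for (rep in 1:5) {
      th <- runif(1, 0, 2 * pi)
      R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
      moved <- l %*% R + matrix(runif(2, -50, 50), 7, 2, byrow = TRUE)
      rot <- distortion_summary(h, moved, metric = "euclidean")
      expect_equal(rot$max_distortion, base$max_distortion, tolerance = 1e-9)
      expect_equal(rot$avg_distortion, base$avg_distortion, tolerance = 1e-9)
    }
  })
})

test_that("classical MDS embeds Euclidean-embeddable distances exactly", {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  D <- as.matrix(dist(square))
  rec <- classical_mds(D, 2)
  rep <- distortion_summary(D, rec, metric = "euclidean",
                            high_is_dist = TRUE)
  expect_lt(rep$max_distortion, 1e-9)

  # 1D configuration in k = 2: second axis collapses
  line <- matrix(seq(0, 90, by = 10), ncol = 1)
  rec1 <- classical_mds(as.matrix(dist(line)), 2)
  expect_lt(max(abs(rec1[, 2])), 1e-7 * 90) # collapses to numerical noise

  # deterministic sign convention
  expect_identical(classical_mds(D, 2), classical_mds(D, 2))
  expect_error(classical_mds(matrix(0, 3, 3), 2), "no positive")
})

test_that("classical MDS pairwise distances match an independent
           double-centering eigendecomposition", {
  cloud <- random_cloud(10, 12, seed = 17)
  D <- as.matrix(dist(cloud))
  got <- classical_mds(D, 2)
  # independent oracle: explicit Torgerson double centering
  n <- nrow(D)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (D^2) %*% J
  eig <- eigen(B, symmetric = TRUE)
  oracle <- eig$vectors[, 1:2] %*% diag(sqrt(pmax(eig$values[1:2], 0)))
  expect_equal(as.matrix(dist(got)), as.matrix(dist(oracle)),
               tolerance = 1e-8)
})

test_that("random projection is seeded, linear, and JL-unbiased on average", {
  cloud <- random_cloud(6, 12, seed = 2)
  expect_identical(random_projection(cloud, 2, seed = 5),
                   random_projection(cloud, 2, seed = 5))
  expect_false(identical(random_projection(cloud, 2, seed = 5),
                         random_projection(cloud, 2, seed = 6)))
  zero <- matrix(0, 3, 12)
  expect_true(all(random_projection(zero, 2, seed = 1) == 0))
  expect_error(random_projection(cloud, 12, seed = 1), "below the data dimension")

  # E ||P(x - y)||^2 = ||x - y||^2 over many seeds (Monte-Carlo tolerance)
  x <- cloud[1, ]; y <- cloud[2, ]
  true_sq <- sum((x - y)^2)
  sq <- vapply(1:400, function(s) {
    p <- random_projection(rbind(x, y), 2, seed = s)
    sum((p[1, ] - p[2, ])^2)
  }, numeric(1))
  expect_lt(abs(mean(sq) - true_sq) / true_sq, 0.15)
})

test_that("ratio summaries use truncation and reproduce published rows", {
  rs <- ratio_summary(c(3197.8), c(1000))
  expect_equal(rs$ratios$ratio, 3.197) # truncated, not rounded to 3.198
  tab <- printed_benchmarks()
  t1 <- dplyr::filter(tab, statistic == "max")
  rs1 <- ratio_summary(t1$mds, t1$sanjay)
  expect_equal(rs1$ratios$ratio, t1$printed_ratio_mds_sanjay)
  expect_equal(rs1$mean, 2.56)

  eq <- ratio_summary(c(2, 3), c(2, 3))
  expect_equal(eq$ratios$ratio, c(1, 1))
  expect_equal(eq$mean, 1)
  expect_error(ratio_summary(1:3, 1:2), "length mismatch")
  expect_error(ratio_summary(c(1), c(0)), "positive")
})

test_that("method comparison emits the published table shape", {
  cloud <- generate_flow_like_cloud(60, m = 12, seed = 5)
  # single-method table
  tab1 <- compare_methods(cloud, methods = "mds", sample_size = 8, seed = 2)
  expect_equal(tab1$method, "mds")
  expect_true(is.na(tab1$ratio_vs_sanjay))

  tab <- compare_methods(cloud, sample_size = 8, bits = 8, seed = 2)
  expect_setequal(tab$method, c("sanjay", "mds", "rp"))
  expect_equal(names(tab), c("dataset_id", "method", "max_distortion",
                             "avg_distortion", "ratio_vs_sanjay"))
  expect_true(all(tab$max_distortion >= tab$avg_distortion))
  san <- tab$max_distortion[tab$method == "sanjay"]
  expect_equal(tab$ratio_vs_sanjay[tab$method == "mds"],
               floor(tab$max_distortion[tab$method == "mds"] / san * 1000) / 1000)
})

test_that("planar data padded to 12 channels is recovered by both
           MDS (exactly) and the synthesis (to quantization)", {
  pts <- planar_cloud(8, seed = 3, pad_to = 12)
  D <- as.matrix(dist(pts))
  mds_rep <- distortion_summary(D, classical_mds(D, 2), metric = "euclidean",
                                high_is_dist = TRUE)
  expect_lt(mds_rep$max_distortion, 1e-6 * max(D))
  fit <- find_min_epsilon(D, bits = 10, block = 2, band = "additive")
  low <- fit$embedding$coords / fit$embedding$scale
  san_rep <- distortion_summary(D, low, metric = "euclidean",
                                high_is_dist = TRUE)
  expect_lt(san_rep$max_distortion, 0.02 * max(D))
})
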