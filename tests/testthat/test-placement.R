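test_that("trilateration recovers points from consistent distances", {
  expect_equal(trilaterate(rbind(c(0, 0), c(1, 0), c(0, 1)),
                           c(sqrt(2), 1, 1)), c(1, 1))
  withr::with_seed(5, {
    for (k in 2:3) {
      anchors <- matrix(runif((k + 1) * k, 0, 100), k + 1, k)
      truth <- runif(k, 0, 100)
      dists <- apply(anchors, 1, function(a) sqrt(sum((a - truth)^2)))
      expect_equal(trilaterate(anchors, dists), truth, tolerance = 1e-9)
    }
  })
})

test_that("trilateration under noise stays near the grid-search optimum", {
  withr::with_seed(31, {
    anchors <- rbind(c(0, 0), c(100, 0), c(0, 100))
    truth <- c(40, 65)
    dists <- apply(anchors, 1, function(a) sqrt(sum((a - truth)^2)))
    noisy <- dists * (1 + runif(3, -0.01, 0.01))
    est <- trilaterate(anchors, noisy)
    resid <- function(p) sum((apply(anchors, 1, function(a)
      sqrt(sum((a - p)^2))) - noisy)^2)
    # dense grid around the truth as an independent minimizer
    grid <- expand.grid(x = seq(30, 50, by = 0.25), y = seq(55, 75, by = 0.25))
    best <- grid[which.min(apply(grid, 1, function(r) resid(as.numeric(r)))), ]
    expect_lt(sqrt(sum((est - as.numeric(best))^2)), 1)
    expect_lt(resid(est), resid(truth) + 1e-9) # least squares beats truth on noisy data
  })
})

test_that("degenerate anchors and bad distances are rejected by name", {
  collinear <- rbind(c(0, 0), c(1, 1), c(2, 2))
  expect_error(trilaterate(collinear, c(1, 1, 1)), "collinear")
  expect_error(trilaterate(rbind(c(0, 0), c(1, 0), c(0, 1)), c(-1, 1, 1)),
               "non-negative")
  expect_error(trilaterate(rbind(c(0, 0), c(1, 0)), c(1, 1)), "at least 3")
})

test_that("all cells are placed, structural points keep synthesized positions", {
  b <- blob_cloud(40, m = 12, seed = 21, sep = 900, sd = 25)
  part <- structure(list(labels = b$labels, n = 3L),
                    class = "community_partition")
  sp <- build_structural_points(b$cloud, part, 2L, seed = 1)
  D <- pairwise_distance_matrix(sp, "euclidean")
  fit <- find_min_epsilon(D, bits = 8, block = 2, band = "additive")
  low <- project_all_points(b$cloud, part, sp, fit$embedding,
                            metric = "euclidean")
  expect_equal(nrow(low$coords), 120L)
  expect_true(all(is.finite(as.matrix(low$coords[, c("x", "y")]))))
  # the structural table is exactly the synthesis output
  expect_equal(as.matrix(low$structural[, c("x_grid", "y_grid")]),
               fit$embedding$coords, ignore_attr = TRUE)
})

test_that("a cell coinciding with a component centroid lands on its anchor
           when the anchor embedding is distance-consistent", {
  # structural set living in the plane, embedded exactly (scale 1)
  anchors <- rbind(c(10, 10), c(50, 12), c(30, 60))
  O <- colMeans(anchors)
  sp <- structure(list(points = rbind(O, anchors),
                       roles = c("community_centroid",
                                 paste0("component_centroid_", 1:3)),
                       community = rep(1L, 4), n = 1L, d = 4L,
                       target_dim = 2L),
                  class = "structural_points")
  ge <- structure(list(coords = rbind(round(O), anchors), bits = 7L,
                       block = 1L, scale = 1, epsilon_used = 0.01,
                       band = "additive", band_halfwidth = 0,
                       iterations = 7L, D_int = NULL, target_dim = 2L),
                  class = "grid_embedding")
  cells <- rbind(anchors[2, ], c(25, 30))
  part <- structure(list(labels = c(1L, 1L), n = 1L),
                    class = "community_partition")
  out <- project_all_points(cells, part, sp, ge, metric = "euclidean")
  expect_equal(as.numeric(out$coords[1, c("x", "y")]), anchors[2, ],
               tolerance = 1e-9)
  # consistent distances recover any point exactly
  expect_equal(as.numeric(out$coords[2, c("x", "y")]), c(25, 30),
               tolerance = 1e-9)
})

test_that("placement distortion on a planar single-community fixture is
           bounded by band plus trilateration residual", {
  pts <- planar_cloud(30, seed = 12)[, 1:2]
  part <- structure(list(labels = rep(1L, 30), n = 1L),
                    class = "community_partition")
  sp <- build_structural_points(pts, part, 2L, seed = 2)
  D <- pairwise_distance_matrix(sp, "euclidean")
  fit <- find_min_epsilon(D, bits = 10, block = 2, band = "additive")
  low <- project_all_points(pts, part, sp, fit$embedding,
                            metric = "euclidean")
  rep <- distortion_summary(pts,
                            as.matrix(low$coords[, c("x", "y")]) / low$scale,
                            metric = "euclidean")
  # anchors are near-exact; cells inherit band + quantization + residual
  diameter <- max(dist(pts))
  expect_lt(rep$max_distortion, 0.1 * diameter)
})

test_that("collinear embedded anchors fall back to the community centroid", {
  pts <- matrix(c(0, 0, 10, 0, 20, 0, 5, 0), ncol = 2, byrow = TRUE)
  part <- structure(list(labels = rep(1L, 4), n = 1L),
                    class = "community_partition")
  sp <- build_structural_points(pts, part, 2L)
  # force a degenerate embedding: all anchors on one line
  ge <- structure(list(coords = matrix(c(0L, 5L, 10L, 2L, 0L, 0L, 0L, 0L),
                                       ncol = 2),
                       bits = 6L, block = 2L, scale = 1, epsilon_used = 0.1,
                       band = "additive", band_halfwidth = 1,
                       iterations = 3L, D_int = NULL, target_dim = 2L),
                  class = "grid_embedding")
  expect_warning(out <- project_all_points(pts, part, sp, ge,
                                           metric = "euclidean"),
                 "affinely dependent")
  cent_idx <- which(sp$roles == "community_centroid")
  expect_true(all(out$coords$x == ge$coords[cent_idx, 1] &
                    out$coords$y == ge$coords[cent_idx, 2]))
})
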