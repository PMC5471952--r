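#' Centroid of a set of channel vectors
#'
#' Coordinate-wise arithmetic mean; the surrogate that stands in for all cells
#' of a community during synthesis.
#'
#' @param points Matrix or data frame, one row per point.
#' @return Numeric vector of column means.
#' @export
centroid <- function(points) {
  m <- as_cloud_matrix(points, "points")
  colMeans(m)
}

#' Component centroids of a community via k-means
#'
#' Splits a community into `k` component sub-communities with k-means
#' (k-means++ style seeding, fixed seed, at most 300 iterations) and returns
#' the component means, sorted lexicographically for a stable ordering. When
#' the community has fewer than `k` points (or fewer than `k` distinct
#' points), the available points are padded with copies of the community
#' centroid, with a warning: the structural point count must stay fixed.
#'
#' @param points Matrix or data frame, one row per point.
#' @param k Number of components (3 for 2D targets, 4 for 3D).
#' @param seed Master seed (k-means substream).
#' @return A `k` x m numeric matrix of component centroids.
#' @export
k_component_centroids <- function(points, k, seed = 1L) {
  m <- as_cloud_matrix(points, "points")
  if (k < 1) abort("`k` must be at least 1")
  if (k == 1) return(matrix(colMeans(m), nrow = 1,
                            dimnames = list(NULL, colnames(m))))
  distinct <- unique(m)
  if (nrow(m) < k || nrow(distinct) < k) {
    warn(sprintf(
      "community has %d point(s) (%d distinct) but %d components requested; padding with the community centroid",
      nrow(m), nrow(distinct), k))
    ctr <- colMeans(m)
    centers <- rbind(distinct,
                     matrix(rep(ctr, k - nrow(distinct)),
                            ncol = ncol(m), byrow = TRUE))[seq_len(k), , drop = FALSE]
  } else if (nrow(m) == k) {
    centers <- m # each point is its own component
  } else {
    centers <- withr::with_seed(substream_seed(seed, "kmeans"), {
      init <- kmeanspp_init(m, k)
      kmeans(m, centers = init, iter.max = 300L)$centers
    })
  }
  centers <- centers[do.call(order, as.data.frame(centers)), , drop = FALSE]
  rownames(centers) <- NULL
  centers
}

# k-means++ seeding: first center uniform, then proportional to squared
# distance from the nearest chosen center.
kmeanspp_init <- function(m, k) {
  n <- nrow(m)
  idx <- integer(k)
  idx[1] <- sample.int(n, 1)
  d2 <- rowSums((m - matrix(m[idx[1], ], n, ncol(m), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    probs <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    idx[j] <- sample.int(n, 1, prob = probs)
    nd2 <- rowSums((m - matrix(m[idx[j], ], n, ncol(m), byrow = TRUE))^2)
    d2 <- pmin(d2, nd2)
  }
  m[idx, , drop = FALSE]
}

#' Assemble the structural point set
#'
#' Per community `C_i`: its centroid `O_i` plus `k` component centroids
#' `E_i^1..E_i^k` with `k = 3` for 2D targets and `k = 4` for 3D, ordered
#' `O_1, E_1^1, E_1^2, E_1^3, O_2, ...`. The structural point count is
#' `d = 4n` (2D) or `d = 5n` (3D) for `n` communities.
#'
#' @param data Events-by-channels table or matrix.
#' @param partition A `community_partition` covering all rows.
#' @param target_dim 2 or 3.
#' @param seed Master seed.
#' @return A `structural_points` object: `points` (d x m matrix), `roles`,
#'   `community`, `n` and `d`.
#' @export
build_structural_points <- function(data, partition, target_dim = 2L,
                                    seed = 1L) {
  m <- as_cloud_matrix(data)
  stopifnot(inherits(partition, "community_partition"))
  if (!target_dim %in% c(2L, 3L)) abort("`target_dim` must be 2 or 3")
  if (length(partition$labels) != nrow(m)) {
    abort("partition does not cover the data rows")
  }
  k <- target_dim + 1L
  n <- partition$n
  pts <- list(); roles <- character(0); comm <- integer(0)
  for (i in seq_len(n)) {
    rows <- m[partition$labels == i, , drop = FALSE]
    O <- colMeans(rows)
    E <- k_component_centroids(rows, k, seed = seed + i)
    pts[[length(pts) + 1L]] <- rbind(O, E)
    roles <- c(roles, "community_centroid",
               paste0("component_centroid_", seq_len(k)))
    comm <- c(comm, rep(i, k + 1L))
  }
  points <- do.call(rbind, pts)
  rownames(points) <- NULL
  structure(list(points = points, roles = roles, community = comm,
                 n = n, d = nrow(points), target_dim = target_dim),
            class = "structural_points")
}

#' @export
print.structural_points <- function(x, ...) {
  cat(sprintf("structural points: d = %d (%d communities x %d points each), %dD target\n",
              x$d, x$n, x$d / x$n, x$target_dim))
  invisible(x)
}

#' @describeIn build_structural_points Structural points as a tibble.
#' @param x A `structural_points` object.
#' @param ... Unused.
#' @export
tidy.structural_points <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(community = x$community, role = x$roles),
    tibble::as_tibble(as.data.frame(x$points)))
}

#' Pairwise distance matrix of the structural points
#'
#' @param sp A `structural_points` object (or a plain matrix of points).
#' @param metric `"manhattan"` (default) or `"euclidean"`.
#' @return A d x d symmetric numeric matrix with zero diagonal and the metric
#'   attached as attribute `"metric"`.
#' @export
pairwise_distance_matrix <- function(sp, metric = "manhattan") {
  metric <- check_metric(metric)
  pts <- if (inherits(sp, "structural_points")) sp$points else
    as_cloud_matrix(sp, "sp")
  if (nrow(pts) < 2) abort("need at least two points")
  D <- pairwise_dist(pts, metric)
  dimnames(D) <- NULL
  attr(D, "metric") <- metric
  D
}
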