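#' Position a point from its distances to known anchors
#'
#' A point's 2D (3D) position is determined by its distances to 3 (4)
#' affinely independent anchors. Differencing the squared-distance equations
#' linearizes the system, which is solved in the least-squares sense: when
#' the distances are consistent (generated by a true point) the recovery is
#' exact to float precision; when they carry band distortion the residual is
#' minimized.
#'
#' @param anchors (k+1) x k (or more rows) matrix of anchor positions.
#' @param dists Non-negative distances from the unknown point to each anchor.
#' @return Numeric length-k position.
#' @examples
#' trilaterate(rbind(c(0, 0), c(1, 0), c(0, 1)), c(sqrt(2), 1, 1)) # (1, 1)
#' @export
trilaterate <- function(anchors, dists) {
  A <- as.matrix(anchors)
  k <- ncol(A)
  if (nrow(A) < k + 1) abort(sprintf("need at least %d anchors in %dD", k + 1, k))
  if (length(dists) != nrow(A)) abort("one distance per anchor required")
  if (any(dists < 0)) abort("distances must be non-negative")
  M <- 2 * sweep(A[-1, , drop = FALSE], 2, A[1, ], "-")
  rhs <- (dists[1]^2 - dists[-1]^2) +
    (rowSums(A[-1, , drop = FALSE]^2) - sum(A[1, ]^2))
  qr_M <- qr(M)
  if (qr_M$rank < k) {
    abort(sprintf(
      "degenerate anchors: affinely dependent (rank %d < %d); %s",
      qr_M$rank, k,
      if (k == 2) "anchors are collinear" else "anchors are coplanar"))
  }
  as.numeric(qr.coef(qr(cbind(M)), rhs))
}

#' Place every cell from its community's embedded anchors
#'
#' Extends the synthesized structural embedding to all N cells: each cell's
#' high-dimensional distances to its own community's component centroids are
#' scaled into grid units and the cell is positioned by least-squares
#' trilateration against those anchors' synthesized grid coordinates.
#' Structural points keep their synthesized positions. When a community's
#' embedded anchors are affinely dependent, the community centroid is added
#' as an extra anchor; if still degenerate the cell is placed at the
#' community centroid's position, with a warning.
#'
#' Note: with `metric = "manhattan"` the anchor distances are Manhattan in
#' the data space but Euclidean in the embedding plane — the same modeling
#' mismatch the synthesis band carries; a warning records it in the result.
#'
#' @param data Events-by-channels table or matrix (N cells).
#' @param partition `community_partition` over the N cells.
#' @param sp `structural_points` built from the same partition.
#' @param ge `grid_embedding` of the structural points.
#' @param metric High-dimensional metric for anchor distances.
#' @return A `lowdim_points` object: `coords` (tibble of N placed cells, grid
#'   units, with community), `structural` (tibble of the d synthesized
#'   points) and `scale`.
#' @export
project_all_points <- function(data, partition, sp, ge,
                               metric = "manhattan") {
  metric <- check_metric(metric)
  m <- as_cloud_matrix(data)
  stopifnot(inherits(partition, "community_partition"),
            inherits(sp, "structural_points"),
            inherits(ge, "grid_embedding"))
  if (nrow(ge$coords) != sp$d) abort("embedding does not cover the structural points")
  if (length(partition$labels) != nrow(m)) abort("partition inconsistent with data")
  k <- ge$target_dim
  axes <- c("x", "y", "z")[seq_len(k)]
  out <- matrix(NA_real_, nrow(m), k)
  for (i in seq_len(partition$n)) {
    rows <- which(partition$labels == i)
    comp_idx <- which(sp$community == i & sp$roles != "community_centroid")
    cent_idx <- which(sp$community == i & sp$roles == "community_centroid")
    anchors_hd <- sp$points[comp_idx, , drop = FALSE]
    anchors_ld <- ge$coords[comp_idx, , drop = FALSE]
    use_idx <- comp_idx
    if (qr(sweep(anchors_ld[-1, , drop = FALSE], 2, anchors_ld[1, ], "-"))$rank < k) {
      use_idx <- c(comp_idx, cent_idx)
      anchors_hd <- sp$points[use_idx, , drop = FALSE]
      anchors_ld <- ge$coords[use_idx, , drop = FALSE]
    }
    degenerate <- qr(sweep(anchors_ld[-1, , drop = FALSE], 2,
                           anchors_ld[1, ], "-"))$rank < k
    if (degenerate) {
      warn(sprintf(
        "community %d: embedded anchors are affinely dependent; placing its cells at the community centroid", i))
      for (rw in rows) out[rw, ] <- ge$coords[cent_idx, ]
    } else {
      for (rw in rows) {
        dists <- apply(anchors_hd, 1, function(a) {
          if (metric == "manhattan") sum(abs(m[rw, ] - a)) else
            sqrt(sum((m[rw, ] - a)^2))
        }) * ge$scale
        out[rw, ] <- trilaterate(anchors_ld, dists)
      }
    }
  }
  coords <- tibble::as_tibble(as.data.frame(out))
  names(coords) <- axes
  coords <- dplyr::bind_cols(
    tibble::tibble(cell = seq_len(nrow(m)), community = partition$labels),
    coords)
  structural <- tidy(ge)
  structural$role <- sp$roles
  structural$community <- sp$community
  res <- structure(list(coords = coords, structural = structural,
                        scale = ge$scale, target_dim = k, metric = metric),
                   class = "lowdim_points")
  if (metric == "manhattan") {
    attr(res, "metric_note") <-
      "anchor distances are Manhattan in data space but Euclidean in the embedding plane"
  }
  res
}

#' @export
print.lowdim_points <- function(x, ...) {
  cat(sprintf("low-dimensional point set: %d placed cells + %d structural points in %dD (scale %g)\n",
              nrow(x$coords), nrow(x$structural), x$target_dim, x$scale))
  invisible(x)
}

#' @describeIn project_all_points Placed cells as a tibble (grid and data
#'   units).
#' @param x A `lowdim_points` object.
#' @param ... Unused.
#' @export
tidy.lowdim_points <- function(x, ...) {
  out <- x$coords
  axes <- c("x", "y", "z")[seq_len(x$target_dim)]
  for (a in axes) out[[paste0(a, "_data")]] <- out[[a]] / x$scale
  out
}
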