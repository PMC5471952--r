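#' Synthesize a low-dimensional visualization of cytometry events
#'
#' The full pipeline behind the command-line tool: (optionally subsample,
#' then) pick the network threshold by degree-entropy maximization, build the
#' thresholded cell-similarity network, partition it into communities by
#' random-walk agglomeration, summarize each community by its centroid plus
#' k-means component centroids, synthesize grid coordinates for those
#' structural points by iterative bit-vector refinement, and place every
#' remaining cell by trilateration against its community's embedded anchors.
#'
#' @param data Events-by-channels table or matrix.
#' @param target_dim 2 or 3.
#' @param bits Coordinate width b of the synthesized grid (default 10).
#' @param block Bits fixed per refinement iteration (default 2).
#' @param epsilon `"auto"` (smallest feasible band via [find_min_epsilon()])
#'   or a fixed positive value.
#' @param band Tolerance semantics for the synthesis band; the default
#'   additive band bounds the worst-pair additive distortion directly.
#' @param metric High-dimensional metric (`"manhattan"` default).
#' @param threshold `"auto"` (entropy-maximizing) or a fixed value `>= 0`.
#' @param sample_size Optional subsample size applied before the pipeline.
#' @param walk_length Walktrap random-walk length.
#' @param seed Master seed fanned out to all random substreams.
#' @param node_budget Per-step synthesis search budget.
#' @return A `sanjay_embedding` object bundling the network threshold,
#'   community partition, structural points, grid embedding and per-cell
#'   placements; see [tidy.sanjay_embedding()], [glance.sanjay_embedding()]
#'   and [autoplot.sanjay_embedding()].
#' @export
sanjay_embed <- function(data, target_dim = 2L, bits = 10L, block = 2L,
                         epsilon = "auto", band = "additive",
                         metric = "manhattan", threshold = "auto",
                         sample_size = NULL, walk_length = 4L, seed = 1L,
                         node_budget = 5e5) {
  metric <- check_metric(metric)
  m <- as_cloud_matrix(data)
  if (!is.null(sample_size) && sample_size < nrow(m)) {
    m <- as_cloud_matrix(subsample_points(m, sample_size, seed = seed))
  }
  if (identical(threshold, "auto")) threshold <- as.numeric(select_threshold(m))
  net <- build_tfcn(m, threshold)
  partition <- detect_communities(net, walk_length = walk_length, seed = seed)
  sp <- build_structural_points(m, partition, target_dim = target_dim,
                                seed = seed)
  D <- pairwise_distance_matrix(sp, metric = metric)
  if (identical(epsilon, "auto")) {
    fit <- find_min_epsilon(D, target_dim = target_dim, bits = bits,
                            block = block, band = band,
                            node_budget = node_budget)
    ge <- fit$embedding
  } else {
    if (!is.numeric(epsilon) || epsilon <= 0) {
      abort("`epsilon` must be \"auto\" or a positive number")
    }
    ge <- synthesize_embedding(D, target_dim = target_dim, bits = bits,
                               block = block, epsilon = epsilon, band = band,
                               node_budget = node_budget)
    if (inherits(ge, "sanjay_infeasible")) {
      abort(sprintf(
        "synthesis infeasible at epsilon = %g (failed at iteration %d); try epsilon = \"auto\"",
        epsilon, ge$iteration))
    }
  }
  placed <- project_all_points(m, partition, sp, ge, metric = metric)
  structure(list(data = m, threshold = threshold, network = net,
                 partition = partition, structural = sp, grid = ge,
                 placed = placed, metric = metric, seed = seed),
            class = "sanjay_embedding")
}

#' @export
print.sanjay_embedding <- function(x, ...) {
  cat(sprintf(
    "synthesized embedding: %d cells -> %dD, T = %g, %d communities, d = %d structural points, epsilon = %g\n",
    nrow(x$data), x$grid$target_dim, x$threshold, x$partition$n,
    x$structural$d, x$grid$epsilon_used))
  invisible(x)
}

#' @describeIn sanjay_embed Per-cell coordinates (grid and data units) with
#'   community labels.
#' @param x A `sanjay_embedding`.
#' @param ... Unused.
#' @export
tidy.sanjay_embedding <- function(x, ...) tidy(x$placed)

#' @describeIn sanjay_embed One-row run summary including the structural-set
#'   distortion in data units.
#' @export
glance.sanjay_embedding <- function(x, ...) {
  rep <- structural_distortion(x)
  tibble::tibble(n_cells = nrow(x$data), target_dim = x$grid$target_dim,
                 threshold = x$threshold, n_communities = x$partition$n,
                 d_structural = x$structural$d,
                 epsilon_used = x$grid$epsilon_used, scale = x$grid$scale,
                 max_distortion = rep$max_distortion,
                 avg_distortion = rep$avg_distortion)
}

# Distortion of the structural point set in data units.
structural_distortion <- function(x) {
  D <- pairwise_distance_matrix(x$structural, metric = x$metric)
  distortion_summary(D, x$grid$coords / x$grid$scale, metric = x$metric,
                     high_is_dist = TRUE, method = "sanjay")
}

#' @describeIn sanjay_embed Scatter plot of the placed cells colored by
#'   community, with structural anchors overlaid.
#' @param object A `sanjay_embedding`.
#' @export
autoplot.sanjay_embedding <- function(object, ...) {
  cells <- tidy(object)
  anchors <- object$placed$structural
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$community)),
                        alpha = 0.6, size = 1) +
    ggplot2::geom_point(data = anchors,
                        ggplot2::aes(x = .data$x_grid, y = .data$y_grid,
                                     shape = .data$role), size = 3) +
    ggplot2::labs(colour = "community", shape = "structural role",
                  x = "x (grid units)", y = "y (grid units)",
                  title = "Synthesized low-dimensional embedding") +
    ggplot2::theme_minimal()
}

#' @describeIn distortion_summary Scatter of low- vs high-dimensional pair
#'   distances; the identity line is zero distortion.
#' @param object A `distortion_report`.
#' @export
autoplot.distortion_report <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$d_high, y = .data$d_low)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "high-dimensional distance",
                  y = "embedded distance",
                  title = sprintf("Pairwise distances (max distortion %.3g)",
                                  object$max_distortion)) +
    ggplot2::theme_minimal()
}
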