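#' Specify a mixture of cell populations
#'
#' Describes a Gaussian-mixture point cloud of the kind a multi-population
#' cytometry sample produces: per-population channel means, spreads and
#' mixture weights, optionally including a rare population (weight < 0.05),
#' the regime where rare phenotypes matter.
#'
#' @param means List (or matrix rows) of per-population mean vectors, all of
#'   equal length m.
#' @param spreads Per-population standard deviations (recycled to length of
#'   `means`).
#' @param weights Mixture proportions; must sum to 1.
#' @param rare_fraction Optional weight (< 0.05) for an extra rare population
#'   whose mean is the first population's mean shifted upward; set `NULL` to
#'   skip.
#' @return A `population_spec` object.
#' @export
population_spec <- function(means, spreads = 50, weights = NULL,
                            rare_fraction = NULL) {
  if (is.matrix(means)) means <- lapply(seq_len(nrow(means)), function(i) means[i, ])
  n_pop <- length(means)
  if (n_pop < 1) abort("at least one population required")
  m <- length(means[[1]])
  if (!all(lengths(means) == m)) abort("population means must share one dimension")
  spreads <- rep_len(spreads, n_pop)
  if (any(spreads <= 0)) abort("spreads must be positive")
  if (is.null(weights)) weights <- rep(1 / n_pop, n_pop)
  if (length(weights) != n_pop) abort("one weight per population required")
  if (!is.null(rare_fraction)) {
    if (rare_fraction <= 0 || rare_fraction >= 0.05) {
      abort("`rare_fraction` must lie in (0, 0.05)")
    }
    means <- c(means, list(means[[1]] + 6 * spreads[1]))
    spreads <- c(spreads, spreads[1])
    weights <- c(weights * (1 - rare_fraction), rare_fraction)
    n_pop <- n_pop + 1
  }
  if (abs(sum(weights) - 1) > 1e-8) abort("weights must sum to 1")
  structure(list(n_populations = n_pop, means = means, spreads = spreads,
                 weights = weights, m = m),
            class = "population_spec")
}

# Default study-condition spec: 3 populations in 12 channels on a raw
# fluorescence scale of roughly 0-1000, population means drawn once from the
# instance seed so repeated instances emulate distinct samples.
default_population_spec <- function(m = 12L, n_populations = 3L, seed = 1L,
                                    spread = 50) {
  means <- withr::with_seed(substream_seed(seed, "sim"), {
    lapply(seq_len(n_populations), function(i) runif(m, 100, 900))
  })
  population_spec(means, spreads = spread)
}

#' Generate a cytometry-like synthetic point cloud
#'
#' Gaussian-mixture draws clipped at zero (fluorescence intensities are
#' non-negative), with ground-truth population labels attached for
#' parameter-recovery tests. Deterministic per seed.
#'
#' @param n_cells Number of events (`>= n_populations`).
#' @param m Number of channels (ignored when `spec` is given).
#' @param spec A [population_spec()]; default: 3 well-separated populations
#'   in `m` channels on a 0-1000 intensity scale.
#' @param seed Master seed.
#' @return A tibble of `n_cells` x m channels with the true population id in
#'   attribute `"labels"` (also returned by `attr(x, "labels")`).
#' @export
generate_flow_like_cloud <- function(n_cells, m = 12L, spec = NULL,
                                     seed = 1L) {
  if (is.null(spec)) spec <- default_population_spec(m = m, seed = seed)
  stopifnot(inherits(spec, "population_spec"))
  if (n_cells < spec$n_populations) {
    abort("`n_cells` must be at least the number of populations")
  }
  out <- withr::with_seed(substream_seed(seed, "sim") + 1L, {
    labels <- sample.int(spec$n_populations, n_cells, replace = TRUE,
                         prob = spec$weights)
    # guarantee every population appears
    labels[seq_len(spec$n_populations)] <- seq_len(spec$n_populations)
    vals <- t(vapply(labels, function(p) {
      pmax(0, rnorm(spec$m, mean = spec$means[[p]], sd = spec$spreads[p]))
    }, numeric(spec$m)))
    list(vals = vals, labels = labels)
  })
  colnames(out$vals) <- paste0("c", seq_len(spec$m))
  tbl <- tibble::as_tibble(as.data.frame(out$vals))
  attr(tbl, "labels") <- out$labels
  tbl
}

#' One benchmark-shaped test instance
#'
#' A 10-event, 12-channel sample drawn from a 3-population mixture — the unit
#' the published distortion comparisons use (10 randomly chosen points from a
#' 12-dimensional dataset) — together with its pairwise distance matrix.
#'
#' @param seed Instance seed (different seeds emulate different datasets).
#' @param metric Distance metric for the returned matrix.
#' @return List with `cloud` (10 x 12 tibble) and `D` (10 x 10 matrix).
#' @export
sample_benchmark_instance <- function(seed = 1L, metric = "manhattan") {
  metric <- check_metric(metric)
  cloud <- generate_flow_like_cloud(200L, m = 12L, seed = seed)
  sub <- subsample_points(cloud, 10L, seed = seed)
  D <- pairwise_dist(as_cloud_matrix(sub), metric)
  attr(D, "metric") <- metric
  list(cloud = sub, D = D)
}

#' Exhaustive minimum of the maximum additive distortion
#'
#' Brute-force oracle for the synthesis core: enumerates every placement of
#' `d` points on the 2D b-bit grid (with reflection symmetry reduction and
#' branch-and-bound pruning) and returns a placement minimizing the maximum
#' additive distortion `| ||R_i - R_j|| - D_int[i, j] |`, plus that minimum.
#' Additive distortion is used because it is the reported evaluation
#' statistic. Refuses instances beyond `d <= 4`, `bits <= 3`, `k = 2`.
#'
#' @param D_int d x d target distance matrix in grid units.
#' @param bits Coordinate width (`<= 3`).
#' @param k Embedding dimension (must be 2).
#' @return List with `min_max_distortion` and `coords` (d x 2 integer
#'   matrix).
#' @export
brute_force_min_max_distortion <- function(D_int, bits, k = 2L) {
  D_int <- as.matrix(D_int)
  if (nrow(D_int) > 4 || bits > 3 || k != 2) {
    abort("instance above exhaustive-search size bounds (d <= 4, bits <= 3, k = 2)")
  }
  res <- cpp_brute_force_embedding(D_int, as.integer(bits), as.integer(k))
  list(min_max_distortion = res$min_max_distortion, coords = res$coords)
}
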