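#' Per-pair distortion of a projection
#'
#' Distortion of a pair is the absolute change of its distance under
#' projection, `|d(x', y') - d(x, y)|`; the report carries every unordered
#' pair plus the maximum and mean. High-dimensional distances use `metric`;
#' low-dimensional distances use `low_metric`, defaulting to Euclidean (the
#' distance the synthesis band controls and the one read off a scatter plot).
#'
#' @param high N x m matrix / data frame of original points, or an N x N
#'   distance matrix (`high_is_dist = TRUE`).
#' @param low N x k matrix / data frame of projected coordinates, in the same
#'   units as `high` (rescale grid coordinates by the embedding scale first).
#' @param metric High-dimensional metric.
#' @param low_metric Low-dimensional metric.
#' @param high_is_dist Treat `high` as a precomputed distance matrix.
#' @param method Optional method tag stored in the report.
#' @return A `distortion_report`; see [tidy.distortion_report()] and
#'   [glance.distortion_report()].
#' @export
distortion_summary <- function(high, low, metric = "manhattan",
                               low_metric = "euclidean",
                               high_is_dist = FALSE, method = NA_character_) {
  metric <- check_metric(metric)
  low_metric <- check_metric(low_metric)
  Dh <- if (high_is_dist) as.matrix(high) else
    pairwise_dist(as_cloud_matrix(high, "high"), metric)
  lowm <- as_cloud_matrix(low, "low")
  if (nrow(Dh) != nrow(lowm)) {
    abort(sprintf("point count mismatch: %d high vs %d low", nrow(Dh), nrow(lowm)))
  }
  if (nrow(Dh) < 2) abort("need at least two points")
  Dl <- pairwise_dist(lowm, low_metric)
  ut <- which(upper.tri(Dh), arr.ind = TRUE)
  pairs <- tibble::tibble(
    i = ut[, 1], j = ut[, 2],
    d_high = Dh[ut], d_low = Dl[ut],
    distortion = abs(Dl[ut] - Dh[ut]))
  structure(list(pairs = pairs, max_distortion = max(pairs$distortion),
                 avg_distortion = mean(pairs$distortion), metric = metric,
                 low_metric = low_metric, method = method),
            class = "distortion_report")
}

#' @export
print.distortion_report <- function(x, ...) {
  cat(sprintf("distortion report (%s): %d pairs, max = %g, avg = %g\n",
              if (is.na(x$method)) "projection" else x$method,
              nrow(x$pairs), x$max_distortion, x$avg_distortion))
  invisible(x)
}

#' @describeIn distortion_summary Per-pair distortions as a tibble.
#' @param x A `distortion_report`.
#' @param ... Unused.
#' @export
tidy.distortion_report <- function(x, ...) x$pairs

#' @describeIn distortion_summary One-row summary (max, avg, metrics, method).
#' @export
glance.distortion_report <- function(x, ...) {
  tibble::tibble(method = x$method, n_pairs = nrow(x$pairs),
                 max_distortion = x$max_distortion,
                 avg_distortion = x$avg_distortion,
                 metric = x$metric, low_metric = x$low_metric)
}

#' Classical (Torgerson) multidimensional scaling
#'
#' Double-centers the squared distance matrix, takes the top-k non-negative
#' eigenpairs and scales eigenvectors by the square roots of their
#' eigenvalues. Deterministic up to sign; signs are fixed by making each
#' axis's largest-magnitude loading positive. Axes beyond the matrix's
#' positive rank are zero.
#'
#' @param D N x N distance matrix.
#' @param k Target dimension.
#' @return N x k coordinate matrix.
#' @export
classical_mds <- function(D, k = 2L) {
  D <- as.matrix(D)
  if (max(D) <= 0) abort("distance matrix has no positive entries")
  if (nrow(D) < k + 1) abort(sprintf("need at least %d points for k = %d", k + 1, k))
  fit <- suppressWarnings(cmdscale(as.dist(D), k = k, eig = TRUE))
  pts <- fit$points
  if (ncol(pts) < k) { # rank deficiency: pad trailing axes with zeros
    pts <- cbind(pts, matrix(0, nrow(pts), k - ncol(pts)))
  }
  for (a in seq_len(k)) {
    lead <- which.max(abs(pts[, a]))
    if (pts[lead, a] < 0) pts[, a] <- -pts[, a]
  }
  unname(pts)
}

#' Gaussian random projection
#'
#' Multiplies the data by an m x k matrix of independent standard normal
#' entries scaled by `1/sqrt(k)` (the Johnson–Lindenstrauss construction, so
#' squared distances are preserved in expectation). Deterministic per seed.
#'
#' @param data N x m events-by-channels table or matrix.
#' @param k Target dimension (`k < m`).
#' @param seed Master seed (random-projection substream).
#' @return N x k coordinate matrix.
#' @export
random_projection <- function(data, k = 2L, seed = 1L) {
  m <- as_cloud_matrix(data)
  if (k >= ncol(m)) abort(sprintf("`k` must be below the data dimension %d", ncol(m)))
  P <- withr::with_seed(substream_seed(seed, "rp"),
                        matrix(rnorm(ncol(m) * k), ncol(m), k)) / sqrt(k)
  unname(m %*% P)
}

#' Ratio summary of baseline vs synthesis distortions
#'
#' Element-wise `baseline / synthesis` ratios with summary statistics, using
#' truncation (not rounding) to the requested number of decimals — the
#' convention the published comparison tables follow (per-row ratios to 3
#' decimals, summary statistics to 2).
#'
#' @param baseline,synthesis Equal-length positive numeric vectors (e.g. max
#'   distortions per dataset for MDS and for the synthesis).
#' @param digits_row Decimals kept (by truncation) per ratio.
#' @param digits_summary Decimals kept (by truncation) for mean/min/max.
#' @return List with `ratios` (tibble) and truncated `mean`, `min`, `max`.
#' @export
ratio_summary <- function(baseline, synthesis, digits_row = 3L,
                          digits_summary = 2L) {
  if (length(baseline) != length(synthesis)) abort("length mismatch")
  if (any(synthesis <= 0)) abort("synthesis distortions must be positive")
  ratios <- truncate_decimals(baseline / synthesis, digits_row)
  list(
    ratios = tibble::tibble(baseline = baseline, synthesis = synthesis,
                            ratio = ratios),
    mean = truncate_decimals(mean(ratios), digits_summary),
    min = truncate_decimals(min(ratios), digits_summary),
    max = truncate_decimals(max(ratios), digits_summary))
}

truncate_decimals <- function(x, digits) floor(x * 10^digits) / 10^digits

#' Compare synthesis, MDS and random projection on one dataset
#'
#' Subsamples the events (default 10, the size at which exhaustive
#' benchmarking of all three projections is routine), computes the distance
#' matrix in `metric`, runs each requested method on the same subsample, and
#' reports max/avg distortion per method plus the ratio of each baseline's
#' max distortion to the synthesis's. Synthesis coordinates are rescaled to
#' data units before distortion is measured; MDS and random projection are
#' evaluated on their raw (unquantized) outputs.
#'
#' @param data Events-by-channels table or matrix.
#' @param methods Subset of `c("sanjay", "mds", "rp")`.
#' @param sample_size Subsample size (`NULL` to use all events).
#' @param target_dim Embedding dimension.
#' @param bits,block,node_budget Synthesis parameters.
#' @param metric High-dimensional metric.
#' @param seed Master seed.
#' @param dataset_id Identifier written into the table.
#' @return A tibble with columns `dataset_id`, `method`, `max_distortion`,
#'   `avg_distortion`, `ratio_vs_sanjay` (NA when the synthesis was not run).
#' @export
compare_methods <- function(data, methods = c("sanjay", "mds", "rp"),
                            sample_size = 10L, target_dim = 2L, bits = 10L,
                            block = 2L, metric = "manhattan", seed = 1L,
                            node_budget = 5e5, dataset_id = 1L) {
  methods <- match.arg(methods, c("sanjay", "mds", "rp"), several.ok = TRUE)
  metric <- check_metric(metric)
  m <- as_cloud_matrix(data)
  if (!is.null(sample_size) && sample_size < nrow(m)) {
    m <- as_cloud_matrix(subsample_points(m, sample_size, seed = seed))
  }
  D <- pairwise_dist(m, metric)
  reports <- list()
  if ("sanjay" %in% methods) {
    fit <- find_min_epsilon(D, target_dim = target_dim, bits = bits,
                            block = block, band = "additive",
                            node_budget = node_budget)
    low <- fit$embedding$coords / fit$embedding$scale
    reports$sanjay <- distortion_summary(D, low, metric = metric,
                                         high_is_dist = TRUE,
                                         method = "sanjay")
  }
  if ("mds" %in% methods) {
    reports$mds <- distortion_summary(D, classical_mds(D, target_dim),
                                      metric = metric, high_is_dist = TRUE,
                                      method = "mds")
  }
  if ("rp" %in% methods) {
    reports$rp <- distortion_summary(D, random_projection(m, target_dim, seed),
                                     metric = metric, high_is_dist = TRUE,
                                     method = "rp")
  }
  tab <- dplyr::bind_rows(lapply(reports, glance))
  tab <- dplyr::mutate(tab, dataset_id = dataset_id, .before = 1)
  san_max <- if ("sanjay" %in% names(reports))
    reports$sanjay$max_distortion else NA_real_
  tab$ratio_vs_sanjay <- ifelse(
    tab$method == "sanjay", NA_real_,
    truncate_decimals(tab$max_distortion / san_max, 3L))
  dplyr::select(tab, "dataset_id", "method", "max_distortion",
                "avg_distortion", "ratio_vs_sanjay")
}
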