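#' Manhattan distance between two channel vectors
#'
#' Sum of absolute coordinate differences, the metric used to connect cells
#' in the thresholded cell-similarity network.
#'
#' @param u,v Numeric vectors of equal length.
#' @return A non-negative scalar.
#' @examples
#' manhattan_distance(c(1, 2), c(3, 1)) # 3
#' @export
manhattan_distance <- function(u, v) {
  if (length(u) != length(v)) {
    abort(sprintf("length mismatch: %d vs %d", length(u), length(v)))
  }
  sum(abs(u - v))
}

#' Build a thresholded flow cytometry network (T-FCN)
#'
#' Nodes are cells; an undirected edge connects two cells exactly when the
#' Manhattan distance between their channel vectors is at most `threshold`
#' (closed inequality). As the threshold sweeps from 0 to the data diameter
#' the network moves from N isolated nodes to a clique of N nodes.
#'
#' @param data Events-by-channels table or matrix.
#' @param threshold Non-negative distance threshold `T`.
#' @param D Optional precomputed Manhattan distance matrix (recomputed when
#'   omitted).
#' @return A `tfcn` object: the igraph graph plus the threshold and data.
#' @export
build_tfcn <- function(data, threshold, D = NULL) {
  m <- as_cloud_matrix(data)
  if (!is.numeric(threshold) || length(threshold) != 1 || threshold < 0) {
    abort("`threshold` must be a single non-negative number")
  }
  if (is.null(D)) D <- pairwise_dist(m, "manhattan")
  adj <- D <= threshold
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  structure(list(graph = g, threshold = threshold, n_nodes = nrow(m),
                 data = m),
            class = "tfcn")
}

#' @export
print.tfcn <- function(x, ...) {
  cat(sprintf("T-FCN: %d cells, %d edges, threshold T = %g\n",
              x$n_nodes, igraph::ecount(x$graph), x$threshold))
  invisible(x)
}

#' @describeIn build_tfcn Edge list as a tibble of 0-based node index pairs.
#' @param x A `tfcn` object.
#' @param ... Unused.
#' @export
tidy.tfcn <- function(x, ...) {
  e <- igraph::as_edgelist(x$graph, names = FALSE)
  tibble::tibble(from = as.integer(e[, 1]) - 1L, to = as.integer(e[, 2]) - 1L)
}

#' Shannon entropy of the degree distribution
#'
#' Natural-log entropy of the empirical distribution of node degrees. Zero
#' for both the empty network and the clique (all degrees identical); maximal
#' when degrees are spread over many values — the criterion used to pick the
#' most informative threshold.
#'
#' @param net A `tfcn` object.
#' @return Non-negative entropy in nats.
#' @export
degree_entropy <- function(net) {
  stopifnot(inherits(net, "tfcn"))
  entropy_of(igraph::degree(net$graph))
}

entropy_of <- function(values) {
  p <- table(values) / length(values)
  -sum(p * log(p))
}

#' Select the network threshold by entropy maximization
#'
#' Scans candidate thresholds and returns the one whose T-FCN maximizes the
#' entropy of a topological property distribution. Ties break toward the
#' smallest threshold. Two properties are available: the component-size
#' distribution (default) and the degree distribution. The component-size
#' criterion is the default because on multi-population clouds the
#' degree-entropy optimum tends to sit at partially population-bridging
#' thresholds (bridging diversifies degrees), whereas the component-size
#' optimum stays below the inter-population gap, keeping the network's
#' community structure informative.
#'
#' @param data Events-by-channels table or matrix.
#' @param candidates Numeric candidate thresholds, or `"auto"`: the distinct
#'   pairwise distances when there are at most `grid_size` of them, otherwise
#'   `grid_size` quantiles of the pairwise-distance distribution.
#' @param property `"component_size"` or `"degree"` — whose distribution's
#'   entropy is maximized.
#' @param grid_size Size of the automatic candidate grid.
#' @return The selected threshold (scalar, with the scanned grid and
#'   entropies attached as attribute `"scan"`).
#' @export
select_threshold <- function(data, candidates = "auto",
                             property = c("component_size", "degree"),
                             grid_size = 64L) {
  property <- match.arg(property)
  m <- as_cloud_matrix(data)
  D <- pairwise_dist(m, "manhattan")
  pd <- D[upper.tri(D)]
  if (identical(candidates, "auto")) {
    u <- sort(unique(pd))
    candidates <- if (length(u) <= grid_size) u else {
      unique(as.numeric(quantile(pd, probs = seq(0, 1, length.out = grid_size),
                                 names = FALSE)))
    }
  }
  if (length(candidates) == 0) abort("empty candidate threshold set")
  candidates <- sort(candidates)
  ent <- vapply(candidates, function(T) {
    deg <- rowSums(D <= T) - 1L # closed inequality, minus self
    if (property == "degree") {
      entropy_of(deg)
    } else {
      adj <- D <= T
      diag(adj) <- FALSE
      g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
      entropy_of(igraph::components(g)$csize)
    }
  }, numeric(1))
  best <- candidates[which.max(ent)] # which.max takes the first (smallest) tie
  attr(best, "scan") <- tibble::tibble(threshold = candidates, entropy = ent)
  best
}

#' Detect communities by random-walk agglomeration
#'
#' Walktrap community detection: nodes whose short random walks have similar
#' visit profiles are merged agglomeratively, and the merge sequence is cut at
#' the modularity-maximizing level. Isolated nodes become singleton
#' communities; connected components are never merged across.
#'
#' @param net A `tfcn` object.
#' @param walk_length Random-walk length (default 4, the customary Walktrap
#'   setting).
#' @param seed Master seed (the algorithm is deterministic; the seed is fanned
#'   to a named substream for interface consistency).
#' @return A `community_partition` object with `labels` (length-N integer
#'   vector of community ids `1..n`) and `n`.
#' @export
detect_communities <- function(net, walk_length = 4L, seed = 1L) {
  stopifnot(inherits(net, "tfcn"))
  if (walk_length < 1) abort("`walk_length` must be at least 1")
  g <- net$graph
  deg <- igraph::degree(g)
  labels <- integer(net$n_nodes)
  keep <- which(deg > 0)
  if (length(keep) > 0) {
    sub <- igraph::induced_subgraph(g, keep)
    wt <- withr::with_seed(substream_seed(seed, "walks"),
                           igraph::cluster_walktrap(sub, steps = walk_length))
    labels[keep] <- igraph::membership(wt)
  }
  iso <- which(deg == 0)
  if (length(iso) > 0) {
    labels[iso] <- max(labels) + seq_along(iso)
  }
  labels <- match(labels, sort(unique(labels))) # relabel onto 1..n
  structure(list(labels = as.integer(labels), n = length(unique(labels))),
            class = "community_partition")
}

#' @export
print.community_partition <- function(x, ...) {
  cat(sprintf("community partition: %d communities over %d cells\n",
              x$n, length(x$labels)))
  invisible(x)
}

#' @describeIn detect_communities Partition as a tibble of cell / community.
#' @param x A `community_partition`.
#' @param ... Unused.
#' @export
tidy.community_partition <- function(x, ...) {
  tibble::tibble(cell = seq_along(x$labels), community = x$labels)
}
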