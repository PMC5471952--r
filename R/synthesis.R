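#' Quantize a distance matrix onto the b-bit grid
#'
#' Coordinates are synthesized as unsigned `b`-bit integers, so target
#' distances are mapped to grid units by `scale = (2^b - 1) / max(D)` and
#' rounded. The scale factor converts grid units back to data units.
#'
#' @param D Symmetric non-negative distance matrix.
#' @param bits Bit width `b >= 2` of the synthesized coordinates.
#' @return List with `D_int` (rounded integer matrix) and `scale`.
#' @export
scale_distances_to_grid <- function(D, bits) {
  if (bits < 2) abort("`bits` must be at least 2")
  D <- as.matrix(D)
  mx <- max(D)
  if (mx <= 0) abort("distance matrix has no positive entries; nothing to scale")
  scale <- (2^bits - 1) / mx
  D_int <- round(D * scale)
  diag(D_int) <- 0
  list(D_int = D_int, scale = scale)
}

#' Reachable squared-distance interval between two partially fixed points
#'
#' During refinement a point's coordinate is a fixed `s`-bit prefix followed
#' by r = b - s free bits, so each axis ranges over
#' `[prefix * 2^r, prefix * 2^r + 2^r - 1]`. The minimum and maximum squared
#' Euclidean distance over all completions is computed by interval arithmetic
#' per axis and summed; when both points are fully fixed `lo == hi` is the
#' exact squared distance.
#'
#' @param prefix_i,prefix_j Integer vectors: the per-axis prefixes of the two
#'   points (equal length `k`).
#' @param bits Total coordinate width `b`.
#' @param s Number of bits already fixed (`0 <= s <= b`).
#' @return List with integers `lo` and `hi`, `lo <= hi`.
#' @export
subsquare_distance_bounds <- function(prefix_i, prefix_j, bits, s) {
  if (length(prefix_i) != length(prefix_j)) {
    abort("prefix width mismatch between the two points")
  }
  if (s < 0 || s > bits) abort("`s` must lie in [0, bits]")
  r <- bits - s
  span <- 2^r - 1
  lo_i <- prefix_i * 2^r; hi_i <- lo_i + span
  lo_j <- prefix_j * 2^r; hi_j <- lo_j + span
  dmin <- pmax(0, pmax(lo_i, lo_j) - pmin(hi_i, hi_j))
  dmax <- pmax(hi_i - lo_j, hi_j - lo_i)
  list(lo = sum(dmin^2), hi = sum(dmax^2))
}

# Per-pair squared-distance band matrices for the two tolerance semantics:
# multiplicative (the squared-band reading of the refinement constraint) and
# additive (|r - D| <= t, the semantics of the existential distance-
# preservation formula and of the reported distortion statistic; t is
# epsilon * max(D_int) grid units so epsilon stays on (0, 1]).
band_matrices <- function(D_int, epsilon, band) {
  D_int <- as.matrix(D_int)
  if (band == "multiplicative") {
    list(lo = (1 - epsilon) * D_int^2, hi = (1 + epsilon) * D_int^2,
         halfwidth = NA_real_)
  } else {
    t <- epsilon * max(D_int)
    list(lo = pmax(D_int - t, 0)^2, hi = (D_int + t)^2, halfwidth = t)
  }
}

#' Solve one bit-refinement step
#'
#' Given every point's current `s`-bit prefix, finds one `l`-bit block per
#' point per axis such that for every pair `i != j` the reachable
#' squared-distance interval after appending still intersects the tolerance
#' band — `[(1 - epsilon) D[i,j]^2, (1 + epsilon) D[i,j]^2]` for the
#' multiplicative semantics, or `|r - D[i,j]| <= epsilon * max(D)` for the
#' additive semantics. The decision problem is solved by a complete
#' backtracking search with interval pruning; among satisfying assignments
#' the search is biased toward sub-squares whose midpoints fit the target
#' distances.
#'
#' @param prefixes d x k integer matrix of current prefixes.
#' @param D_int d x d integer target distance matrix (grid units).
#' @param bits,s,l Coordinate width, bits fixed so far, and block size.
#' @param epsilon Band half-width parameter on (0, 1].
#' @param band `"multiplicative"` (squared-distance band) or `"additive"`
#'   (absolute distance band, half-width `epsilon * max(D_int)` grid units).
#' @param node_budget Search-node budget; exhaustion is reported as a
#'   `"budget"` status distinguishable from `"unsat"`.
#' @param symmetry_break Restrict the first point's first block to the lower
#'   half of each axis (valid by per-axis reflection symmetry).
#' @param rule `"interval"` (default) intersects the reachable
#'   squared-distance interval with the band, so a selected sub-square always
#'   retains completions able to satisfy both bounds; `"literal"` applies
#'   both bounds to the maximum reachable squared distance — the selection
#'   constraint exactly as printed in the refinement recurrence, kept for
#'   fidelity experiments (it can accept sub-squares whose every completion
#'   violates the lower bound). The two coincide at the final iteration.
#' @return List with `status` (`"sat"`, `"unsat"` or `"budget"`) and, when
#'   sat, `blocks` (d x k integer matrix of the appended l-bit blocks).
#' @export
solve_refinement_step <- function(prefixes, D_int, bits, s, l, epsilon,
                                  band = c("multiplicative", "additive"),
                                  node_budget = 5e5, symmetry_break = TRUE,
                                  rule = c("interval", "literal")) {
  band <- match.arg(band)
  rule <- match.arg(rule)
  if (l < 1 || l > bits - s) abort("`l` must lie in [1, bits - s]")
  if (epsilon <= 0) abort("`epsilon` must be positive")
  D2 <- (as.matrix(D_int))^2
  bm <- band_matrices(D_int, epsilon, band)
  res <- cpp_solve_step(prefixes, as.integer(bits), as.integer(s),
                        as.integer(l), D2, bm$lo, bm$hi, node_budget,
                        symmetry_break, rule == "literal")
  status <- c("sat", "unsat", "budget")[res$status + 1L]
  list(status = status, blocks = if (status == "sat") res$blocks else NULL,
       nodes = res$nodes)
}

#' Synthesize a grid embedding by iterative bit refinement
#'
#' The core synthesis routine: target distances are quantized onto the b-bit
#' grid, every coordinate starts fully free, and `b / l` refinement steps fix
#' `l` high-order bits per axis at a time, each step solved as a decision
#' problem ([solve_refinement_step()]). On success the fully fixed coordinates
#' satisfy the tolerance band for every pair — multiplicative semantics:
#' `(1 - eps) D^2 <= ||R_i - R_j||^2 <= (1 + eps) D^2`; additive semantics:
#' `| ||R_i - R_j|| - D | <= eps * max(D)` — asserted post hoc before
#' returning.
#'
#' @param D Distance matrix in data units (e.g. from
#'   [pairwise_distance_matrix()]).
#' @param target_dim Embedding dimension k, 2 or 3.
#' @param bits Coordinate width b (default 10).
#' @param block Bits fixed per iteration l (default 2; must divide b).
#' @param epsilon Band half-width parameter.
#' @param band Tolerance semantics; see [solve_refinement_step()]. The
#'   multiplicative band is the squared-distance reading of the refinement
#'   constraint; the additive band matches the distortion statistic the
#'   method is evaluated by and is what the full pipeline optimizes.
#' @param node_budget Per-step search budget.
#' @param symmetry_break See [solve_refinement_step()].
#' @return On success a `grid_embedding` object (`coords`: d x k integer
#'   matrix, `scale`, `epsilon_used`, `band`, `band_halfwidth` (grid units,
#'   additive band only), `iterations`, `bits`); on failure an object of
#'   class `sanjay_infeasible` recording the step reached and whether the
#'   failure was UNSAT or budget exhaustion.
#' @export
synthesize_embedding <- function(D, target_dim = 2L, bits = 10L, block = 2L,
                                 epsilon = 0.1,
                                 band = c("multiplicative", "additive"),
                                 node_budget = 5e5, symmetry_break = TRUE) {
  band <- match.arg(band)
  if (!target_dim %in% c(2L, 3L)) abort("`target_dim` must be 2 or 3")
  if (bits %% block != 0) abort("`bits` must be divisible by `block`")
  D <- as.matrix(D)
  if (nrow(D) < 2) abort("need at least two points")
  sc <- scale_distances_to_grid(D, bits)
  D_int <- sc$D_int
  iterations <- bits %/% block
  bm <- band_matrices(D_int, epsilon, band)
  d <- nrow(D)

  # The backtracking engine is sensitive to the order points are assigned in
  # and to which satisfying model the value ordering steers it toward; a
  # dead end found under one strategy can take exponentially long to escape.
  # A portfolio of restarts keeps the search effective while preserving
  # completeness (a genuine UNSAT from any single attempt is conclusive):
  # first a geometrically hinted attempt whose value ordering follows a
  # classical-MDS configuration of the quantized distances (for
  # near-Euclidean-embeddable inputs the rounded hint already satisfies
  # tight bands), then pairwise-fit attempts under farthest-point, identity
  # and seeded shuffled orders.
  hint <- if (d >= target_dim + 1) {
    tryCatch({
      h <- classical_mds(D_int, target_dim)
      h <- sweep(h, 2, apply(h, 2, min), "-")
      pmax(pmin(h, 2^bits - 1), 0)
    }, error = function(e) NULL)
  }
  fp_ord <- farthest_point_order(D_int)
  attempts <- list()
  if (!is.null(hint)) {
    attempts <- list(list(ord = fp_ord, hint = TRUE),
                     list(ord = seq_len(d), hint = TRUE))
  }
  attempts <- c(attempts, list(list(ord = fp_ord, hint = FALSE),
                               list(ord = seq_len(d), hint = FALSE)))
  for (a in seq_len(6L)) {
    attempts[[length(attempts) + 1L]] <-
      list(ord = withr::with_seed(substream_seed(a, "solver"),
                                  sample.int(d)),
           hint = FALSE)
  }
  no_hint <- matrix(0, d, target_dim)
  status <- "budget"; res <- NULL; deepest <- 0L
  for (att in attempts) {
    ord <- att$ord
    bm_lo <- bm$lo[ord, ord, drop = FALSE]
    bm_hi <- bm$hi[ord, ord, drop = FALSE]
    h <- no_hint
    if (att$hint) {
      h <- hint[ord, , drop = FALSE]
      if (symmetry_break) {
        # reflect the hint so the first-assigned point sits in the lower
        # half of each axis, matching the symmetry-breaking constraint
        for (a in seq_len(target_dim)) {
          if (h[1, a] > (2^bits - 1) / 2) h[, a] <- (2^bits - 1) - h[, a]
        }
      }
    }
    attempt <- cpp_synthesize(d, as.integer(target_dim), as.integer(bits),
                              as.integer(block), bm_lo, bm_hi,
                              node_budget / length(attempts), symmetry_break,
                              h, att$hint)
    st <- c("sat", "unsat", "budget")[attempt$status + 1L]
    deepest <- max(deepest, attempt$deepest)
    if (st == "sat") {
      res <- attempt
      res$coords <- attempt$coords[order(ord), , drop = FALSE]
      status <- "sat"
      break
    }
    if (st == "unsat") { status <- "unsat"; break }
  }
  if (status != "sat") {
    return(structure(list(status = status, s_reached = deepest,
                          iteration = deepest %/% block,
                          epsilon = epsilon, band = band),
                     class = "sanjay_infeasible"))
  }
  coords <- res$coords
  check <- embedding_band_check(coords, D_int, epsilon, band)
  if (!check$ok) {
    abort(sprintf(
      "internal error: synthesized coordinates violate the epsilon band for pair (%d, %d)",
      check$i, check$j))
  }
  structure(list(coords = coords, bits = bits, block = block,
                 scale = sc$scale, epsilon_used = epsilon, band = band,
                 band_halfwidth = band_matrices(D_int, epsilon, band)$halfwidth,
                 iterations = iterations, D_int = D_int,
                 target_dim = target_dim),
            class = "grid_embedding")
}

# Farthest-point traversal: start from the globally farthest pair, then
# repeatedly append the point maximizing its minimum distance to the chosen
# set. Placing the frame-defining points first makes the search robust.
farthest_point_order <- function(D) {
  d <- nrow(D)
  if (d <= 2) return(seq_len(d))
  start <- which(D == max(D), arr.ind = TRUE)[1, ]
  ord <- c(start[1], start[2])
  remaining <- setdiff(seq_len(d), ord)
  while (length(remaining) > 0) {
    mins <- vapply(remaining, function(i) min(D[i, ord]), numeric(1))
    nxt <- remaining[which.max(mins)]
    ord <- c(ord, nxt)
    remaining <- setdiff(remaining, nxt)
  }
  as.integer(ord)
}

# Exhaustive post-hoc verification of the tolerance band.
embedding_band_check <- function(coords, D_int, epsilon, band) {
  G2 <- as.matrix(dist(coords))^2
  bm <- band_matrices(D_int, epsilon, band)
  lo_ok <- G2 >= bm$lo - 1e-9
  hi_ok <- G2 <= bm$hi + 1e-9
  bad <- which(!(lo_ok & hi_ok), arr.ind = TRUE)
  if (nrow(bad) == 0) list(ok = TRUE) else
    list(ok = FALSE, i = bad[1, 1], j = bad[1, 2])
}

#' @export
print.grid_embedding <- function(x, ...) {
  cat(sprintf(
    "grid embedding: %d points in %dD, %d-bit coordinates, epsilon = %g, scale = %g grid units per data unit\n",
    nrow(x$coords), x$target_dim, x$bits, x$epsilon_used, x$scale))
  invisible(x)
}

#' @export
print.sanjay_infeasible <- function(x, ...) {
  cat(sprintf("synthesis infeasible (%s) at epsilon = %g, iteration %d (s = %d bits fixed)\n",
              x$status, x$epsilon, x$iteration, x$s_reached))
  invisible(x)
}

#' @describeIn synthesize_embedding Grid coordinates as a tibble (grid and
#'   data units).
#' @param x A `grid_embedding`.
#' @param ... Unused.
#' @export
tidy.grid_embedding <- function(x, ...) {
  coords <- x$coords
  axes <- c("x", "y", "z")[seq_len(ncol(coords))]
  out <- tibble::as_tibble(as.data.frame(coords))
  names(out) <- paste0(axes, "_grid")
  for (a in seq_along(axes)) out[[axes[a]]] <- coords[, a] / x$scale
  dplyr::bind_cols(tibble::tibble(point = seq_len(nrow(coords))), out)
}

#' @describeIn synthesize_embedding One-row summary: size, epsilon, scale and
#'   realized additive distortion (grid units).
#' @export
glance.grid_embedding <- function(x, ...) {
  G <- as.matrix(dist(x$coords))
  err <- abs(G - x$D_int)[upper.tri(G)]
  tibble::tibble(d = nrow(x$coords), target_dim = x$target_dim,
                 bits = x$bits, epsilon_used = x$epsilon_used,
                 scale = x$scale, iterations = x$iterations,
                 max_distortion_grid = max(err),
                 avg_distortion_grid = mean(err))
}

#' Smallest feasible band width by bisection
#'
#' Feasibility of the synthesis band is monotone in `epsilon` (a wider band
#' only relaxes constraints), so the smallest workable `epsilon` on (0, 1] is
#' found by doubling from `eps_init` until a synthesis succeeds, then
#' bisecting the bracket down to `tol`. Budget-exhausted steps count as
#' failures, keeping the search conservative. With the additive band the
#' minimized quantity is directly the worst-pair additive distortion (in
#' units of `epsilon * max(D_int)` grid units).
#'
#' @inheritParams synthesize_embedding
#' @param tol Bisection tolerance on epsilon.
#' @param eps_init Initial (optimistic) epsilon for the doubling phase.
#' @return List with `epsilon` (the smallest feasible value found) and
#'   `embedding` (its `grid_embedding`).
#' @export
find_min_epsilon <- function(D, target_dim = 2L, bits = 10L, block = 2L,
                             band = c("multiplicative", "additive"),
                             tol = 0.01, eps_init = 0.025,
                             node_budget = 5e5) {
  band <- match.arg(band)
  if (tol <= 0) abort("`tol` must be positive")
  try_eps <- function(eps) synthesize_embedding(
    D, target_dim = target_dim, bits = bits, block = block, epsilon = eps,
    band = band, node_budget = node_budget)
  eps <- eps_init
  res <- try_eps(eps)
  while (inherits(res, "sanjay_infeasible") && eps < 1) {
    eps <- min(1, eps * 2)
    res <- try_eps(eps)
  }
  if (inherits(res, "sanjay_infeasible")) {
    abort(sprintf(
      "synthesis infeasible even at epsilon = 1 (failed %s at iteration %d); the distance matrix may violate the triangle inequality or the grid may be too coarse",
      res$status, res$iteration))
  }
  hi <- eps; best <- res
  lo <- if (eps == eps_init) 0 else eps / 2
  while (hi - lo > tol) {
    mid <- (hi + lo) / 2
    res <- try_eps(mid)
    if (inherits(res, "sanjay_infeasible")) lo <- mid
    else { hi <- mid; best <- res }
  }
  list(epsilon = hi, embedding = best)
}

#' Emit one refinement step as an SMT-LIB 2 (QF_BV) query
#'
#' Writes the decision problem solved by [solve_refinement_step()] as
#' standard SMT-LIB 2 text over bit-vectors, so a conformant external solver
#' can be used as an alternative backend: one `l`-bit unknown per point per
#' axis, with the reachable-interval band constraints expressed in unsigned
#' bit-vector arithmetic at a width wide enough to avoid overflow.
#'
#' @inheritParams solve_refinement_step
#' @return A character scalar of SMT-LIB 2 text (also invisibly returned when
#'   `path` is given).
#' @param path Optional file to write the query to.
#' @export
encode_refinement_smtlib <- function(prefixes, D_int, bits, s, l, epsilon,
                                     path = NULL) {
  d <- nrow(prefixes); k <- ncol(prefixes)
  r <- bits - s; rl <- r - l
  w <- 2L * bits + 4L # working width: squared sums stay below 2^(2b+2)
  bv <- function(val, width) sprintf("(_ bv%.0f %d)", val, width)
  ext <- function(x, from) sprintf("((_ zero_extend %d) %s)", w - from, x)
  lines <- c("(set-logic QF_BV)",
             sprintf("; refinement step: d = %d, k = %d, b = %d, s = %d, l = %d, epsilon = %g",
                     d, k, bits, s, l, epsilon))
  var <- function(i, a) sprintf("A_%d_%d", i, a)
  for (i in seq_len(d)) for (a in seq_len(k)) {
    lines <- c(lines, sprintf("(declare-const %s (_ BitVec %d))", var(i, a), l))
  }
  # lo/hi endpoints of each point-axis interval, at width w
  lo_expr <- function(i, a) {
    base <- bv(prefixes[i, a] * 2^(r) , w) # prefix shifted past r free bits
    sprintf("(bvadd %s (bvshl %s %s))", base, ext(var(i, a), l),
            bv(rl, w))
  }
  for (i in seq_len(d)) for (a in seq_len(k)) {
    lines <- c(lines,
      sprintf("(define-fun lo_%d_%d () (_ BitVec %d) %s)", i, a, w, lo_expr(i, a)),
      sprintf("(define-fun hi_%d_%d () (_ BitVec %d) (bvadd lo_%d_%d %s))",
              i, a, w, i, a, bv(2^rl - 1, w)))
  }
  # scale the band by 2^dig to express (1 +/- eps) with integer arithmetic
  dig <- 20L
  lo_f <- floor((1 - epsilon) * 2^dig); hi_f <- ceiling((1 + epsilon) * 2^dig)
  ws <- w + dig + 2L
  for (i in seq_len(d)) for (j in seq_len(d)) {
    if (j <= i) next
    dmin <- sprintf(
      "(ite (bvult hi_%d_%s lo_%d_%s) (bvsub lo_%d_%s hi_%d_%s) (ite (bvult hi_%d_%s lo_%d_%s) (bvsub lo_%d_%s hi_%d_%s) %s))",
      i, "%a%", j, "%a%", j, "%a%", i, "%a%",
      j, "%a%", i, "%a%", i, "%a%", j, "%a%", bv(0, w))
    dmax <- sprintf(
      "(ite (bvult (bvsub hi_%d_%s lo_%d_%s) (bvsub hi_%d_%s lo_%d_%s)) (bvsub hi_%d_%s lo_%d_%s) (bvsub hi_%d_%s lo_%d_%s))",
      j, "%a%", i, "%a%", i, "%a%", j, "%a%",
      i, "%a%", j, "%a%", j, "%a%", i, "%a%")
    sq <- function(e) sprintf("(bvmul %s %s)", e, e)
    lo_terms <- hi_terms <- character(k)
    for (a in seq_len(k)) {
      lo_terms[a] <- sq(gsub("%a%", a, dmin, fixed = TRUE))
      hi_terms[a] <- sq(gsub("%a%", a, dmax, fixed = TRUE))
    }
    sum_expr <- function(terms) if (k == 1) terms else
      sprintf("(bvadd %s)", paste(terms, collapse = " "))
    wide <- function(e) sprintf("((_ zero_extend %d) %s)", ws - w, e)
    t2 <- D_int[i, j]^2
    lines <- c(lines,
      sprintf("(assert (bvule (bvmul %s %s) %s))",
              wide(sum_expr(lo_terms)), bv(2^dig, ws), bv(hi_f * t2, ws)),
      sprintf("(assert (bvuge (bvmul %s %s) %s))",
              wide(sum_expr(hi_terms)), bv(2^dig, ws), bv(lo_f * t2, ws)))
  }
  lines <- c(lines, "(check-sat)", "(get-model)")
  txt <- paste(lines, collapse = "\n")
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}
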