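test_that("distance quantization scales the largest distance to the grid edge", {
  D <- matrix(c(0, 100, 100, 0), 2)
  sc <- scale_distances_to_grid(D, 8)
  expect_equal(sc$scale, 2.55)
  expect_equal(max(sc$D_int), 255)
  # identity scaling when max(D) already equals the grid edge
  D2 <- matrix(c(0, 255, 255, 0), 2)
  expect_equal(scale_distances_to_grid(D2, 8)$D_int, round(D2))
  # quantization bound: |D_int / scale - D| <= 0.5 / scale elementwise
  Dr <- as.matrix(dist(random_cloud(6, 3, seed = 2)))
  scr <- scale_distances_to_grid(Dr, 10)
  expect_true(all(abs(scr$D_int / scr$scale - Dr) <= 0.5 / scr$scale + 1e-12))
  expect_error(scale_distances_to_grid(matrix(0, 2, 2), 8), "no positive")
  expect_error(scale_distances_to_grid(D, 1), "at least 2")
})

test_that("sub-square bounds equal exhaustive enumeration over completions", {
  # fully fixed points: lo = hi = exact squared distance
  ex <- subsquare_distance_bounds(c(1, 2), c(4, 6), bits = 3, s = 3)
  expect_equal(ex$lo, 25)
  expect_equal(ex$hi, 25)
  # 1D, b = 2, prefixes 0 vs 1 with one free bit: ranges {0,1} vs {2,3}
  b1 <- subsquare_distance_bounds(0, 1, bits = 2, s = 1)
  expect_equal(b1$lo, 1)
  expect_equal(b1$hi, 9)

  # randomized battery against brute-force enumeration, r <= 3
  enumerate_bounds <- function(pi, pj, bits, s) {
    r <- bits - s
    comps <- expand.grid(rep(list(0:(2^r - 1)), 2 * length(pi)))
    k <- length(pi)
    d2 <- apply(comps, 1, function(f) {
      ci <- pi * 2^r + f[seq_len(k)]
      cj <- pj * 2^r + f[k + seq_len(k)]
      sum((ci - cj)^2)
    })
    list(lo = min(d2), hi = max(d2))
  }
  withr::with_seed(99, {
    for (case in 1:60) {
      bits <- sample(2:5, 1)
      s <- sample.int(bits, 1) # r = bits - s <= 3 by construction
      r <- bits - s
      if (r > 3) s <- bits - 3
      k <- sample(1:2, 1)
      pi <- sample(0:(2^s - 1), k, replace = TRUE)
      pj <- sample(0:(2^s - 1), k, replace = TRUE)
      got <- subsquare_distance_bounds(pi, pj, bits, s)
      want <- enumerate_bounds(pi, pj, bits, s)
      expect_equal(got$lo, want$lo)
      expect_equal(got$hi, want$hi)
    }
  })
  expect_error(subsquare_distance_bounds(c(1, 2), 1, 4, 2), "width mismatch")
})

test_that("one refinement step solves trivial SAT and UNSAT instances", {
  # two free points can realize any single distance within the grid
  pref <- matrix(0L, 2, 2)
  D_int <- matrix(c(0, 40, 40, 0), 2)
  st <- solve_refinement_step(pref, D_int, bits = 6, s = 0, l = 2,
                              epsilon = 0.3)
  expect_equal(st$status, "sat")
  expect_true(all(st$blocks >= 0 & st$blocks <= 3))

  # triangle-inequality violation is UNSAT at tight epsilon by the final step
  Dbad <- matrix(c(0, 40, 4, 40, 0, 4, 4, 4, 0), 3)
  res <- synthesize_embedding(Dbad, epsilon = 0.01, bits = 6, block = 2)
  expect_s3_class(res, "sanjay_infeasible")
  expect_equal(res$status, "unsat")

  # returned blocks satisfy the interval-band post-condition
  D3 <- matrix(8, 3, 3); diag(D3) <- 0
  st3 <- solve_refinement_step(matrix(0L, 3, 2), D3, bits = 6, s = 0, l = 2,
                               epsilon = 0.1)
  expect_equal(st3$status, "sat")
  for (i in 1:2) for (j in (i + 1):3) {
    bb <- subsquare_distance_bounds(st3$blocks[i, ], st3$blocks[j, ],
                                    bits = 6, s = 2)
    expect_lte(bb$lo, (1 + 0.1) * 64)
    expect_gte(bb$hi, (1 - 0.1) * 64)
  }
})

test_that("synthesized embeddings honor the band contract for both semantics", {
  pts <- planar_cloud(4, seed = 10)[, 1:2]
  D <- as.matrix(dist(pts))
  for (band in c("multiplicative", "additive")) {
    ge <- synthesize_embedding(D, epsilon = 0.1, bits = 8, block = 2,
                               band = band)
    expect_s3_class(ge, "grid_embedding")
    G2 <- as.matrix(dist(ge$coords))^2
    if (band == "multiplicative") {
      T2 <- ge$D_int^2
      expect_true(all(G2 >= (1 - 0.1) * T2 - 1e-9))
      expect_true(all(G2 <= (1 + 0.1) * T2 + 1e-9))
    } else {
      t <- ge$band_halfwidth
      expect_true(all(abs(sqrt(G2) - ge$D_int) <= t + 1e-9))
    }
    expect_true(all(ge$coords >= 0 & ge$coords <= 2^8 - 1))
  }
})

test_that("two points embed a single distance nearly exactly", {
  D <- matrix(c(0, 123.4, 123.4, 0), 2)
  fit <- find_min_epsilon(D, bits = 8, block = 2, tol = 0.005)
  # a lone distance is realizable up to quantization
  realized <- as.matrix(dist(fit$embedding$coords))[1, 2]
  expect_lt(abs(realized - fit$embedding$D_int[1, 2]), 2)
})

test_that("feasibility is monotone in epsilon", {
  inst_D <- as.matrix(dist(random_cloud(5, 12, seed = 4),
                           method = "manhattan"))
  for (band in c("multiplicative", "additive")) {
    fit <- find_min_epsilon(inst_D, bits = 8, block = 2, band = band)
    eps <- fit$epsilon
    again <- synthesize_embedding(inst_D, epsilon = min(1, 2 * eps),
                                  bits = 8, block = 2, band = band)
    expect_s3_class(again, "grid_embedding")
  }
})

test_that("duplicated structural points are co-located in the embedding", {
  pts <- rbind(c(0, 0), c(50, 10), c(50, 10), c(10, 70))
  D <- as.matrix(dist(pts))
  ge <- synthesize_embedding(D, epsilon = 0.05, bits = 6, block = 2,
                             band = "additive")
  expect_s3_class(ge, "grid_embedding")
  expect_equal(ge$coords[2, ], ge$coords[3, ])
})

test_that("the emitted SMT-LIB step encoding is well-formed QF_BV text", {
  D_int <- matrix(c(0, 12, 12, 0), 2)
  txt <- encode_refinement_smtlib(matrix(0L, 2, 2), D_int, bits = 6, s = 0,
                                  l = 2, epsilon = 0.2)
  expect_match(txt, "\\(set-logic QF_BV\\)")
  expect_match(txt, "declare-const A_1_1 \\(_ BitVec 2\\)")
  expect_match(txt, "\\(check-sat\\)")
  # balanced parentheses
  chars <- strsplit(txt, "")[[1]]
  depth <- cumsum((chars == "(") - (chars == ")"))
  expect_true(all(depth >= 0))
  expect_equal(depth[length(depth)], 0)
  # one unknown per point per axis, two band assertions per pair
  expect_equal(length(gregexpr("declare-const", txt)[[1]]), 4L)
  expect_equal(length(gregexpr("\\(assert ", txt)[[1]]), 2L)
})
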