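# Shared fixture builders; everything is generated in code at test time.

# Uniform random cloud on the raw intensity scale.
random_cloud <- function(n, m, seed = 1, lo = 0, hi = 1000) {
  withr::with_seed(seed, matrix(runif(n * m, lo, hi), n, m,
                                dimnames = list(NULL, paste0("c", seq_len(m)))))
}

# Distance matrix of a planted 2D configuration (Euclidean), optionally
# zero-padded to extra channels.
planar_cloud <- function(n, seed = 1, pad_to = NULL, lo = 0, hi = 1000) {
  pts <- random_cloud(n, 2, seed = seed, lo = lo, hi = hi)
  if (!is.null(pad_to) && pad_to > 2) {
    pts <- cbind(pts, matrix(0, n, pad_to - 2))
    colnames(pts) <- paste0("c", seq_len(ncol(pts)))
  }
  pts
}

# Three well-separated Gaussian blobs in m channels; returns cloud + labels.
blob_cloud <- function(n_per, m = 12, seed = 1, sep = 600, sd = 20) {
  withr::with_seed(seed, {
    centers <- matrix(runif(3 * m, 100, 900), 3, m)
    # push centers apart along each channel (upward, so nothing clips at 0)
    centers <- centers + sep * (seq_len(3) - 1)
    vals <- do.call(rbind, lapply(1:3, function(p) {
      matrix(rnorm(n_per * m, mean = rep(centers[p, ], each = n_per), sd = sd),
             n_per, m)
    }))
    vals <- pmax(vals, 0)
    colnames(vals) <- paste0("c", seq_len(m))
    list(cloud = vals, labels = rep(1:3, each = n_per))
  })
}

# Stable fingerprint of a numeric matrix, for distinctness checks.
digest_key <- function(m) paste(round(as.numeric(m), 6), collapse = ",")

# Max additive distortion (data units) between a distance matrix and a
# low-dimensional point set, recomputed independently of distortion_summary.
max_additive_distortion <- function(D, low) {
  Dl <- as.matrix(dist(low))
  max(abs(Dl - as.matrix(D)))
}
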