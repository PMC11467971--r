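# Independent oracles, deliberately avoiding the code paths they check.

# Extremize w' A w / w' M w over the unit sphere by seeded random search
# with shrinking local refinement; no eigendecomposition involved.
sphere_max_ratio <- function(a, m, n = 20000, iters = 30, seed = 1) {
  d <- nrow(a)
  ratio <- function(x) colSums(x * (a %*% x)) / colSums(x * (m %*% x))
  withr::with_seed(seed, {
    x <- matrix(rnorm(n * d), d)
    r <- ratio(x)
    best <- x[, which.max(r)]
    best_r <- max(r)
    rad <- 0.5
    for (i in seq_len(iters)) {
      p <- best + rad * matrix(rnorm(400 * d), d)
      rp <- ratio(p)
      if (max(rp) > best_r) {
        best <- p[, which.max(rp)]
        best_r <- max(rp)
      }
      rad <- rad * 0.75
    }
    best_r
  })
}

sphere_min_ratio <- function(a, m, ...) {
  # min of w'Aw / w'Mw = 1 - max of w'(M-A)w / w'Mw
  1 - sphere_max_ratio(m - a, m, ...)
}

# plug-in mutual information (bits) straight from a 2x2 joint count table
mi_from_table <- function(tab) {
  p <- tab / sum(tab)
  pr <- rowSums(p)
  pc <- colSums(p)
  s <- 0
  for (i in seq_len(nrow(p))) for (j in seq_len(ncol(p))) {
    if (p[i, j] > 0) s <- s + p[i, j] * log2(p[i, j] / (pr[i] * pc[j]))
  }
  s
}
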