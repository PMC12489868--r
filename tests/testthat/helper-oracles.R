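# Independent brute-force oracles used across the suite.  These deliberately
# use plain loops / pairwise enumeration so they share no code path with the
# package implementation they check.

bruteGlcm <- function(px, levels, offset = c(0L, 1L), symmetric = TRUE) {
  L <- levels
  Q <- pmin(floor(px * L), L - 1L)
  H <- nrow(px); W <- ncol(px)
  M <- matrix(0, L, L)
  for (y in seq_len(H)) for (x in seq_len(W)) {
    y2 <- y + offset[1L]; x2 <- x + offset[2L]
    if (y2 >= 1 && y2 <= H && x2 >= 1 && x2 <= W) {
      i <- Q[y, x] + 1L; j <- Q[y2, x2] + 1L
      M[i, j] <- M[i, j] + 1
      if (symmetric) M[j, i] <- M[j, i] + 1
    }
  }
  M / sum(M)
}

bruteContrast <- function(P) {
  s <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P)))
    s <- s + (i - j)^2 * P[i, j]
  s
}

# Front partition by repeatedly peeling the set of points dominated by none.
bruteFronts <- function(F) {
  dom <- function(a, b) all(a <= b) && any(a < b)
  idx <- seq_len(nrow(F))
  fronts <- list()
  while (length(idx) > 0L) {
    nd <- idx[vapply(idx, function(i)
      !any(vapply(idx, function(j) j != i && dom(F[j, ], F[i, ]), logical(1))),
      logical(1))]
    fronts[[length(fronts) + 1L]] <- nd
    idx <- setdiff(idx, nd)
  }
  fronts
}

# A small noisy vessel phantom used by several tests.
testPhantom <- function(seed = 1L, size = 64L, noise = 0.02) {
  generatePhantom(phantomSpec(width = size, height = size, seed = seed,
                              noiseSigma = noise))
}
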