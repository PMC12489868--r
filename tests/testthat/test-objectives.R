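test_that("GLCM is a normalized, optionally symmetric pair distribution", {
  P <- glcm(matrix(0.5, 8, 8))
  k <- floor(0.5 * 8) + 1
  expect_equal(P[k, k], 1)                      # constant: all mass diagonal
  expect_equal(sum(P), 1, tolerance = 1e-12)

  # alternating two-level row: all mass off-diagonal, symmetrized
  m <- matrix(c(0, 1, 0, 1), 1, 4)
  P2 <- glcm(m, glcmConfig(levels = 2))
  expect_equal(P2, matrix(c(0, 0.5, 0.5, 0), 2, 2))

  set.seed(11)
  px <- matrix(runif(16 * 16), 16, 16)
  cfg <- glcmConfig(levels = 8)
  expect_equal(glcm(px, cfg), bruteGlcm(px, 8), tolerance = 1e-15)
  expect_equal(glcm(px, cfg), t(glcm(px, cfg)))  # symmetric accumulation

  # asymmetric and non-horizontal offsets also match the oracle
  cfgA <- glcmConfig(levels = 4, offset = c(1L, -1L), symmetric = FALSE)
  expect_equal(glcm(px, cfgA), bruteGlcm(px, 4, c(1L, -1L), FALSE),
               tolerance = 1e-15)

  expect_error(glcm(matrix(0.5, 1, 1), glcmConfig(offset = c(0L, 1L))),
               "no valid pixel pairs")
  expect_error(glcmConfig(offset = c(0, 0)), "offset")
  expect_error(glcmConfig(levels = 1), "levels")
})

test_that("GLCM contrast equals the direct double sum", {
  expect_equal(glcmContrast(glcm(matrix(0.3, 8, 8))), 0)
  offdiag <- matrix(c(0, 0.5, 0.5, 0), 2, 2)
  expect_equal(glcmContrast(offdiag), 1)

  set.seed(12)
  P <- matrix(runif(64), 8, 8); P <- P / sum(P)
  expect_equal(glcmContrast(P), bruteContrast(P), tolerance = 1e-12)

  expect_error(glcmContrast(P * 2), "normalized")
})

test_that("GLCM contrast is invariant to whole-bin intensity shifts", {
  set.seed(13)
  q <- matrix(sample(0:5, 100, replace = TRUE), 10, 10)
  px <- (q + 0.5) / 8                       # bin centers, shiftable by 2 bins
  c0 <- glcmContrast(glcm(px))
  c1 <- glcmContrast(glcm(px + 2 / 8))
  expect_equal(c0, c1, tolerance = 1e-12)
})

test_that("FNVE annihilates affine images and scales linearly", {
  expect_equal(fnve(matrix(0.5, 16, 16)), 0)
  ramp <- outer(seq(0, 1, length.out = 20), seq(0, 0.5, length.out = 30), `+`)
  expect_equal(fnve(ramp / max(ramp)), 0, tolerance = 1e-14)

  set.seed(14)
  px <- matrix(runif(400), 20, 20)
  expect_equal(fnve(px + 0.3), fnve(px), tolerance = 1e-12)  # offset invariant
  expect_equal(fnve(0.5 * px), 0.5 * fnve(px), tolerance = 1e-12)

  expect_error(fnve(matrix(0.5, 2, 5)), "3 x 3")
})

test_that("FNVE error shrinks as the noise field grows", {
  relerr <- function(n, sigma, seeds) {
    mean(vapply(seeds, function(s) {
      set.seed(s)
      abs(fnve(matrix(rnorm(n * n, 0.5, sigma), n, n)) - sigma) / sigma
    }, numeric(1)))
  }
  e128 <- relerr(128, 0.05, 1:3)
  e256 <- relerr(256, 0.05, 1:3)
  e512 <- relerr(512, 0.05, 1:3)
  expect_lt(e512, e128)
  expect_lt(e512, 0.05)
  expect_lt(e256, 0.10)
})

test_that("candidate evaluation is deterministic and degenerates gracefully", {
  const <- grayImage(matrix(0.6, 32, 32))
  fp <- evaluateCandidate(const, claheParams(4, 4, 0.01, 0.6))
  expect_equal(contrast(fp), 0)
  expect_equal(noise(fp), 0)

  ph <- testPhantom(seed = 15)
  p <- claheParams(6, 6, 0.004, 0.7)
  f1 <- evaluateCandidate(ph@image, p)
  f2 <- evaluateCandidate(ph@image, p)
  expect_identical(contrast(f1), contrast(f2))
  expect_identical(noise(f1), noise(f2))

  big <- testPhantom(seed = 16, size = 128, noise = 0.02)
  nLo <- noise(evaluateCandidate(big@image, claheParams(8, 8, 0.001, 0.6)))
  nHi <- noise(evaluateCandidate(big@image, claheParams(8, 8, 0.01, 0.6)))
  expect_gte(nHi, nLo)
})
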