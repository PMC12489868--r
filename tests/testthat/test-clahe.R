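test_that("tile histograms bin region pixels exactly", {
  const <- matrix(0.5, 16, 16)
  h <- tileHistogram(const, c(1, 8, 1, 8), 256)
  expect_equal(sum(h), 64)
  expect_equal(sum(h > 0), 1)
  expect_equal(h[floor(0.5 * 256) + 1], 64)

  chk <- matrix(rep(c(0.2, 0.7), 32), 8, 8)
  h2 <- tileHistogram(chk, c(1, 8, 1, 8), 2)
  expect_equal(h2, c(32, 32))

  set.seed(3)
  px <- matrix(runif(100), 10, 10)
  h3 <- tileHistogram(px, c(2, 7, 3, 9), 16)
  oracle <- integer(16)
  for (i in 2:7) for (j in 3:9) {
    b <- min(floor(px[i, j] * 16) + 1, 16)
    oracle[b] <- oracle[b] + 1L
  }
  expect_identical(h3, oracle)

  expect_error(tileHistogram(px, c(0, 5, 1, 5)), "region")
  expect_error(tileHistogram(px, c(1, 11, 1, 5)), "region")
})

test_that("clip-and-redistribute reaches the equal-redistribution fixed point", {
  expect_equal(clipAndRedistribute(c(10, 0, 0, 0), 4), c(4, 2, 2, 2),
               tolerance = 1e-9)
  expect_equal(clipAndRedistribute(c(3, 3, 3, 3), 4), c(3, 3, 3, 3))
  expect_error(clipAndRedistribute(c(1, 2), 0), "positive")

  set.seed(8)
  for (k in 1:20) {
    h <- rpois(64, lambda = runif(1, 0.5, 20))
    clip <- runif(1, 1, 10)
    out <- clipAndRedistribute(h, clip)
    expect_equal(sum(out), sum(h), tolerance = 1e-9)   # mass conserved
    if (clip * length(h) >= sum(h))                    # feasible limit
      expect_true(all(out <= clip + 1e-6))
  }
})

test_that("Rayleigh transfer matches its closed form and stays monotone", {
  # raw quantile form
  expect_equal(rayleighTransfer(0, 0.7, gMin = 0.1, rescale = FALSE), 0.1)
  expect_equal(rayleighTransfer(1 - exp(-2), 0.5, rescale = FALSE), 1,
               tolerance = 1e-12)
  expect_error(rayleighTransfer(c(0, 1), 0), "positive")
  expect_error(rayleighTransfer(c(0.5, 0.2), 0.6), "non-decreasing")

  cdf <- seq(0, 1, length.out = 256)
  for (a in c(0.5, 0.7, 0.9)) {
    lut <- rayleighTransfer(cdf, a)
    expect_true(all(diff(lut) >= 0))
    expect_gte(min(lut), 0)
    expect_lte(max(lut), 1)
    expect_equal(lut[1], 0)
    expect_equal(lut[256], 1, tolerance = 1e-12)
  }
  # alpha genuinely changes the mapping (larger alpha brightens midtones)
  l5 <- rayleighTransfer(cdf, 0.5)
  l9 <- rayleighTransfer(cdf, 0.9)
  expect_gt(l9[128], l5[128])
})

test_that("CLAHE maps constants to constants and stays within [0,1]", {
  const <- grayImage(matrix(0.42, 48, 48))
  out <- clahe(const, claheParams(8, 8, 0.01, 0.6))
  expect_s4_class(out, "GrayImage")
  expect_equal(max(pixels(out)) - min(pixels(out)), 0)

  set.seed(5)
  img <- grayImage(matrix(runif(50 * 70), 50, 70))   # non-divisible size
  for (p in list(claheParams(4, 4, 0.01, 0.6), claheParams(7, 3, 0.003, 0.9))) {
    o <- pixels(clahe(img, p))
    expect_gte(min(o), 0)
    expect_lte(max(o), 1)
    expect_identical(dim(o), dim(pixels(img)))
  }

  expect_error(clahe(grayImage(matrix(0.5, 8, 8)), claheParams(12, 12)),
               "incompatible")
})

test_that("CLAHE raises GLCM contrast of a low-contrast vessel phantom", {
  ph <- testPhantom(seed = 6, size = 96, noise = 0.01)
  img <- ph@image
  out <- clahe(img, claheParams(8, 8, 0.01, 0.6))
  expect_gt(glcmContrast(glcm(out)), glcmContrast(glcm(img)))
})

test_that("a smaller clip limit amplifies noise less", {
  ph <- testPhantom(seed = 9, size = 128, noise = 0.02)
  lo <- clahe(ph@image, claheParams(8, 8, 0.001, 0.6))
  hi <- clahe(ph@image, claheParams(8, 8, 0.01, 0.6))
  expect_gte(fnve(pixels(hi)), fnve(pixels(lo)))
})
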