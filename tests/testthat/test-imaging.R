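test_that("value channel extraction is the per-pixel channel maximum", {
  set.seed(10)
  arr <- array(runif(3 * 9 * 11), c(9, 11, 3))
  v <- rgbToValue(arr)
  expect_s4_class(v, "GrayImage")
  expect_equal(pixels(v), pmax(arr[, , 1], arr[, , 2], arr[, , 3]))

  gray <- array(0.4, c(5, 5, 3))
  expect_true(all(pixels(rgbToValue(gray)) == 0.4))

  black <- array(0, c(4, 4, 3))
  expect_true(all(pixels(rgbToValue(black)) == 0))

  expect_error(rgbToValue(array(0.5, c(4, 4, 2))), "three channels")
  expect_error(rgbToValue(matrix(0.5, 4, 4)), "three channels")
})

test_that("mean luminosity equals brute-force summation", {
  expect_equal(meanLuminosity(matrix(0.7, 6, 6)), 0.7)
  half <- matrix(c(rep(0, 18), rep(1, 18)), 6, 6)
  expect_equal(meanLuminosity(half), 0.5)

  set.seed(2)
  px <- matrix(runif(48), 6, 8)
  s <- 0
  for (i in 1:6) for (j in 1:8) s <- s + px[i, j]
  expect_equal(meanLuminosity(grayImage(px)), s / 48)
})

test_that("exposure classification partitions [0,1] with inclusive upper bounds", {
  expect_identical(classifyExposure(0.6), "underexposed")
  expect_identical(classifyExposure(0.75), "correct")
  expect_identical(classifyExposure(0.8), "correct")
  expect_identical(classifyExposure(0.81), "overexposed")
  expect_identical(classifyExposure(0), "underexposed")
  expect_identical(classifyExposure(1), "overexposed")
  expect_error(classifyExposure(-0.01), "\\[0, 1\\]")
  expect_error(classifyExposure(1.01), "\\[0, 1\\]")

  for (v in seq(0, 1, by = 0.05))
    expect_true(classifyExposure(v) %in%
                  c("underexposed", "correct", "overexposed"))

  # a GrayImage is classified through its mean
  expect_identical(classifyExposure(grayImage(matrix(0.9, 4, 4))),
                   "overexposed")
})

test_that("LoG sharpness is zero on constants and decays with defocus", {
  expect_equal(sharpnessLogVariance(matrix(0.5, 32, 32)), 0)
  expect_error(sharpnessLogVariance(matrix(0.5, 32, 32), logSigma = 0),
               "positive")

  base <- phantomSpec(width = 96, height = 96, seed = 4, noiseSigma = 0)
  sharp <- pixels(generatePhantom(base)@image)
  b1 <- base; b1@blurSigma <- 1
  b3 <- base; b3@blurSigma <- 3
  s0 <- sharpnessLogVariance(sharp)
  s1 <- sharpnessLogVariance(pixels(generatePhantom(b1)@image))
  s3 <- sharpnessLogVariance(pixels(generatePhantom(b3)@image))
  expect_gt(s0, s1)
  expect_gt(s1, s3)
  expect_gte(s3, 0)
})

test_that("sharpest-frame selection picks the maximal score, first on ties", {
  f <- grayImage(matrix(runif(64, 0.3, 0.7), 8, 8))
  same <- frameSequence(list(f, f, f))
  expect_identical(selectSharpestFrame(same), 1L)

  seqs <- generateSequence(phantomSpec(width = 64, height = 64, seed = 3,
                                       noiseSigma = 0),
                           nFrames = 3, blurSchedule = c(3, 0, 3))
  expect_identical(selectSharpestFrame(seqs), 2L)

  single <- frameSequence(list(f))
  expect_identical(selectSharpestFrame(single), 1L)

  # selected frame attains the maximum score
  scores <- vapply(frames(seqs), sharpnessLogVariance, numeric(1))
  expect_equal(scores[selectSharpestFrame(seqs)], max(scores))
})

test_that("frame sequences enforce shared dimensions and non-emptiness", {
  a <- grayImage(matrix(0.5, 8, 8))
  b <- grayImage(matrix(0.5, 8, 9))
  expect_error(frameSequence(list()), "at least one")
  expect_error(frameSequence(list(a, b)), "same dimensions")
})
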