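test_that("degenerate phantom specs give exactly the background level", {
  spec <- phantomSpec(width = 32, height = 32, nVessels = 0,
                      vignetteStrength = 0, noiseSigma = 0,
                      backgroundLevel = 0.8)
  b <- generatePhantom(spec)
  expect_true(all(pixels(b@image) == 0.8))
  expect_false(any(b@vesselMask))
})

test_that("phantoms are bitwise reproducible under a fixed seed", {
  spec <- phantomSpec(seed = 77)
  b1 <- generatePhantom(spec)
  b2 <- generatePhantom(spec)
  expect_identical(pixels(b1@image), pixels(b2@image))
  expect_identical(b1@vesselMask, b2@vesselMask)
})

test_that("phantom specs validate their ranges", {
  expect_error(phantomSpec(backgroundLevel = 0.2, vesselContrast = 0.5),
               "backgroundLevel")
  expect_error(phantomSpec(vignetteStrength = 1), "vignetteStrength")
  expect_error(phantomSpec(noiseSigma = -0.1), "noiseSigma")
})

test_that("a bright sparse phantom is overexposed by construction", {
  spec <- phantomSpec(width = 96, height = 96, backgroundLevel = 0.95,
                      nVessels = 2, vesselWidth = 2, vesselContrast = 0.3,
                      vignetteStrength = 0.05, noiseSigma = 0.005, seed = 5)
  b <- generatePhantom(spec)
  expect_gt(meanLuminosity(b@image), 0.8)
  expect_identical(classifyExposure(meanLuminosity(b@image)), "overexposed")
})

test_that("vessel-mask pixels are darker than the untouched background", {
  spec <- phantomSpec(width = 96, height = 96, vignetteStrength = 0,
                      noiseSigma = 0, blurSigma = 0, seed = 8)
  b <- generatePhantom(spec)
  expect_gt(sum(b@vesselMask), 0)
  expect_true(all(pixels(b@image)[b@vesselMask] < spec@backgroundLevel))
  expect_lt(mean(pixels(b@image)[b@vesselMask]),
            mean(pixels(b@image)[!b@vesselMask]))
})

test_that("bright-background phantoms have negatively skewed histograms", {
  b <- generatePhantom(phantomSpec(seed = 9))
  v <- as.vector(pixels(b@image))
  skew <- mean((v - mean(v))^3) / stats::sd(v)^3
  expect_lt(skew, 0)
})

test_that("the generator's noise ties out with the FNVE estimator", {
  spec <- phantomSpec(width = 512, height = 512, nVessels = 0,
                      vignetteStrength = 0, vesselContrast = 0,
                      backgroundLevel = 0.5, noiseSigma = 0.05, seed = 10)
  b <- generatePhantom(spec)
  expect_lt(abs(fnve(b@image) - 0.05) / 0.05, 0.05)
})

test_that("frame sequences follow the blur schedule", {
  spec <- phantomSpec(width = 64, height = 64, seed = 12)
  s <- generateSequence(spec, 3, c(3, 0, 3))
  expect_identical(selectSharpestFrame(s), 2L)

  flat <- generateSequence(spec, 3, c(1, 1, 1))
  scores <- vapply(frames(flat), sharpnessLogVariance, numeric(1))
  expect_identical(selectSharpestFrame(flat), which.max(scores))

  one <- generateSequence(spec, 1, 0)
  expect_identical(nFrames(one), 1L)

  expect_error(generateSequence(spec, 3, c(0, 1)), "per frame")
})

test_that("the exposure suite lands one phantom in each class", {
  suite <- exposureSuite(phantomSpec(seed = 13))
  expect_named(suite, c("underexposed", "correct", "overexposed"))
  mls <- vapply(suite, function(b) meanLuminosity(b@image), numeric(1))
  expect_lte(mls[["underexposed"]], 0.6)
  expect_gt(mls[["correct"]], 0.6); expect_lte(mls[["correct"]], 0.8)
  expect_gt(mls[["overexposed"]], 0.8)
  for (cls in names(suite))
    expect_identical(classifyExposure(mls[[cls]]), cls)

  suite2 <- exposureSuite(phantomSpec(seed = 13))
  expect_identical(pixels(suite$correct@image), pixels(suite2$correct@image))
})
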