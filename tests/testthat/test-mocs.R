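test_that("Mantegna scale and Levy steps behave as heavy-tailed draws", {
  expect_equal(levySigma(1.5), 0.6966, tolerance = 1e-4)
  expect_error(levySigma(1), "1, 2")
  expect_error(levyStep(4, beta = 2.5), "1, 2")

  set.seed(21); a <- levyStep(6, 1.5)
  set.seed(21); b <- levyStep(6, 1.5)
  expect_identical(a, b)

  set.seed(22)
  steps <- levyStep(1e5, 1.5)
  tailFrac <- mean(abs(steps) > 10)
  expect_gt(tailFrac, 1e-3)          # Gaussian with this core scale: ~1e-45
})

test_that("cuckoo proposals stay within bounds and respect the guide", {
  b <- searchBounds()
  cfg <- mocsConfig(seed = 1)
  x <- c(8, 8, 0.005, 0.7)
  set.seed(30)
  expect_identical(proposeCuckoo(x, x, b, cfg), x)  # zero directional term
  set.seed(31)
  for (k in 1:200) {
    g <- b@lower + runif(4) * (b@upper - b@lower)
    xp <- proposeCuckoo(x, g, b, cfg)
    expect_true(all(xp >= b@lower & xp <= b@upper))
  }
})

test_that("abandonment walk explores but never leaves the bounds", {
  b <- searchBounds()
  set.seed(40)
  X <- sapply(1:4, function(d) runif(10, b@lower[d], b@upper[d]))

  same <- abandonWalk(X, b, mocsConfig(pDiscovery = 0))
  expect_identical(same, X)

  set.seed(41)
  all1 <- abandonWalk(X, b, mocsConfig(pDiscovery = 1))
  expect_true(mean(all1 != X) > 0.9)   # nearly every coordinate moved

  set.seed(42)
  cfg <- mocsConfig(pDiscovery = 0.75)
  for (k in 1:100) {
    out <- abandonWalk(X, b, cfg)
    expect_true(all(out >= matrix(b@lower, 10, 4, byrow = TRUE) &
                      out <= matrix(b@upper, 10, 4, byrow = TRUE)))
  }

  expect_error(abandonWalk(X[1:2, ], b, cfg), "at least 3")
})

test_that("dominance and non-dominated sorting match first principles", {
  expect_true(dominates(c(-5, 0.01), c(-4, 0.02)))
  expect_false(dominates(c(-5, 0.02), c(-4, 0.01)))
  expect_false(dominates(c(-5, 0.01), c(-5, 0.01)))

  pts <- rbind(c(1, 2), c(2, 1), c(3, 3))
  fr <- nondominatedSort(pts)
  expect_identical(fr[[1]], c(1L, 2L))
  expect_identical(fr[[2]], 3L)

  ident <- matrix(1, 5, 2)
  expect_identical(nondominatedSort(ident), list(1:5))
  expect_error(nondominatedSort(matrix(numeric(0), 0, 2)), "empty")

  set.seed(50)
  for (k in 1:100) {
    n <- sample(2:50, 1)
    F <- matrix(runif(2 * n), n, 2)
    expect_identical(nondominatedSort(F), bruteFronts(F))
  }
})

test_that("crowding distance rewards spread and is order-invariant", {
  expect_identical(crowdingDistance(matrix(c(1, 2), 1, 2)), Inf)
  expect_identical(crowdingDistance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))

  three <- rbind(c(0, 0), c(1, 1), c(2, 2))   # evenly spaced, collinear
  cd <- crowdingDistance(three)
  expect_identical(cd[c(1, 3)], c(Inf, Inf))
  expect_equal(cd[2], 2)                       # 1 per objective, normalized

  set.seed(51)
  F <- matrix(runif(20), 10, 2)
  p <- sample(10)
  expect_equal(crowdingDistance(F)[p], crowdingDistance(F[p, ]))
})

test_that("the middle-of-front selection follows the stated convention", {
  mkFront <- function(n) {
    fit <- cbind(contrast = seq_len(n), noise = seq_len(n) / 10)
    new("ParetoFront", vectors = matrix(runif(4 * n), n, 4), fitness = fit,
        crowding = crowdingDistance(fit))
  }
  expect_identical(selectMiddle(mkFront(1)), 1L)
  expect_identical(selectMiddle(mkFront(3)), 2L)
  expect_identical(selectMiddle(mkFront(4)), 2L)   # floor((n-1)/2), 0-based 1
})

test_that("decision vectors decode by rounding tiles within bounds", {
  p <- decodeParams(c(7.6, 4.2, 0.005, 0.7))
  expect_identical(tilesX(p), 8L)
  expect_identical(tilesY(p), 4L)
  expect_equal(clipLimit(p), 0.005)
  expect_equal(alpha(p), 0.7)

  up <- decodeParams(c(12, 12, 0.01, 0.9))
  expect_identical(c(tilesX(up), tilesY(up)), c(12L, 12L))
  lo <- decodeParams(c(4, 4, 0.001, 0.5))
  expect_identical(c(tilesX(lo), tilesY(lo)), c(4L, 4L))

  expect_error(decodeParams(c(13, 8, 0.005, 0.7)), "bounds")
})

test_that("the optimizer is deterministic, in-bounds and elitist", {
  b <- searchBounds(rep(-5, 4), rep(5, 4))
  # cheap analytic objectives on the first dimension
  fit <- function(v) c(v[1]^2, (v[1] - 2)^2)
  cfg <- mocsConfig(population = 20, iterations = 8, seed = 99)

  r1 <- mocsOptimize(fit, b, cfg)
  r2 <- mocsOptimize(fit, b, cfg)
  expect_identical(r1$front@vectors, r2$front@vectors)
  expect_identical(r1$front@fitness, r2$front@fitness)
  expect_identical(r1$best, r2$best)

  A <- r1$front@vectors
  expect_true(all(A >= matrix(b@lower, nrow(A), 4, byrow = TRUE) &
                    A <= matrix(b@upper, nrow(A), 4, byrow = TRUE)))

  # elitism: no later front member is strictly dominated by an earlier one
  hist <- r1$history
  for (t in seq_len(length(hist) - 1)) {
    Ft0 <- cbind(-hist[[t]][, "contrast"], hist[[t]][, "noise"])
    Ft1 <- cbind(-hist[[t + 1]][, "contrast"], hist[[t + 1]][, "noise"])
    for (i in seq_len(nrow(Ft1)))
      for (j in seq_len(nrow(Ft0)))
        expect_false(dominates(Ft0[j, ], Ft1[i, ]))
  }

  # archive never exceeds the population size
  expect_lte(nrow(A), cfg@population)
  for (h in hist) expect_lte(nrow(h), cfg@population)
})

test_that("failed or non-finite evaluations are dominated by everything", {
  b <- searchBounds(rep(0, 4), rep(1, 4))
  fit <- function(v) if (v[1] > 0.5) c(NaN, 1) else c(v[1], 1 - v[1])
  expect_warning(
    res <- mocsOptimize(fit, b, mocsConfig(population = 10, iterations = 2,
                                           seed = 3)),
    "non-finite")
  expect_true(all(is.finite(res$front@fitness)))
  expect_true(all(res$front@vectors[, 1] <= 0.5))
})
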