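## Multi-objective cuckoo search: Levy-flight exploitation, abandonment
## random-walk exploration, and an elitist non-dominated archive with
## crowding-distance truncation.  All fitness handling inside the optimizer
## uses the minimization convention; for the imaging problem the minimized
## pair is (-contrast, noise).

#' Mantegna scale for Levy-stable steps
#'
#' The Gaussian scale sigma_u of the Mantegna algorithm,
#' (Gamma(1 + beta) sin(pi beta / 2) / (Gamma((1 + beta) / 2) beta
#' 2^((beta - 1) / 2)))^(1 / beta), such that u / |v|^(1 / beta) with
#' u ~ N(0, sigma_u^2), v ~ N(0, 1) approximates a Levy-stable step.
#'
#' @param beta Levy exponent in (1, 2].
#' @return Positive scalar sigma_u (about 0.6966 for beta = 1.5).
#' @export
levySigma <- function(beta) {
  if (!(beta > 1 && beta <= 2)) stop("'beta' must lie in (1, 2]")
  (gamma(1 + beta) * sin(pi * beta / 2) /
     (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
}

#' Draw one Levy-flight step per dimension
#'
#' Mantegna samples u / |v|^(1 / beta); heavy-tailed, so occasional long
#' jumps let the search escape local basins.  Draws from the current global
#' RNG stream (seed it for reproducibility).
#'
#' @param dim number of dimensions.
#' @param beta Levy exponent in (1, 2] (default 1.5).
#' @return Numeric vector of `dim` steps.
#' @export
levyStep <- function(dim, beta = 1.5) {
  su <- levySigma(beta)
  u <- stats::rnorm(dim, 0, su)
  v <- stats::rnorm(dim)
  u / abs(v)^(1 / beta)
}

#' Propose a cuckoo solution by a Levy walk toward a guide
#'
#' x' = x + stepScale * (upper - lower) (x) levy (x) (x - guide), clamped to
#' the bounds elementwise; the directional term vanishes when x equals the
#' guide, so solutions already at a front guide stay put.
#'
#' @param x current decision vector (within bounds).
#' @param guide decision vector of a front member to walk toward.
#' @param bounds a [SearchBounds-class].
#' @param cfg a [MocsConfig-class] (uses `levyBeta` and `stepScale`).
#' @return Proposed decision vector within bounds.
#' @export
proposeCuckoo <- function(x, guide, bounds, cfg = mocsConfig()) {
  step <- levyStep(length(x), cfg@levyBeta)
  xp <- x + cfg@stepScale * (bounds@upper - bounds@lower) * step * (x - guide)
  pmin(pmax(xp, bounds@lower), bounds@upper)
}

#' Abandonment (biased random walk) over a population
#'
#' For each nest, every coordinate is replaced with probability `pDiscovery`
#' by x + r (x_p - x_q), where r ~ Uniform(0, 1) and p, q are two distinct
#' random nests; results are clamped to the bounds.  This is the exploration
#' move of cuckoo search: discovered eggs are thrown out and rebuilt far
#' from the current configuration.
#'
#' @param population numeric matrix (>= 3 rows) of decision vectors.
#' @param bounds a [SearchBounds-class].
#' @param cfg a [MocsConfig-class] (uses `pDiscovery`).
#' @return Matrix of the same shape, within bounds.
#' @export
abandonWalk <- function(population, bounds, cfg = mocsConfig()) {
  n <- nrow(population)
  if (is.null(n) || n < 3L)
    stop("abandonment walk needs a population of at least 3 nests")
  d <- ncol(population)
  out <- population
  for (i in seq_len(n)) {
    pq <- sample.int(n, 2L)
    r <- stats::runif(1)
    mask <- stats::runif(d) < cfg@pDiscovery
    if (any(mask))
      out[i, mask] <- out[i, mask] +
        r * (population[pq[1L], mask] - population[pq[2L], mask])
  }
  sweep(sweep(out, 2, bounds@lower, pmax), 2, bounds@upper, pmin)
}

#' Pareto dominance (minimization)
#'
#' `a` dominates `b` iff a is no worse in every minimized objective and
#' strictly better in at least one.
#'
#' @param a,b numeric objective vectors of equal length, minimization
#'   convention (for the imaging problem: (-contrast, noise)).
#' @return Logical scalar.
#' @examples
#' dominates(c(-5, 0.01), c(-4, 0.02))  # TRUE: better in both
#' dominates(c(-5, 0.02), c(-4, 0.01))  # FALSE: a trade-off
#' @export
dominates <- function(a, b) {
  all(a <= b) && any(a < b)
}

.front0 <- function(F) {
  n <- nrow(F)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    if (!keep[i]) next
    for (j in seq_len(n)) {
      if (i != j && dominates(F[j, ], F[i, ])) { keep[i] <- FALSE; break }
    }
  }
  which(keep)
}

#' Non-dominated sorting
#'
#' Partitions a set of objective vectors (minimization) into fronts: front 1
#' holds the points dominated by none; front k the points dominated only by
#' members of earlier fronts.
#'
#' @param points numeric matrix, one objective vector per row.
#' @return List of integer index vectors, one per front, partitioning the
#'   row indices.
#' @export
nondominatedSort <- function(points) {
  if (!is.matrix(points)) points <- as.matrix(points)
  if (nrow(points) == 0L) stop("empty input")
  remaining <- seq_len(nrow(points))
  fronts <- list()
  while (length(remaining) > 0L) {
    idx <- .front0(points[remaining, , drop = FALSE])
    fronts[[length(fronts) + 1L]] <- remaining[idx]
    remaining <- remaining[-idx]
  }
  fronts
}

#' Crowding distance of a front
#'
#' For each objective the front is sorted; boundary members receive +Inf and
#' interior members accumulate the normalized gap between their neighbors,
#' summed over objectives.  Members in sparse objective-space regions score
#' higher and are preferred when an archive must be truncated.
#'
#' @param front numeric matrix of objective vectors (any consistent sign
#'   convention; the measure only uses distances).
#' @return Numeric vector of crowding distances, one per row.
#' @export
crowdingDistance <- function(front) {
  if (!is.matrix(front)) front <- as.matrix(front)
  n <- nrow(front)
  if (n == 0L) stop("empty front")
  cd <- rep(0, n)
  if (n <= 2L) return(rep(Inf, n))
  for (m in seq_len(ncol(front))) {
    ord <- order(front[, m])
    f <- front[ord, m]
    cd[ord[1L]] <- Inf
    cd[ord[n]] <- Inf
    rng <- f[n] - f[1L]
    if (rng > 0) {
      gaps <- (f[3:n] - f[1:(n - 2L)]) / rng
      cd[ord[2:(n - 1L)]] <- cd[ord[2:(n - 1L)]] + gaps
    }
  }
  cd
}

#' Select the balanced (middle) solution of a Pareto front
#'
#' Members are sorted by the contrast objective; the member at 0-based index
#' floor((n - 1) / 2) is returned, a balanced trade-off between contrast
#' gain and noise amplification.  Ties in the sort key are broken by larger
#' crowding distance, then by lower noise.
#'
#' @param front a [ParetoFront-class].
#' @return Integer row index (into the front's members) of the selection.
#' @export
selectMiddle <- function(front) {
  stopifnot(is(front, "ParetoFront"))
  n <- nrow(front@fitness)
  if (n == 0L) stop("empty front")
  ord <- order(front@fitness[, 1L], -front@crowding, front@fitness[, 2L])
  ord[(n - 1L) %/% 2L + 1L]
}

#' Decode a continuous decision vector into CLAHE parameters
#'
#' Tile counts are searched as continuous values and integerized only here:
#' rounded half-up and clamped to the integer bound range.  Clip limit and
#' alpha pass through unchanged.
#'
#' @param vector numeric 4-vector (tilesX, tilesY, clipLimit, alpha) within
#'   bounds.
#' @param bounds a [SearchBounds-class].
#' @return A [ClaheParams-class].
#' @examples
#' decodeParams(c(7.6, 4.2, 0.005, 0.7), searchBounds())  # tiles 8 x 4
#' @export
decodeParams <- function(vector, bounds = searchBounds()) {
  if (length(vector) != 4L) stop("decision vector must have 4 dimensions")
  tol <- 1e-9
  if (any(vector < bounds@lower - tol) || any(vector > bounds@upper + tol))
    stop("decision vector outside the search bounds")
  ti <- floor(vector[1:2] + 0.5)
  ti <- pmin(pmax(ti, ceiling(bounds@lower[1:2])), floor(bounds@upper[1:2]))
  claheParams(ti[1L], ti[2L], vector[3L], vector[4L])
}

## Sample an archive guide with crowding-weighted probability.
.sampleGuide <- function(A, cd) {
  w <- cd
  fin <- is.finite(w)
  w[!fin] <- if (any(fin) && max(w[fin]) > 0) 2 * max(w[fin]) else 1
  w[w <= 0] <- min(w[w > 0], 1)
  A[sample.int(nrow(A), 1L, prob = w), ]
}

## Keep the best `n` rows by front rank, then crowding within the last front.
.truncateByFronts <- function(F, n) {
  fronts <- nondominatedSort(F)
  sel <- integer(0)
  for (fr in fronts) {
    if (length(sel) + length(fr) <= n) {
      sel <- c(sel, fr)
    } else {
      need <- n - length(sel)
      if (need > 0L) {
        cd <- crowdingDistance(F[fr, , drop = FALSE])
        sel <- c(sel, fr[order(cd, decreasing = TRUE)[seq_len(need)]])
      }
      break
    }
  }
  sel
}

.evalRow <- function(fitness, x) {
  f <- tryCatch(fitness(x), error = function(e) {
    warning("candidate evaluation failed: ", conditionMessage(e))
    c(Inf, Inf)
  })
  if (length(f) != 2L || anyNA(f) || any(!is.finite(f) & !is.infinite(f))) {
    warning("non-finite fitness; candidate treated as dominated by everything")
    f <- c(Inf, Inf)
  }
  ifelse(is.finite(f), f, Inf)
}

#' Multi-objective cuckoo search over a box-bounded space
#'
#' Generic two-objective cuckoo search (minimization).  Each iteration
#' performs, for every nest, a Levy-flight proposal toward a randomly chosen
#' (crowding-weighted) member of the non-dominated archive, which replaces a
#' uniformly random nest if it dominates it (and with probability 1/2 when
#' mutually non-dominated); then the abandonment walk ([abandonWalk()])
#' regenerates discovered nests, the old and walked populations are merged
#' and truncated back to the population size by non-dominated sorting with
#' crowding distance, and the elitist archive is updated.  Fully
#' deterministic given `cfg@seed`.
#'
#' @param fitness function taking a decision vector and returning the two
#'   minimized objectives as a numeric length-2 vector.  Non-finite or
#'   failing evaluations are treated as dominated by everything (with a
#'   warning).
#' @param bounds a [SearchBounds-class]; its length sets the dimensionality.
#' @param cfg a [MocsConfig-class].
#' @param keepHistory record per-iteration archive objective snapshots
#'   (default TRUE).
#' @return A list with `front` (a [ParetoFront-class]; fitness stored in
#'   natural signs (contrast, noise) = (-f1, f2)), `bestIndex` (the
#'   [selectMiddle()] member), `best` (that member's decision vector) and
#'   `history` (list of per-iteration archive objective matrices in natural
#'   signs).
#' @export
mocsOptimize <- function(fitness, bounds, cfg = mocsConfig(),
                         keepHistory = TRUE) {
  stopifnot(is(bounds, "SearchBounds"), is(cfg, "MocsConfig"))
  validObject(bounds); validObject(cfg)
  set.seed(cfg@seed)
  n <- cfg@population
  d <- length(bounds@lower)
  rng <- bounds@upper - bounds@lower

  X <- matrix(stats::runif(n * d), n, d)
  X <- sweep(sweep(X, 2, rng, `*`), 2, bounds@lower, `+`)
  F <- t(vapply(seq_len(n), function(i) .evalRow(fitness, X[i, ]),
                numeric(2)))

  i0 <- .front0(F)
  A <- X[i0, , drop = FALSE]; FA <- F[i0, , drop = FALSE]
  history <- if (keepHistory) vector("list", cfg@iterations) else NULL

  for (t in seq_len(cfg@iterations)) {
    cdA <- crowdingDistance(FA)
    for (i in seq_len(n)) {
      g <- .sampleGuide(A, cdA)
      xp <- proposeCuckoo(X[i, ], g, bounds, cfg)
      fp <- .evalRow(fitness, xp)
      j <- sample.int(n, 1L)
      if (dominates(fp, F[j, ]) ||
          (!dominates(F[j, ], fp) && stats::runif(1) < 0.5)) {
        X[j, ] <- xp; F[j, ] <- fp
      }
    }
    Xw <- abandonWalk(X, bounds, cfg)
    changed <- which(rowSums(Xw != X) > 0L)
    Fw <- F
    for (i in changed) Fw[i, ] <- .evalRow(fitness, Xw[i, ])
    XM <- rbind(X, Xw); FM <- rbind(F, Fw)
    sel <- .truncateByFronts(FM, n)
    X <- XM[sel, , drop = FALSE]; F <- FM[sel, , drop = FALSE]

    ## elitist archive: union with the population, drop duplicates,
    ## keep the non-dominated set truncated to the population size
    U <- rbind(A, X); FU <- rbind(FA, F)
    dup <- duplicated(cbind(U, FU))
    U <- U[!dup, , drop = FALSE]; FU <- FU[!dup, , drop = FALSE]
    i0 <- .front0(FU)
    if (length(i0) > n) {
      cd <- crowdingDistance(FU[i0, , drop = FALSE])
      i0 <- i0[order(cd, decreasing = TRUE)[seq_len(n)]]
    }
    A <- U[i0, , drop = FALSE]; FA <- FU[i0, , drop = FALSE]
    if (keepHistory)
      history[[t]] <- cbind(contrast = -FA[, 1L], noise = FA[, 2L])
  }

  natural <- cbind(-FA[, 1L], FA[, 2L])
  colnames(natural) <- c("contrast", "noise")
  front <- new("ParetoFront", vectors = A, fitness = natural,
               crowding = crowdingDistance(FA))
  bi <- selectMiddle(front)
  list(front = front, bestIndex = bi, best = A[bi, ], history = history)
}

#' Optimize CLAHE parameters for one image
#'
#' Runs the multi-objective cuckoo search over the 4-D CLAHE parameter space
#' (tilesX, tilesY, clipLimit, alpha), maximizing GLCM contrast of the
#' enhanced image while minimizing its FNVE noise estimate, and returns the
#' balanced middle-of-front solution together with the full Pareto front.
#' Evaluations are cached on the decoded (integer-tile) parameter tuple,
#' since rounding collapses many decision vectors onto one CLAHE setting.
#'
#' @param img a [GrayImage-class].
#' @param bounds a [SearchBounds-class] (default: study search box).
#' @param cfg a [MocsConfig-class] (default: 50 nests, 20 iterations,
#'   discovery probability 0.75).
#' @param glcmCfg a [GlcmConfig-class] for the contrast objective.
#' @param bins CLAHE histogram bins (default 256).
#' @return A list with `best` (a [ClaheParams-class]), `front`
#'   (a [ParetoFront-class]), `bestIndex` and `history` (see
#'   [mocsOptimize()]).
#' @examples
#' \donttest{
#' ph <- generatePhantom(phantomSpec(width = 64, height = 64))
#' res <- optimizeClahe(ph@image, cfg = mocsConfig(population = 8,
#'                                                 iterations = 3))
#' res$best
#' }
#' @export
optimizeClahe <- function(img, bounds = searchBounds(), cfg = mocsConfig(),
                          glcmCfg = glcmConfig(), bins = 256L) {
  cache <- new.env(parent = emptyenv())
  evalFun <- function(v) {
    p <- decodeParams(v, bounds)
    key <- paste(p@tilesX, p@tilesY, sprintf("%.17g", p@clipLimit),
                 sprintf("%.17g", p@alpha), sep = "|")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    fp <- evaluateCandidate(img, p, glcmCfg, bins = bins)
    val <- c(-fp@contrast, fp@noise)
    assign(key, val, envir = cache)
    val
  }
  res <- mocsOptimize(evalFun, bounds, cfg)
  res$best <- decodeParams(res$best, bounds)
  res
}
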