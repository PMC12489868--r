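## Synthetic conjunctiva-like phantoms: dark curvilinear vessels on a
## bright, vignetted scleral background, with controllable exposure,
## defocus blur and additive Gaussian sensor noise.  Every pipeline stage
## can be tested against the recorded ground truth without any study data.

## Stamp one vessel track (random walk with momentum) into a depth map.
.vesselDepth <- function(H, W, vesselWidth) {
  track <- matrix(0, H, W)
  ## start on a random border point heading inward
  side <- sample.int(4L, 1L)
  pos <- switch(side,
    c(1, stats::runif(1, 1, W)),
    c(H, stats::runif(1, 1, W)),
    c(stats::runif(1, 1, H), 1),
    c(stats::runif(1, 1, H), W))
  theta <- switch(side, pi / 2, -pi / 2, 0, pi) +
    stats::runif(1, -0.5, 0.5)
  nSteps <- as.integer(1.5 * max(H, W))
  for (s in seq_len(nSteps)) {
    theta <- theta + stats::rnorm(1, 0, 0.12)   # momentum: smooth turns
    pos <- pos + c(sin(theta), cos(theta))
    r <- round(pos[1L]); cc <- round(pos[2L])
    if (r >= 1 && r <= H && cc >= 1 && cc <= W) track[r, cc] <- 1
  }
  w <- max(0.8, vesselWidth * stats::runif(1, 0.7, 1.3))
  d <- .gaussBlur(track, w / 2)
  if (max(d) > 0) d / max(d) else d
}

#' Generate a synthetic conjunctiva phantom
#'
#' Builds a smooth bright background at `backgroundLevel` with a quadratic
#' radial vignette, carves `nVessels` seeded random-walk vessel tracks with
#' Gaussian cross-sections of depth `vesselContrast` (crossings take the
#' deeper value, not the sum), then applies defocus blur (if `blurSigma` >
#' 0) and adds Gaussian sensor noise clipped to [0, 1].  The ground-truth
#' vessel mask, the pre-clipping noise sigma and the intended exposure class
#' are returned alongside the image.  Bitwise reproducible given the seed.
#'
#' @param spec a [PhantomSpec-class].
#' @return A [PhantomBundle-class].
#' @examples
#' b <- generatePhantom(phantomSpec(seed = 7))
#' b
#' @export
generatePhantom <- function(spec = phantomSpec()) {
  stopifnot(is(spec, "PhantomSpec"))
  validObject(spec)
  set.seed(spec@seed)
  H <- spec@height; W <- spec@width

  ## vignetted background
  yy <- matrix(seq_len(H), H, W); xx <- matrix(seq_len(W), H, W, byrow = TRUE)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  r2 <- ((yy - cy) / (H / 2))^2 + ((xx - cx) / (W / 2))^2
  bg <- spec@backgroundLevel * (1 - spec@vignetteStrength * r2 / max(r2, 1e-12))

  depth <- matrix(0, H, W)
  for (v in seq_len(spec@nVessels))
    depth <- pmax(depth, .vesselDepth(H, W, spec@vesselWidth))
  depth <- depth * spec@vesselContrast
  mask <- depth > 0.5 * spec@vesselContrast & spec@vesselContrast > 0

  clean <- pmax(bg - depth, 0)
  if (spec@blurSigma > 0) clean <- .gaussBlur(clean, spec@blurSigma)
  noisy <- clean
  if (spec@noiseSigma > 0)
    noisy <- noisy + matrix(stats::rnorm(H * W, 0, spec@noiseSigma), H, W)
  img <- grayImage(.clamp01(noisy), 8L)

  new("PhantomBundle", image = img, vesselMask = mask,
      trueNoiseSigma = spec@noiseSigma,
      exposureTarget = classifyExposure(meanLuminosity(img)))
}

#' Generate a frame sequence from one phantom
#'
#' Renders the same underlying phantom once per frame with a per-frame
#' defocus blur taken from `blurSchedule` (noise is redrawn per frame, as a
#' sensor would).  The frame with the smallest scheduled blur is the
#' ground-truth sharpest frame.
#'
#' @param spec a [PhantomSpec-class]; its `blurSigma` is ignored in favour
#'   of the schedule.
#' @param nFrames number of frames.
#' @param blurSchedule numeric vector of per-frame blur sigmas, length
#'   `nFrames`.
#' @param frameRate frames per second metadata (default 50).
#' @return A [FrameSequence-class].
#' @export
generateSequence <- function(spec, nFrames, blurSchedule, frameRate = 50) {
  if (length(blurSchedule) != nFrames)
    stop("'blurSchedule' must have one sigma per frame")
  frames <- lapply(seq_len(nFrames), function(i) {
    s <- spec
    s@blurSigma <- as.numeric(blurSchedule[i])
    s@seed <- spec@seed   # same anatomy ...
    b <- generatePhantom(s)
    ## ... but frame-specific noise: re-draw with a frame-offset seed
    set.seed(spec@seed + 104729L * i)
    px <- .px(b@image)
    if (spec@noiseSigma > 0) {
      sNo <- s; sNo@noiseSigma <- 0
      clean <- .px(generatePhantom(sNo)@image)
      px <- .clamp01(clean + matrix(stats::rnorm(length(clean), 0,
                                                 spec@noiseSigma),
                                    nrow(clean), ncol(clean)))
    }
    grayImage(px, 8L)
  })
  frameSequence(frames, frameRate)
}

#' Generate one phantom per exposure class
#'
#' Produces three phantoms whose background levels are tuned (by a few
#' fixed-point adjustments of the background toward a per-class target mean)
#' so that their mean luminosities fall in (0, 0.6], (0.6, 0.8] and
#' (0.8, 1), i.e. the underexposed, correct and overexposed classes; each
#' result is verified with [classifyExposure()].
#'
#' @param baseSpec a [PhantomSpec-class] used for geometry, noise and seed.
#' @return Named list of three [PhantomBundle-class] objects
#'   (`underexposed`, `correct`, `overexposed`).
#' @export
exposureSuite <- function(baseSpec = phantomSpec()) {
  targets <- c(underexposed = 0.45, correct = 0.72, overexposed = 0.9)
  out <- lapply(names(targets), function(cls) {
    tgt <- targets[[cls]]
    s <- baseSpec
    s@backgroundLevel <- min(1, max(s@vesselContrast, tgt))
    for (k in 1:4) {
      b <- generatePhantom(s)
      off <- tgt - meanLuminosity(b@image)
      if (abs(off) < 0.005) break
      s@backgroundLevel <- min(1, max(s@vesselContrast,
                                      s@backgroundLevel + off))
    }
    b <- generatePhantom(s)
    if (classifyExposure(meanLuminosity(b@image)) != cls)
      stop("could not reach exposure class '", cls,
           "' with the given base specification")
    b
  })
  names(out) <- names(targets)
  out
}
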