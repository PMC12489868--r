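#' @import methods
NULL

## ---------------------------------------------------------------------------
## Core imaging containers
## ---------------------------------------------------------------------------

#' GrayImage: a normalized single-channel luminance image
#'
#' The universal currency of the enhancement pipeline: a numeric matrix of
#' luminance values on the [0, 1] scale, with rows indexing image height (y)
#' and columns indexing width (x).  The original acquisition bit depth is
#' carried along so writers can restore the source scale.
#'
#' @slot pixels numeric matrix of luminance in [0, 1]; rows = height,
#'   columns = width.
#' @slot sourceDepth integer scalar, original bit depth (default 8).
#'
#' @details Images must be at least 3 x 3 pixels: the fast noise variance
#' estimator sums a 3 x 3 operator response over interior pixels and is
#' undefined below that size.
#'
#' @seealso [grayImage()], [fnve()], [clahe()]
#' @exportClass GrayImage
setClass("GrayImage",
  representation(pixels = "matrix", sourceDepth = "integer"),
  prototype(pixels = matrix(0, 3L, 3L), sourceDepth = 8L)
)

setValidity("GrayImage", function(object) {
  px <- object@pixels
  if (!is.numeric(px))
    return("'pixels' must be a numeric matrix")
  if (nrow(px) < 3L || ncol(px) < 3L)
    return("image must be at least 3 x 3 pixels")
  if (anyNA(px) || !all(is.finite(px)))
    return("pixel values must be finite and non-missing")
  if (min(px) < 0 || max(px) > 1)
    return("pixel values must lie in [0, 1]")
  if (length(object@sourceDepth) != 1L || object@sourceDepth < 1L)
    return("'sourceDepth' must be a positive integer scalar")
  TRUE
})

#' Construct a GrayImage
#'
#' @param pixels numeric matrix of luminance values in [0, 1]
#'   (rows = height, columns = width).
#' @param sourceDepth original bit depth of the acquisition (default 8).
#' @return A [GrayImage-class] object.
#' @examples
#' img <- grayImage(matrix(runif(64), 8, 8))
#' meanLuminosity(img)
#' @export
grayImage <- function(pixels, sourceDepth = 8L) {
  new("GrayImage", pixels = pixels, sourceDepth = as.integer(sourceDepth))
}

#' FrameSequence: an ordered list of equally sized frames
#'
#' Holds the value-channel frames of a short video sequence, together with
#' the acquisition frame rate (metadata only; no temporal processing is
#' performed beyond sharpest-frame selection).
#'
#' @slot frames list of [GrayImage-class] objects, all the same size.
#' @slot frameRate numeric scalar, frames per second.
#' @exportClass FrameSequence
setClass("FrameSequence",
  representation(frames = "list", frameRate = "numeric"),
  prototype(frameRate = 50)
)

setValidity("FrameSequence", function(object) {
  if (length(object@frames) == 0L)
    return("a FrameSequence must contain at least one frame")
  if (!all(vapply(object@frames, is, logical(1), class2 = "GrayImage")))
    return("all frames must be GrayImage objects")
  dims <- vapply(object@frames, function(f) dim(f@pixels), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    return("all frames must share the same dimensions")
  TRUE
})

#' Construct a FrameSequence
#'
#' @param frames list of [GrayImage-class] objects sharing one size.
#' @param frameRate frames per second (metadata only).
#' @return A [FrameSequence-class] object.
#' @export
frameSequence <- function(frames, frameRate = 50) {
  new("FrameSequence", frames = frames, frameRate = as.numeric(frameRate))
}

## ---------------------------------------------------------------------------
## CLAHE parameterisation
## ---------------------------------------------------------------------------

#' ClaheParams: the four-dimensional CLAHE decision vector
#'
#' The parameters tuned by the optimizer: the tile grid (horizontal and
#' vertical tile counts), the normalized clip limit and the Rayleigh shape
#' parameter alpha of the output-histogram transfer function.
#'
#' @slot tilesX integer, number of horizontal tiles (>= 2).
#' @slot tilesY integer, number of vertical tiles (>= 2).
#' @slot clipLimit numeric in (0, 1]: per-bin histogram ceiling as a fraction
#'   of the tile pixel count.
#' @slot alpha numeric > 0, Rayleigh shape parameter; larger alpha brightens
#'   the enhanced tile.
#' @exportClass ClaheParams
setClass("ClaheParams",
  representation(tilesX = "integer", tilesY = "integer",
                 clipLimit = "numeric", alpha = "numeric"),
  prototype(tilesX = 8L, tilesY = 8L, clipLimit = 0.01, alpha = 0.6)
)

setValidity("ClaheParams", function(object) {
  if (object@tilesX < 2L || object@tilesY < 2L)
    return("tile counts must be >= 2 (bilinear blending needs a 2 x 2 grid)")
  if (!(object@clipLimit > 0 && object@clipLimit <= 1))
    return("'clipLimit' must lie in (0, 1]")
  if (object@alpha <= 0)
    return("'alpha' must be > 0")
  TRUE
})

#' Construct CLAHE parameters
#'
#' Defaults are the fixed-parameter baseline used throughout: an 8 x 8 tile
#' grid, clip limit 0.01 and Rayleigh alpha 0.6.
#'
#' @param tilesX,tilesY horizontal and vertical tile counts (>= 2).
#' @param clipLimit normalized clip limit in (0, 1].
#' @param alpha Rayleigh shape parameter (> 0).
#' @return A [ClaheParams-class] object.
#' @examples
#' claheParams(8, 8, 0.01, 0.6)
#' @export
claheParams <- function(tilesX = 8L, tilesY = 8L, clipLimit = 0.01,
                        alpha = 0.6) {
  new("ClaheParams", tilesX = as.integer(tilesX), tilesY = as.integer(tilesY),
      clipLimit = as.numeric(clipLimit), alpha = as.numeric(alpha))
}

## ---------------------------------------------------------------------------
## Objectives
## ---------------------------------------------------------------------------

#' GlcmConfig: gray-level co-occurrence matrix settings
#'
#' @slot levels integer >= 2, gray-level quantization (default 8).
#' @slot offset integer 2-vector (row, col) displacement, not (0, 0);
#'   default c(0, 1), i.e. horizontal distance-1 pairs.
#' @slot symmetric logical; if TRUE the matrix is accumulated symmetrically.
#' @exportClass GlcmConfig
setClass("GlcmConfig",
  representation(levels = "integer", offset = "integer", symmetric = "logical"),
  prototype(levels = 8L, offset = c(0L, 1L), symmetric = TRUE)
)

setValidity("GlcmConfig", function(object) {
  if (object@levels < 2L) return("'levels' must be >= 2")
  if (length(object@offset) != 2L || all(object@offset == 0L))
    return("'offset' must be a (row, col) pair different from (0, 0)")
  TRUE
})

#' Construct GLCM settings
#' @param levels gray-level quantization count (default 8).
#' @param offset integer (row, col) displacement (default c(0, 1)).
#' @param symmetric accumulate pairs in both directions (default TRUE).
#' @return A [GlcmConfig-class] object.
#' @export
glcmConfig <- function(levels = 8L, offset = c(0L, 1L), symmetric = TRUE) {
  new("GlcmConfig", levels = as.integer(levels), offset = as.integer(offset),
      symmetric = isTRUE(symmetric))
}

#' FitnessPair: the two objective values of a candidate
#'
#' GLCM contrast (to be maximized) and the FNVE noise standard deviation
#' estimate on the [0, 1] luminance scale (to be minimized).  Internally the
#' optimizer minimizes the pair (-contrast, noise); this class keeps the
#' natural signs.
#'
#' @slot contrast numeric >= 0, GLCM contrast.
#' @slot noise numeric >= 0, FNVE estimate of the noise standard deviation.
#' @exportClass FitnessPair
setClass("FitnessPair",
  representation(contrast = "numeric", noise = "numeric"),
  prototype(contrast = 0, noise = 0)
)

setValidity("FitnessPair", function(object) {
  if (!is.finite(object@contrast) || !is.finite(object@noise))
    return("fitness values must be finite")
  if (object@contrast < 0 || object@noise < 0)
    return("fitness values must be non-negative")
  TRUE
})

#' Construct a FitnessPair
#' @param contrast GLCM contrast (>= 0).
#' @param noise FNVE noise estimate (>= 0).
#' @return A [FitnessPair-class] object.
#' @export
fitnessPair <- function(contrast, noise) {
  new("FitnessPair", contrast = as.numeric(contrast), noise = as.numeric(noise))
}

## ---------------------------------------------------------------------------
## Optimizer configuration and results
## ---------------------------------------------------------------------------

#' SearchBounds: box constraints for the CLAHE decision vector
#'
#' Order of dimensions: (tilesX, tilesY, clipLimit, alpha).  Defaults are the
#' study bounds: tiles 4..12 per axis, clip limit 0.001..0.01, alpha 0.5..0.9.
#'
#' @slot lower numeric 4-vector of lower bounds.
#' @slot upper numeric 4-vector of upper bounds, elementwise > lower.
#' @exportClass SearchBounds
setClass("SearchBounds",
  representation(lower = "numeric", upper = "numeric"),
  prototype(lower = c(4, 4, 0.001, 0.5), upper = c(12, 12, 0.01, 0.9))
)

setValidity("SearchBounds", function(object) {
  if (length(object@lower) != length(object@upper))
    return("'lower' and 'upper' must have the same length")
  if (!all(is.finite(object@lower)) || !all(is.finite(object@upper)))
    return("bounds must be finite")
  if (!all(object@lower < object@upper))
    return("'lower' must be elementwise strictly below 'upper'")
  TRUE
})

#' Construct search bounds
#' @param lower,upper numeric vectors (tilesX, tilesY, clipLimit, alpha);
#'   defaults are the study search box.
#' @return A [SearchBounds-class] object.
#' @export
searchBounds <- function(lower = c(4, 4, 0.001, 0.5),
                         upper = c(12, 12, 0.01, 0.9)) {
  new("SearchBounds", lower = as.numeric(lower), upper = as.numeric(upper))
}

#' MocsConfig: multi-objective cuckoo search settings
#'
#' Defaults follow the study settings: 50 nests, 20 iterations and a survival
#' probability of 25%, i.e. a discovery (abandonment) probability of 0.75.
#' The Levy exponent and step scale are the customary cuckoo-search values.
#'
#' @slot population integer >= 4, number of nests.
#' @slot iterations integer >= 1, number of generations.
#' @slot pDiscovery numeric in [0, 1], per-coordinate abandonment probability.
#' @slot levyBeta numeric in (1, 2], Levy flight exponent.
#' @slot stepScale numeric > 0, Levy step size as a fraction of the
#'   per-dimension bound range.
#' @slot seed integer RNG seed; every stochastic operator draws from a stream
#'   seeded with it, making runs fully reproducible.
#' @exportClass MocsConfig
setClass("MocsConfig",
  representation(population = "integer", iterations = "integer",
                 pDiscovery = "numeric", levyBeta = "numeric",
                 stepScale = "numeric", seed = "integer"),
  prototype(population = 50L, iterations = 20L, pDiscovery = 0.75,
            levyBeta = 1.5, stepScale = 0.01, seed = 1L)
)

setValidity("MocsConfig", function(object) {
  if (object@population < 4L) return("'population' must be >= 4")
  if (object@iterations < 1L) return("'iterations' must be >= 1")
  if (object@pDiscovery < 0 || object@pDiscovery > 1)
    return("'pDiscovery' must lie in [0, 1]")
  if (!(object@levyBeta > 1 && object@levyBeta <= 2))
    return("'levyBeta' must lie in (1, 2]")
  if (object@stepScale <= 0) return("'stepScale' must be > 0")
  TRUE
})

#' Construct MOCS settings
#' @param population number of nests (default 50).
#' @param iterations number of generations (default 20).
#' @param pDiscovery abandonment probability P_a (default 0.75, i.e. a 25%
#'   survival probability).
#' @param levyBeta Levy exponent in (1, 2] (default 1.5).
#' @param stepScale Levy step size as a fraction of the bound range
#'   (default 0.01).
#' @param seed RNG seed (default 1).
#' @return A [MocsConfig-class] object.
#' @export
mocsConfig <- function(population = 50L, iterations = 20L, pDiscovery = 0.75,
                       levyBeta = 1.5, stepScale = 0.01, seed = 1L) {
  new("MocsConfig", population = as.integer(population),
      iterations = as.integer(iterations), pDiscovery = as.numeric(pDiscovery),
      levyBeta = as.numeric(levyBeta), stepScale = as.numeric(stepScale),
      seed = as.integer(seed))
}

#' ParetoFront: archive of mutually non-dominated candidates
#'
#' @slot vectors numeric matrix (n x d) of decision vectors.
#' @slot fitness numeric matrix (n x 2) with columns (contrast, noise) in
#'   natural signs: contrast is maximized, noise minimized.
#' @slot crowding numeric vector of crowding distances; boundary members
#'   are +Inf.
#' @exportClass ParetoFront
setClass("ParetoFront",
  representation(vectors = "matrix", fitness = "matrix", crowding = "numeric")
)

setValidity("ParetoFront", function(object) {
  n <- nrow(object@vectors)
  if (n == 0L) return("a ParetoFront must have at least one member")
  if (nrow(object@fitness) != n || ncol(object@fitness) != 2L)
    return("'fitness' must be an n x 2 matrix (contrast, noise)")
  if (length(object@crowding) != n)
    return("'crowding' must have one entry per member")
  fmin <- cbind(-object@fitness[, 1L], object@fitness[, 2L])
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i != j && all(fmin[i, ] <= fmin[j, ]) && any(fmin[i, ] < fmin[j, ]))
      return("front members must be mutually non-dominated")
  }
  TRUE
})

## ---------------------------------------------------------------------------
## Quality metrics / phantoms / pipeline
## ---------------------------------------------------------------------------

#' QualityReport: full-reference quality of an enhanced image
#'
#' @slot psnr numeric, peak signal-to-noise ratio in decibels (may be +Inf
#'   for identical images).
#' @slot ssim numeric in [-1, 1], global structural similarity.
#' @slot niqe numeric, optional no-reference score supplied by an external
#'   evaluator; NA when absent.
#' @exportClass QualityReport
setClass("QualityReport",
  representation(psnr = "numeric", ssim = "numeric", niqe = "numeric"),
  prototype(psnr = NA_real_, ssim = NA_real_, niqe = NA_real_)
)

setValidity("QualityReport", function(object) {
  if (!is.na(object@ssim) && object@ssim > 1 + 1e-12)
    return("'ssim' cannot exceed 1")
  TRUE
})

#' PhantomSpec: parameters of the synthetic conjunctiva phantom
#'
#' Describes a bright, vignetted scleral background crossed by dark
#' curvilinear vessels, with optional defocus blur and additive Gaussian
#' sensor noise.  All intensities are on the [0, 1] scale.
#'
#' @slot width,height image size in pixels.
#' @slot nVessels number of vessel tracks.
#' @slot vesselWidth mean vessel width in pixels.
#' @slot vesselContrast luminance drop at the vessel centerline, in [0, 1].
#' @slot backgroundLevel target background luminance in [0, 1].
#' @slot vignetteStrength radial darkening toward the corners, in [0, 1).
#' @slot noiseSigma standard deviation of additive Gaussian noise.
#' @slot blurSigma Gaussian defocus blur sigma in pixels (0 = sharp).
#' @slot seed integer RNG seed.
#' @exportClass PhantomSpec
setClass("PhantomSpec",
  representation(width = "integer", height = "integer", nVessels = "integer",
                 vesselWidth = "numeric", vesselContrast = "numeric",
                 backgroundLevel = "numeric", vignetteStrength = "numeric",
                 noiseSigma = "numeric", blurSigma = "numeric",
                 seed = "integer"),
  prototype(width = 128L, height = 128L, nVessels = 6L, vesselWidth = 3,
            vesselContrast = 0.35, backgroundLevel = 0.75,
            vignetteStrength = 0.15, noiseSigma = 0.01, blurSigma = 0,
            seed = 1L)
)

setValidity("PhantomSpec", function(object) {
  if (object@width < 3L || object@height < 3L)
    return("phantom must be at least 3 x 3 pixels")
  if (object@nVessels < 0L) return("'nVessels' must be >= 0")
  if (object@vesselWidth <= 0) return("'vesselWidth' must be > 0")
  if (object@vesselContrast < 0 || object@vesselContrast > 1)
    return("'vesselContrast' must lie in [0, 1]")
  if (object@backgroundLevel < 0 || object@backgroundLevel > 1)
    return("'backgroundLevel' must lie in [0, 1]")
  if (object@backgroundLevel - object@vesselContrast < 0)
    return("'backgroundLevel' must be >= 'vesselContrast' (vessels cannot go below black)")
  if (object@vignetteStrength < 0 || object@vignetteStrength >= 1)
    return("'vignetteStrength' must lie in [0, 1)")
  if (object@noiseSigma < 0) return("'noiseSigma' must be >= 0")
  if (object@blurSigma < 0) return("'blurSigma' must be >= 0")
  TRUE
})

#' Construct a phantom specification
#'
#' Defaults emulate a correct-exposure acquisition: a bright (0.75) vignetted
#' background, six dark vessels of ~3 px width and 0.35 contrast, mild sensor
#' noise (sigma 0.01) and no defocus.
#'
#' @param width,height image size in pixels (default 128 x 128).
#' @param nVessels number of vessel tracks (default 6).
#' @param vesselWidth mean vessel width in pixels (default 3).
#' @param vesselContrast centerline luminance drop (default 0.35).
#' @param backgroundLevel background luminance (default 0.75).
#' @param vignetteStrength radial darkening strength (default 0.15).
#' @param noiseSigma additive Gaussian noise sigma (default 0.01).
#' @param blurSigma defocus blur sigma in pixels (default 0).
#' @param seed RNG seed (default 1).
#' @return A [PhantomSpec-class] object.
#' @export
phantomSpec <- function(width = 128L, height = 128L, nVessels = 6L,
                        vesselWidth = 3, vesselContrast = 0.35,
                        backgroundLevel = 0.75, vignetteStrength = 0.15,
                        noiseSigma = 0.01, blurSigma = 0, seed = 1L) {
  new("PhantomSpec", width = as.integer(width), height = as.integer(height),
      nVessels = as.integer(nVessels), vesselWidth = as.numeric(vesselWidth),
      vesselContrast = as.numeric(vesselContrast),
      backgroundLevel = as.numeric(backgroundLevel),
      vignetteStrength = as.numeric(vignetteStrength),
      noiseSigma = as.numeric(noiseSigma), blurSigma = as.numeric(blurSigma),
      seed = as.integer(seed))
}

#' PhantomBundle: a phantom image with its ground truth
#'
#' @slot image the noisy [GrayImage-class] phantom.
#' @slot vesselMask logical matrix marking vessel pixels.
#' @slot trueNoiseSigma the noise sigma actually added (pre-clipping).
#' @slot exposureTarget the exposure class the phantom was built for.
#' @exportClass PhantomBundle
setClass("PhantomBundle",
  representation(image = "GrayImage", vesselMask = "matrix",
                 trueNoiseSigma = "numeric", exposureTarget = "character")
)

setValidity("PhantomBundle", function(object) {
  if (!identical(dim(object@vesselMask), dim(object@image@pixels)))
    return("mask dimensions must match the image")
  if (!is.logical(object@vesselMask))
    return("'vesselMask' must be logical")
  TRUE
})

#' PipelineConfig: settings for the end-to-end enhancement pipeline
#'
#' @slot bounds [SearchBounds-class] for the optimizer.
#' @slot mocs [MocsConfig-class] optimizer settings.
#' @slot glcm [GlcmConfig-class] contrast-objective settings.
#' @slot fixedClahe [ClaheParams-class] baseline comparator parameters
#'   (default 8 x 8 tiles, clip 0.01, alpha 0.6).
#' @slot logSigma numeric, Laplacian-of-Gaussian sigma for frame selection.
#' @slot metricsL integer, gray-level count for PSNR/SSIM (default 256).
#' @exportClass PipelineConfig
setClass("PipelineConfig",
  representation(bounds = "SearchBounds", mocs = "MocsConfig",
                 glcm = "GlcmConfig", fixedClahe = "ClaheParams",
                 logSigma = "numeric", metricsL = "integer")
)

setValidity("PipelineConfig", function(object) {
  if (object@logSigma <= 0) return("'logSigma' must be > 0")
  if (object@metricsL < 2L) return("'metricsL' must be >= 2")
  TRUE
})

#' Construct a pipeline configuration
#' @param bounds optimizer search bounds.
#' @param mocs optimizer settings.
#' @param glcm GLCM settings for the contrast objective.
#' @param fixedClahe baseline CLAHE parameters (8 x 8, clip 0.01, alpha 0.6).
#' @param logSigma LoG sigma for the focus measure (default 2).
#' @param metricsL gray levels for the quality metrics (default 256).
#' @return A [PipelineConfig-class] object.
#' @export
pipelineConfig <- function(bounds = searchBounds(), mocs = mocsConfig(),
                           glcm = glcmConfig(), fixedClahe = claheParams(),
                           logSigma = 2, metricsL = 256L) {
  new("PipelineConfig", bounds = bounds, mocs = mocs, glcm = glcm,
      fixedClahe = fixedClahe, logSigma = as.numeric(logSigma),
      metricsL = as.integer(metricsL))
}

#' RunReport: the result of one pipeline run
#'
#' @slot inputId character label of the input.
#' @slot exposure exposure class of the analysed frame.
#' @slot frameIndex index of the selected (sharpest) frame; 1 for stills.
#' @slot optimizedParams [ClaheParams-class] chosen by the optimizer.
#' @slot fixedParams [ClaheParams-class] of the baseline arm.
#' @slot originalFitness,fixedFitness,mocsFitness [FitnessPair-class] of the
#'   original image and of the two enhancement arms.
#' @slot fixedQuality,mocsQuality [QualityReport-class] of each arm against
#'   the original.
#' @slot front [ParetoFront-class] archive of the optimizer run.
#' @slot fixedImage,mocsImage enhanced [GrayImage-class] outputs.
#' @slot seed integer seed used.
#' @slot timestamps character vector (start, end) in ISO 8601.
#' @exportClass RunReport
setClass("RunReport",
  representation(inputId = "character", exposure = "character",
                 frameIndex = "integer", optimizedParams = "ClaheParams",
                 fixedParams = "ClaheParams", originalFitness = "FitnessPair",
                 fixedFitness = "FitnessPair", mocsFitness = "FitnessPair",
                 fixedQuality = "QualityReport", mocsQuality = "QualityReport",
                 front = "ParetoFront", fixedImage = "GrayImage",
                 mocsImage = "GrayImage", seed = "integer",
                 timestamps = "character")
)

## ---------------------------------------------------------------------------
## show() methods
## ---------------------------------------------------------------------------

setMethod("show", "GrayImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf("GrayImage: %d x %d (H x W), %d-bit source, range [%.3f, %.3f]\n",
              d[1], d[2], object@sourceDepth,
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "FrameSequence", function(object) {
  d <- dim(object@frames[[1]]@pixels)
  cat(sprintf("FrameSequence: %d frame(s) of %d x %d at %.1f fps\n",
              length(object@frames), d[1], d[2], object@frameRate))
})

setMethod("show", "ClaheParams", function(object) {
  cat(sprintf("ClaheParams: %d x %d tiles, clip %.4g, Rayleigh alpha %.3g\n",
              object@tilesX, object@tilesY, object@clipLimit, object@alpha))
})

setMethod("show", "FitnessPair", function(object) {
  cat(sprintf("FitnessPair: contrast %.4g (maximize), FNVE %.4g (minimize)\n",
              object@contrast, object@noise))
})

setMethod("show", "ParetoFront", function(object) {
  cat(sprintf("ParetoFront: %d member(s)\n", nrow(object@vectors)))
  cat(sprintf("  contrast range [%.4g, %.4g], noise range [%.4g, %.4g]\n",
              min(object@fitness[, 1]), max(object@fitness[, 1]),
              min(object@fitness[, 2]), max(object@fitness[, 2])))
})

setMethod("show", "QualityReport", function(object) {
  cat(sprintf("QualityReport: PSNR %.2f dB, SSIM %.4f, NIQE %s\n",
              object@psnr, object@ssim,
              if (is.na(object@niqe)) "not evaluated" else
                sprintf("%.3f", object@niqe)))
})

setMethod("show", "PhantomBundle", function(object) {
  cat(sprintf(
    "PhantomBundle: %d x %d, %.1f%% vessel pixels, true sigma %.4g, target '%s'\n",
    nrow(object@image@pixels), ncol(object@image@pixels),
    100 * mean(object@vesselMask), object@trueNoiseSigma,
    object@exposureTarget))
})

setMethod("show", "RunReport", function(object) {
  cat(sprintf("RunReport for '%s' (%s, frame %d, seed %d)\n",
              object@inputId, object@exposure, object@frameIndex, object@seed))
  cat("  optimized: "); show(object@optimizedParams)
  cat(sprintf("  contrast  original %.4g | fixed %.4g | MOCS %.4g\n",
              object@originalFitness@contrast, object@fixedFitness@contrast,
              object@mocsFitness@contrast))
  cat(sprintf("  FNVE      original %.4g | fixed %.4g | MOCS %.4g\n",
              object@originalFitness@noise, object@fixedFitness@noise,
              object@mocsFitness@noise))
  cat(sprintf("  quality   fixed PSNR %.2f / SSIM %.4f | MOCS PSNR %.2f / SSIM %.4f\n",
              object@fixedQuality@psnr, object@fixedQuality@ssim,
              object@mocsQuality@psnr, object@mocsQuality@ssim))
})
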