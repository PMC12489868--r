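#' Extract the HSV value channel from an RGB image
#'
#' Isolates luminance from chromatic information by keeping the value (V)
#' channel of the HSV decomposition, which for each pixel is simply the
#' maximum of the red, green and blue components.
#'
#' @param rgb a numeric array of dimension H x W x 3 with values in [0, 1],
#'   or an [EBImage::Image] in color mode (stored width-first; it is
#'   transposed internally).
#' @param sourceDepth bit depth to record on the result (default 8).
#' @return A [GrayImage-class] with V = max(R, G, B) per pixel.
#' @examples
#' arr <- array(runif(3 * 12 * 16), c(12, 16, 3))
#' v <- rgbToValue(arr)
#' all(pixels(v) == pmax(arr[,,1], arr[,,2], arr[,,3]))
#' @export
rgbToValue <- function(rgb, sourceDepth = 8L) {
  if (is(rgb, "Image")) {
    d <- EBImage::imageData(rgb)
    if (length(dim(d)) != 3L || dim(d)[3] != 3L)
      stop("expected a three-channel (RGB) image")
    rgb <- aperm(d, c(2L, 1L, 3L))   # EBImage stores x (width) first
  }
  if (!(is.array(rgb) && length(dim(rgb)) == 3L && dim(rgb)[3] == 3L))
    stop("expected an H x W x 3 array with exactly three channels")
  if (min(rgb) < 0 || max(rgb) > 1)
    stop("RGB values must lie in [0, 1]")
  v <- pmax(rgb[, , 1L], rgb[, , 2L], rgb[, , 3L])
  grayImage(v, sourceDepth)
}

#' Average image luminosity
#'
#' The arithmetic mean of all pixel values (V_avg), the statistic used to
#' classify the exposure of an acquisition.
#'
#' @param img a [GrayImage-class] or numeric matrix in [0, 1].
#' @return Scalar mean luminosity in [0, 1].
#' @export
meanLuminosity <- function(img) {
  px <- .px(img)
  if (length(px) == 0L) stop("empty image")
  mean(px)
}

#' Classify exposure from average luminosity
#'
#' Conjunctival images have negatively skewed histograms dominated by the
#' bright scleral background, so a correctly exposed image sits well above
#' mid-gray.  The class boundaries are V_avg <= 0.6 (underexposed),
#' 0.6 < V_avg <= 0.8 (correct) and V_avg > 0.8 (overexposed); both
#' boundaries belong to the lower class.
#'
#' @param vAvg mean luminosity in [0, 1] (see [meanLuminosity()]), or a
#'   [GrayImage-class] whose mean luminosity is computed first.
#' @return One of `"underexposed"`, `"correct"`, `"overexposed"`.
#' @examples
#' classifyExposure(0.6)   # boundary -> underexposed
#' classifyExposure(0.75)  # correct
#' @export
classifyExposure <- function(vAvg) {
  if (is(vAvg, "GrayImage") || is.matrix(vAvg)) vAvg <- meanLuminosity(vAvg)
  if (!is.numeric(vAvg) || length(vAvg) != 1L || is.na(vAvg))
    stop("'vAvg' must be a numeric scalar")
  if (vAvg < 0 || vAvg > 1) stop("'vAvg' must lie in [0, 1]")
  if (vAvg <= 0.6) "underexposed" else if (vAvg <= 0.8) "correct" else
    "overexposed"
}

#' Laplacian-of-Gaussian focus measure
#'
#' Filters the image with a zero-sum Laplacian-of-Gaussian kernel (support
#' half-width ceil(3 sigma), reflect boundary) and returns the variance of
#' the response.  Sharper, better focused frames give larger variance;
#' a constant image gives exactly 0.
#'
#' @param img a [GrayImage-class] or numeric matrix.
#' @param logSigma Gaussian scale of the LoG kernel in pixels (default 2).
#' @return Non-negative sharpness score.
#' @export
sharpnessLogVariance <- function(img, logSigma = 2) {
  if (!is.numeric(logSigma) || length(logSigma) != 1L || logSigma <= 0)
    stop("'logSigma' must be a positive scalar")
  px <- .px(img)
  r <- .filterSame(px, .logKernel(logSigma))
  stats::var(as.vector(r))
}

#' Select the sharpest frame of a sequence
#'
#' Returns the index of the frame with the largest Laplacian-of-Gaussian
#' focus score ([sharpnessLogVariance()]); ties are broken toward the lowest
#' index so selection is deterministic.
#'
#' @param seq a [FrameSequence-class].
#' @param logSigma LoG scale for the focus measure (default 2).
#' @return Integer frame index (1-based).
#' @export
selectSharpestFrame <- function(seq, logSigma = 2) {
  if (!is(seq, "FrameSequence")) stop("'seq' must be a FrameSequence")
  if (length(seq@frames) == 0L) stop("empty frame sequence")
  scores <- vapply(seq@frames, sharpnessLogVariance, numeric(1),
                   logSigma = logSigma)
  which.max(scores)   # which.max returns the first maximum
}
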