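#' Histogram of a tile region
#'
#' Counts pixel values of a rectangular region into `bins` equal-width bins
#' over [0, 1].  A value v falls into bin floor(v * bins) + 1, with v = 1
#' assigned to the last bin.
#'
#' @param img a [GrayImage-class] or numeric matrix in [0, 1].
#' @param region integer 4-vector (rowStart, rowEnd, colStart, colEnd),
#'   1-based inclusive.
#' @param bins number of histogram bins (>= 2, default 256).
#' @return Integer vector of counts summing to the region's pixel count.
#' @export
tileHistogram <- function(img, region, bins = 256L) {
  px <- .px(img)
  bins <- as.integer(bins)
  if (bins < 2L) stop("'bins' must be >= 2")
  r <- as.integer(region)
  if (length(r) != 4L || r[1] < 1L || r[3] < 1L ||
      r[2] > nrow(px) || r[4] > ncol(px) || r[1] > r[2] || r[3] > r[4])
    stop("'region' must be (rowStart, rowEnd, colStart, colEnd) inside the image")
  v <- px[r[1]:r[2], r[3]:r[4]]
  idx <- pmin(floor(v * bins) + 1L, bins)
  tabulate(idx, nbins = bins)
}

#' Clip a histogram and redistribute the excess
#'
#' Bins are ceiled at `clipCount`; the clipped-off mass is redistributed
#' equally over all bins, which may push some bins back over the limit, so
#' the clip/redistribute step is iterated (up to `maxIter` times, stopping
#' early once the remaining excess is negligible).  When the limit is
#' feasible (clipCount x bins >= total mass) this converges to the exact
#' fixed point: saturated bins sit at the limit and the excess is spread
#' equally over the rest.  Total mass is conserved.
#'
#' @param hist numeric vector of non-negative counts.
#' @param clipCount positive per-bin ceiling (counts).
#' @param maxIter maximum clip/redistribute sweeps (default 50).
#' @return Numeric vector, same length and sum as `hist`.
#' @examples
#' clipAndRedistribute(c(10, 0, 0, 0), 4)  # -> 4, 2, 2, 2
#' @export
clipAndRedistribute <- function(hist, clipCount, maxIter = 50L) {
  if (!is.numeric(clipCount) || length(clipCount) != 1L || clipCount <= 0)
    stop("'clipCount' must be a positive scalar")
  if (any(hist < 0)) stop("histogram counts must be non-negative")
  h <- as.numeric(hist)
  total <- sum(h)
  if (total == 0) return(h)
  tol <- 1e-12 * total
  for (i in seq_len(maxIter)) {
    excess <- sum(pmax(h - clipCount, 0))
    if (excess <= tol) break
    h <- pmin(h, clipCount) + excess / length(h)
  }
  h
}

#' Rayleigh transfer function
#'
#' Maps a tile's clipped cumulative distribution c to output gray levels so
#' that the output histogram follows a Rayleigh distribution of shape
#' `alpha`.  The underlying closed form is the Rayleigh quantile function
#' g(c) = gMin + sqrt(2 alpha^2 ln(1 / (1 - c))); available as-is with
#' `rescale = FALSE` (c clamped to at most 1 - eps before the logarithm).
#'
#' By default (`rescale = TRUE`) the range-normalized form used by adaptive
#' equalization implementations is returned: c is pre-compressed by
#' vmax = 1 - exp(-1 / (2 alpha^2)) so that
#' g(c) = gMin + (gMax - gMin) sqrt(-2 alpha^2 ln(1 - vmax c)) spans exactly
#' [gMin, gMax].  Note a plain affine rescale of the raw quantile would
#' cancel alpha entirely (it is a pure scale factor there); the vmax
#' compression is what lets alpha genuinely steer the curvature, and hence
#' the brightness, of the mapping -- larger alpha approaches the (brighter)
#' square-root mapping, smaller alpha darkens the midtones.
#'
#' @param cdf non-decreasing numeric vector in [0, 1], last entry ~ 1.
#' @param alpha Rayleigh shape parameter (> 0); larger values brighten the
#'   output.
#' @param gMin,gMax output luminance range (defaults 0 and 1).
#' @param eps clamp on 1 - c before the logarithm in the raw
#'   (`rescale = FALSE`) form (default 1e-4; inside [clahe()] it is
#'   1 / tile pixel count).  Unused by the range-normalized form, whose
#'   logarithm argument is bounded away from zero by construction.
#' @param rescale use the range-normalized mapping spanning [gMin, gMax]
#'   (default TRUE); with FALSE the raw closed form is returned.
#' @return Numeric look-up table, non-decreasing, in [gMin, gMax] when
#'   rescaled.
#' @export
rayleighTransfer <- function(cdf, alpha, gMin = 0, gMax = 1, eps = 1e-4,
                             rescale = TRUE) {
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0)
    stop("'alpha' must be a positive scalar")
  if (any(diff(cdf) < -1e-12)) stop("'cdf' must be non-decreasing")
  if (rescale) {
    vmax <- 1 - exp(-1 / (2 * alpha^2))
    cc <- pmin(pmax(cdf, 0), 1)
    g <- gMin + (gMax - gMin) * sqrt(-2 * alpha^2 * log(1 - vmax * cc))
  } else {
    cc <- pmin(pmax(cdf, 0), 1 - eps)
    g <- gMin + sqrt(2 * alpha^2 * log(1 / (1 - cc)))
  }
  cummax(g)   # guard monotonicity against floating round-off
}

## Per-tile look-up tables for a padded image.
.claheLuts <- function(P, tilesX, tilesY, tw, th, clipLimit, alpha, bins) {
  npix <- tw * th
  clipCount <- max(1, clipLimit * npix)
  eps <- 1 / npix
  K <- pmin(floor(P * bins) + 1L, bins)   # bin index of every padded pixel
  luts <- array(0, dim = c(tilesY, tilesX, bins))
  for (j in seq_len(tilesY)) {
    rows <- ((j - 1L) * th + 1L):(j * th)
    for (i in seq_len(tilesX)) {
      cols <- ((i - 1L) * tw + 1L):(i * tw)
      h <- tabulate(K[rows, cols], nbins = bins)
      h <- clipAndRedistribute(h, clipCount)
      cdf <- cumsum(h) / sum(h)
      luts[j, i, ] <- rayleighTransfer(cdf, alpha, 0, 1, eps)
    }
  }
  list(luts = luts, K = K)
}

#' Contrast-limited adaptive histogram equalization with Rayleigh output
#'
#' Divides the image into `tilesX` x `tilesY` non-overlapping tiles, clips
#' each tile histogram at `clipLimit` x (tile pixel count) with equal
#' redistribution of the excess, shapes each tile's transfer function to a
#' Rayleigh output distribution ([rayleighTransfer()]), and blends the tile
#' mappings by bilinear interpolation between the four nearest tile centers
#' (linear along edges, nearest at corners), which suppresses blocking
#' artifacts at tile boundaries.  Images whose size is not a multiple of the
#' tile grid are reflect-padded symmetrically and cropped back afterwards.
#'
#' @param img a [GrayImage-class] or numeric matrix in [0, 1].
#' @param params a [ClaheParams-class].
#' @param bins histogram bin count (default 256, matching 8-bit acquisition).
#' @return Enhanced image of the same class and size as the input, in [0, 1].
#' @examples
#' img <- grayImage(matrix(runif(32 * 32, 0.4, 0.6), 32, 32))
#' out <- clahe(img, claheParams(4, 4, 0.01, 0.6))
#' range(pixels(out))
#' @export
clahe <- function(img, params, bins = 256L) {
  stopifnot(is(params, "ClaheParams"))
  validObject(params)
  px <- .px(img)
  H <- nrow(px); W <- ncol(px)
  tx <- params@tilesX; ty <- params@tilesY
  if (W < tx || H < ty)
    stop("tile grid incompatible with image size: fewer than one pixel per tile")
  tw <- ceiling(W / tx); th <- ceiling(H / ty)
  padW <- tw * tx - W; padH <- th * ty - H
  top <- padH %/% 2L; bottom <- padH - top
  left <- padW %/% 2L; right <- padW - left
  P <- .padReflect(px, top, bottom, left, right)
  Hp <- nrow(P); Wp <- ncol(P)

  lk <- .claheLuts(P, tx, ty, tw, th, params@clipLimit, params@alpha,
                   as.integer(bins))
  luts <- lk$luts; K <- lk$K

  ## Bilinear blending between tile-center nodes; indices clamped so pixels
  ## beyond the outer ring of centers extend linearly/nearest.
  ## Outside the outer ring of centers both neighbor indices clamp to the
  ## same node, so the interpolation collapses to the nearest tile mapping.
  yc <- (seq_len(Hp) - 0.5) / th - 0.5
  j0 <- floor(yc); fy <- yc - j0
  j0c <- pmin(pmax(j0, 0), ty - 1L); j1c <- pmin(pmax(j0 + 1, 0), ty - 1L)

  xc <- (seq_len(Wp) - 0.5) / tw - 0.5
  i0 <- floor(xc); fx <- xc - i0
  i0c <- pmin(pmax(i0, 0), tx - 1L); i1c <- pmin(pmax(i0 + 1, 0), tx - 1L)

  lut1 <- function(jrow, icol) {
    ## value of tile (jrow, icol) lut at each pixel's bin
    J <- matrix(jrow, Hp, Wp)
    I <- matrix(icol, Hp, Wp, byrow = TRUE)
    matrix(luts[cbind(as.vector(J), as.vector(I), as.vector(K))], Hp, Wp)
  }
  v00 <- lut1(j0c + 1L, i0c + 1L)
  v01 <- lut1(j0c + 1L, i1c + 1L)
  v10 <- lut1(j1c + 1L, i0c + 1L)
  v11 <- lut1(j1c + 1L, i1c + 1L)
  WY <- matrix(fy, Hp, Wp)
  WX <- matrix(fx, Hp, Wp, byrow = TRUE)
  out <- (1 - WY) * ((1 - WX) * v00 + WX * v01) +
         WY * ((1 - WX) * v10 + WX * v11)

  out <- out[(top + 1L):(top + H), (left + 1L):(left + W), drop = FALSE]
  out <- .clamp01(out)
  if (is(img, "GrayImage")) grayImage(out, img@sourceDepth) else out
}
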