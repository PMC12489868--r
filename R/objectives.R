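#' Gray-level co-occurrence matrix
#'
#' Normalized joint frequency of gray-level pairs at a fixed (row, col)
#' displacement.  Pixel values are quantized to `levels(cfg)` equal-width
#' bins over [0, 1]; with `symmetric = TRUE` each ordered pair is counted in
#' both directions, so the matrix equals its transpose.
#'
#' @param img a [GrayImage-class] or numeric matrix in [0, 1].  Plain
#'   matrices of any size (e.g. a single row) are accepted as long as at
#'   least one offset pair exists.
#' @param cfg a [GlcmConfig-class] (default: 8 levels, offset (0, 1),
#'   symmetric).
#' @return levels x levels numeric matrix with non-negative entries summing
#'   to 1.
#' @examples
#' m <- matrix(c(0, 1, 0, 1), 1, 4)   # alternating two-level row
#' glcm(m, glcmConfig(levels = 2))    # all mass off-diagonal
#' @export
glcm <- function(img, cfg = glcmConfig()) {
  stopifnot(is(cfg, "GlcmConfig"))
  validObject(cfg)
  px <- .px(img)
  L <- cfg@levels
  dr <- cfg@offset[1L]; dc <- cfg@offset[2L]
  H <- nrow(px); W <- ncol(px)
  r1 <- max(1L, 1L - dr); r2 <- min(H, H - dr)
  c1 <- max(1L, 1L - dc); c2 <- min(W, W - dc)
  if (r1 > r2 || c1 > c2) stop("no valid pixel pairs for this offset")
  Q <- pmin(floor(px * L), L - 1L)   # 0-based gray level
  a <- Q[r1:r2, c1:c2, drop = FALSE]
  b <- Q[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
  counts <- tabulate(as.vector(a) * L + as.vector(b) + 1L, nbins = L * L)
  M <- matrix(counts, L, L, byrow = TRUE)   # M[i+1, j+1] = #(i -> j)
  if (cfg@symmetric) M <- M + t(M)
  M / sum(M)
}

#' GLCM contrast
#'
#' The Haralick contrast statistic sum_(i,j) (i - j)^2 p(i, j), measuring
#' local intensity variation; 0 for a constant image (all mass on the
#' diagonal) and at most (levels - 1)^2.
#'
#' @param P a normalized GLCM as returned by [glcm()] (entries sum to 1
#'   within 1e-6).
#' @return Non-negative scalar.
#' @export
glcmContrast <- function(P) {
  if (!is.matrix(P) || nrow(P) != ncol(P))
    stop("'P' must be a square matrix")
  if (abs(sum(P) - 1) > 1e-6)
    stop("'P' must be normalized (entries summing to 1)")
  idx <- seq_len(nrow(P))
  D2 <- outer(idx, idx, function(i, j) (i - j)^2)
  sum(D2 * P)
}

#' Fast noise variance estimation (FNVE)
#'
#' Estimates the standard deviation of additive Gaussian noise from a single
#' image by convolving with the difference of two 3 x 3 Laplacian
#' approximations, N = [1 -2 1; -2 4 -2; 1 -2 1], which annihilates constant
#' and linearly ramping intensity while passing noise.  The estimate is
#'
#'   sigma_n = sqrt(pi / 2) * (1 / (6 (W - 2)(H - 2))) * sum |I * N|
#'
#' with the sum over interior pixels only (valid convolution).  The factor
#' follows from E|Z| = sigma sqrt(2 / pi) for Gaussian Z and from the
#' operator's coefficient norm (its squared-coefficient sum is 36, so the
#' response variance is 36 sigma_n^2).
#'
#' @param img a [GrayImage-class] or numeric matrix, at least 3 x 3.
#' @return Noise standard deviation estimate on the [0, 1] luminance scale
#'   (multiply by 255 to compare with 8-bit-scale figures).
#' @examples
#' fnve(matrix(0.5, 16, 16))                     # exactly 0
#' set.seed(1)
#' fnve(matrix(rnorm(256^2, 0.5, 0.05), 256))    # ~ 0.05
#' @export
fnve <- function(img) {
  px <- .px(img)
  H <- nrow(px); W <- ncol(px)
  if (H < 3L || W < 3L) stop("FNVE requires an image of at least 3 x 3 pixels")
  N <- matrix(c(1, -2, 1, -2, 4, -2, 1, -2, 1), 3, 3, byrow = TRUE)
  r <- .filterValid(px, N)
  sqrt(pi / 2) * sum(abs(r)) / (6 * (W - 2) * (H - 2))
}

#' Evaluate a CLAHE candidate on both objectives
#'
#' Applies CLAHE with the candidate parameters and measures the enhanced
#' image with the two optimizer objectives: GLCM contrast (to maximize) and
#' the FNVE noise estimate (to minimize).  Deterministic for fixed inputs.
#'
#' @param img a [GrayImage-class].
#' @param params a [ClaheParams-class].
#' @param cfg a [GlcmConfig-class] for the contrast objective.
#' @param bins CLAHE histogram bins (default 256).
#' @return A [FitnessPair-class].
#' @export
evaluateCandidate <- function(img, params, cfg = glcmConfig(), bins = 256L) {
  enhanced <- clahe(img, params, bins = bins)
  fitnessPair(glcmContrast(glcm(enhanced, cfg)), fnve(enhanced))
}
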