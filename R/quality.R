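#' Mean squared error on the gray-level scale
#'
#' Images are scaled to the (L - 1)-step integer range (255 for 8-bit) before
#' differencing, so an MSE of 1 means an average error of one gray level.
#'
#' @param original,enhanced [GrayImage-class] objects or numeric matrices of
#'   the same size, values in [0, 1].
#' @param L number of gray levels (default 256).
#' @return Non-negative scalar.
#' @export
mseImage <- function(original, enhanced, L = 256L) {
  a <- .px(original); b <- .px(enhanced)
  if (!identical(dim(a), dim(b)))
    stop("images must have identical dimensions")
  mean(((a - b) * (L - 1))^2)
}

#' Peak signal-to-noise ratio
#'
#' PSNR = 10 log10((L - 1)^2 / MSE) in decibels; higher means the enhanced
#' image deviates less from the original.  Identical images have zero MSE
#' and return +Inf with a warning rather than an error.
#'
#' @inheritParams mseImage
#' @return PSNR in decibels (possibly +Inf).
#' @examples
#' a <- matrix(0.5, 8, 8); b <- a + 1 / 255   # one gray level apart
#' psnr(a, b)                                  # 20 log10(255) ~ 48.13 dB
#' @export
psnr <- function(original, enhanced, L = 256L) {
  m <- mseImage(original, enhanced, L)
  if (m == 0) {
    warning("identical images: PSNR is infinite")
    return(Inf)
  }
  10 * log10((L - 1)^2 / m)
}

#' Global structural similarity index
#'
#' The single-window SSIM statistic computed from whole-image means,
#' variances and covariance on the (L - 1)-scaled representation:
#'
#'   SSIM = (2 mu_x mu_y + C1)(2 sigma_xy + C2) /
#'          ((mu_x^2 + mu_y^2 + C1)(sigma_x^2 + sigma_y^2 + C2))
#'
#' with C1 = (K1 L)^2 and C2 = (K2 L)^2.  A Gaussian sliding-window variant
#' (the convention of the original SSIM literature) is available with
#' `windowed = TRUE`; the global statistic is the default.
#'
#' @inheritParams mseImage
#' @param K1,K2 stabilizing constants (defaults 0.01 and 0.03).
#' @param windowed if TRUE, average the SSIM map computed with local
#'   Gaussian statistics (sigma `windowSigma`) instead of one global window.
#' @param windowSigma Gaussian window scale in pixels (default 1.5).
#' @return SSIM scalar (1 for identical images).
#' @examples
#' a <- matrix(100 / 255, 8, 8); b <- matrix(150 / 255, 8, 8)
#' ssimGlobal(a, b)   # ~ 0.9231 (variance terms cancel)
#' @export
ssimGlobal <- function(original, enhanced, L = 256L, K1 = 0.01, K2 = 0.03,
                       windowed = FALSE, windowSigma = 1.5) {
  x <- .px(original) * (L - 1); y <- .px(enhanced) * (L - 1)
  if (!identical(dim(x), dim(y)))
    stop("images must have identical dimensions")
  C1 <- (K1 * L)^2; C2 <- (K2 * L)^2
  if (!windowed) {
    mx <- mean(x); my <- mean(y)
    vx <- mean((x - mx)^2); vy <- mean((y - my)^2)
    cxy <- mean((x - mx) * (y - my))
    return(((2 * mx * my + C1) * (2 * cxy + C2)) /
             ((mx^2 + my^2 + C1) * (vx + vy + C2)))
  }
  mx <- .gaussBlur(x, windowSigma); my <- .gaussBlur(y, windowSigma)
  vx <- .gaussBlur(x * x, windowSigma) - mx^2
  vy <- .gaussBlur(y * y, windowSigma) - my^2
  cxy <- .gaussBlur(x * y, windowSigma) - mx * my
  mean(((2 * mx * my + C1) * (2 * cxy + C2)) /
         ((mx^2 + my^2 + C1) * (vx + vy + C2)))
}

#' Full-reference quality report
#'
#' PSNR and global SSIM of an enhanced image against its original, plus an
#' optional no-reference NIQE score: NIQE requires a pretrained
#' natural-scene-statistics model and is therefore not computed internally;
#' supply an external evaluator through `niqeFun` and its value is recorded
#' verbatim.
#'
#' @inheritParams mseImage
#' @param niqeFun optional function taking the enhanced [GrayImage-class]
#'   and returning a numeric score (lower is better).
#' @return A [QualityReport-class].
#' @export
qualityReport <- function(original, enhanced, L = 256L, niqeFun = NULL) {
  p <- suppressWarnings(psnr(original, enhanced, L))
  s <- ssimGlobal(original, enhanced, L)
  q <- if (is.null(niqeFun)) NA_real_ else as.numeric(niqeFun(enhanced))
  new("QualityReport", psnr = p, ssim = s, niqe = q)
}
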