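## Internal spatial-filtering helpers.  All convolutions are small-kernel
## correlations implemented as shifted-matrix sums; every kernel used in the
## package is symmetric, so correlation and convolution coincide.

.px <- function(img) {
  if (is(img, "GrayImage")) return(img@pixels)
  if (is.matrix(img) && is.numeric(img)) return(img)
  stop("expected a GrayImage or a numeric matrix")
}

.clamp01 <- function(x) pmin(pmax(x, 0), 1)

## Symmetric (mirror-including-edge) padding; pad widths must not exceed the
## image extent in the padded direction.
.padReflect <- function(px, top, bottom, left, right) {
  H <- nrow(px); W <- ncol(px)
  if (top > H || bottom > H || left > W || right > W)
    stop("reflect padding wider than the image; enlarge the image or shrink the kernel")
  ri <- c(if (top > 0) seq(top, 1L) else integer(0), seq_len(H),
          if (bottom > 0) seq(H, H - bottom + 1L) else integer(0))
  ci <- c(if (left > 0) seq(left, 1L) else integer(0), seq_len(W),
          if (right > 0) seq(W, W - right + 1L) else integer(0))
  px[ri, ci, drop = FALSE]
}

## Same-size correlation with reflect boundary.
.filterSame <- function(px, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  hh <- (kh - 1L) %/% 2L; hw <- (kw - 1L) %/% 2L
  H <- nrow(px); W <- ncol(px)
  P <- .padReflect(px, hh, hh, hw, hw)
  out <- matrix(0, H, W)
  for (a in seq_len(kh)) for (b in seq_len(kw)) {
    k <- kernel[a, b]
    if (k != 0)
      out <- out + k * P[a:(a + H - 1L), b:(b + W - 1L), drop = FALSE]
  }
  out
}

## Valid (interior-only) correlation, no padding.
.filterValid <- function(px, kernel) {
  kh <- nrow(kernel); kw <- ncol(kernel)
  H <- nrow(px); W <- ncol(px)
  if (H < kh || W < kw) stop("image smaller than the kernel")
  oh <- H - kh + 1L; ow <- W - kw + 1L
  out <- matrix(0, oh, ow)
  for (a in seq_len(kh)) for (b in seq_len(kw)) {
    k <- kernel[a, b]
    if (k != 0)
      out <- out + k * px[a:(a + oh - 1L), b:(b + ow - 1L), drop = FALSE]
  }
  out
}

.gaussKernel1d <- function(sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  k / sum(k)
}

## Separable Gaussian blur with reflect boundary; identity for sigma = 0.
.gaussBlur <- function(px, sigma) {
  if (sigma <= 0) return(px)
  k <- .gaussKernel1d(sigma)
  px <- .filterSame(px, matrix(k, ncol = 1))       # along rows (y)
  .filterSame(px, matrix(k, nrow = 1))             # along columns (x)
}

## Zero-sum Laplacian-of-Gaussian kernel, half-width ceil(3 sigma).
.logKernel <- function(sigma) {
  if (sigma <= 0) stop("LoG sigma must be > 0")
  r <- as.integer(ceiling(3 * sigma))
  g <- seq(-r, r)
  xx <- matrix(g, 2 * r + 1L, 2 * r + 1L, byrow = TRUE)
  yy <- matrix(g, 2 * r + 1L, 2 * r + 1L)
  s2 <- sigma^2
  k <- ((xx^2 + yy^2 - 2 * s2) / s2^2) * exp(-(xx^2 + yy^2) / (2 * s2))
  k - mean(k)   # exact zero response on constants
}
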