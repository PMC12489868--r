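#' Read an image file as a GrayImage
#'
#' Reads PNG, TIFF or JPEG files (8- or 16-bit integer, scaled to [0, 1] by
#' the imaging backend).  Color images are reduced to luminance by keeping
#' the HSV value channel ([rgbToValue()]).
#'
#' @param path file path.
#' @param sourceDepth bit depth to record on the result; if `NULL` (default)
#'   it is inferred from the decoded data where possible, else 8.
#' @return A [GrayImage-class].
#' @export
readGrayImage <- function(path, sourceDepth = NULL) {
  if (!file.exists(path)) stop("cannot read '", path, "': no such file")
  im <- EBImage::readImage(path)
  d <- EBImage::imageData(im)
  depth <- if (is.null(sourceDepth)) 8L else as.integer(sourceDepth)
  if (length(dim(d)) == 3L) {
    if (dim(d)[3] >= 3L)
      return(rgbToValue(aperm(d[, , 1:3], c(2L, 1L, 3L)), depth))
    d <- d[, , 1L]
  }
  grayImage(.clamp01(t(d)), depth)
}

#' Write a GrayImage to disk
#'
#' Writes PNG or TIFF (by file extension) on the [0, 1] scale; the backend
#' quantizes to the container's bit depth.
#'
#' @param img a [GrayImage-class].
#' @param path output path ending in .png or .tif/.tiff.
#' @return Invisibly, `path`.
#' @export
writeGrayImage <- function(img, path) {
  px <- .px(img)
  EBImage::writeImage(EBImage::Image(t(px)), path)
  invisible(path)
}

#' Read a directory of frames as a FrameSequence
#'
#' Frame files are ordered lexicographically, the convention used by common
#' video-to-frame extractors.
#'
#' @param dir directory containing the frame images.
#' @param pattern filename regular expression (default PNG/TIFF/JPEG).
#' @param frameRate frames per second to record (default 50).
#' @return A [FrameSequence-class].
#' @export
readFrameSequence <- function(dir, pattern = "\\.(png|tif|tiff|jpg|jpeg)$",
                              frameRate = 50) {
  if (!dir.exists(dir)) stop("cannot read '", dir, "': no such directory")
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE,
                           ignore.case = TRUE))
  if (length(files) == 0L) stop("no frame images found in '", dir, "'")
  frameSequence(lapply(files, readGrayImage), frameRate = frameRate)
}
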