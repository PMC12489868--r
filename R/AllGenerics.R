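#' Accessors for mocsClahe classes
#'
#' Slot accessors for the package's S4 containers.  `pixels()` returns the
#' luminance matrix of a [GrayImage-class]; `frames()` the frame list of a
#' [FrameSequence-class]; `tilesX()`, `tilesY()`, `clipLimit()` and `alpha()`
#' the components of a [ClaheParams-class]; `contrast()` and `noise()` the
#' two objectives of a [FitnessPair-class]; `members()` a data.frame view of
#' a [ParetoFront-class] (decision variables, objectives and crowding).
#'
#' @param x an object of the documented class.
#' @return The slot value (see Description).
#' @name accessors
#' @aliases pixels sourceDepth frames frameRate tilesX tilesY clipLimit
#'   alpha contrast noise members crowding niqe
#' @examples
#' p <- claheParams(8, 8, 0.01, 0.6)
#' tilesX(p); clipLimit(p)
NULL

#' @rdname accessors
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))
#' @rdname accessors
#' @export
setGeneric("sourceDepth", function(x) standardGeneric("sourceDepth"))
#' @rdname accessors
#' @export
setGeneric("frames", function(x) standardGeneric("frames"))
#' @rdname accessors
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname accessors
#' @export
setGeneric("tilesX", function(x) standardGeneric("tilesX"))
#' @rdname accessors
#' @export
setGeneric("tilesY", function(x) standardGeneric("tilesY"))
#' @rdname accessors
#' @export
setGeneric("clipLimit", function(x) standardGeneric("clipLimit"))
#' @rdname accessors
#' @export
setGeneric("alpha", function(x) standardGeneric("alpha"))
#' @rdname accessors
#' @export
setGeneric("contrast", function(x) standardGeneric("contrast"))
#' @rdname accessors
#' @export
setGeneric("noise", function(x) standardGeneric("noise"))
#' @rdname accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname accessors
#' @export
setGeneric("crowding", function(x) standardGeneric("crowding"))
#' @rdname accessors
#' @export
setGeneric("niqe", function(x) standardGeneric("niqe"))

#' @rdname accessors
setMethod("pixels", "GrayImage", function(x) x@pixels)
#' @rdname accessors
setMethod("sourceDepth", "GrayImage", function(x) x@sourceDepth)
#' @rdname accessors
setMethod("frames", "FrameSequence", function(x) x@frames)
#' @rdname accessors
setMethod("frameRate", "FrameSequence", function(x) x@frameRate)
#' @rdname accessors
setMethod("tilesX", "ClaheParams", function(x) x@tilesX)
#' @rdname accessors
setMethod("tilesY", "ClaheParams", function(x) x@tilesY)
#' @rdname accessors
setMethod("clipLimit", "ClaheParams", function(x) x@clipLimit)
#' @rdname accessors
setMethod("alpha", "ClaheParams", function(x) x@alpha)
#' @rdname accessors
setMethod("contrast", "FitnessPair", function(x) x@contrast)
#' @rdname accessors
setMethod("noise", "FitnessPair", function(x) x@noise)
#' @rdname accessors
setMethod("crowding", "ParetoFront", function(x) x@crowding)
#' @rdname accessors
setMethod("niqe", "QualityReport", function(x) x@niqe)

#' @rdname accessors
setMethod("members", "ParetoFront", function(x) {
  d <- ncol(x@vectors)
  out <- as.data.frame(x@vectors)
  names(out) <- if (d == 4L) c("tilesX", "tilesY", "clipLimit", "alpha") else
    paste0("v", seq_len(d))
  out$contrast <- x@fitness[, 1L]
  out$noise <- x@fitness[, 2L]
  out$crowding <- x@crowding
  out
})

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
setMethod("nFrames", "FrameSequence", function(x) length(x@frames))
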