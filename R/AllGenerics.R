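## Accessor generics and show methods.

#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @export
setGeneric("frameStarts", function(x) standardGeneric("frameStarts"))
#' @export
setGeneric("frameEnds", function(x) standardGeneric("frameEnds"))
#' @export
setGeneric("frameDurations", function(x) standardGeneric("frameDurations"))
#' @export
setGeneric("frameMidpoints", function(x) standardGeneric("frameMidpoints"))
#' @export
setGeneric("decayConstant", function(x) standardGeneric("decayConstant"))
#' @export
setGeneric("counts", function(x) standardGeneric("counts"))
#' @export
setGeneric("background", function(x) standardGeneric("background"))
#' @export
setGeneric("geometry", function(x) standardGeneric("geometry"))
#' @export
setGeneric("schedule", function(x) standardGeneric("schedule"))
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))
#' @export
setGeneric("basisValues", function(x) standardGeneric("basisValues"))
#' @export
setGeneric("regionLabels", function(x) standardGeneric("regionLabels"))

#' Accessors for dpet4d containers
#'
#' `nFrames`, `frameStarts`, `frameEnds`, `frameDurations`,
#' `frameMidpoints` and `decayConstant` interrogate a [FrameSchedule-class]
#' (or any object carrying one); `counts` and `background` return the count
#' and background matrices of a [SinogramSeries-class]; `activity` the
#' N_V x N_T activity matrix of an [ImageSeries-class]; `basisValues` the
#' frame-integrated basis matrix of a [BasisMatrix-class]; `regionLabels`
#' the label image of a [Phantom-class].
#'
#' @param x the object.
#' @return see the individual descriptions.
#' @name accessors
#' @aliases nFrames frameStarts frameEnds frameDurations frameMidpoints
#'   decayConstant counts background geometry schedule activity basisValues
#'   regionLabels
NULL

#' @rdname accessors
setMethod("nFrames", "FrameSchedule", function(x) length(x@start))
#' @rdname accessors
setMethod("frameStarts", "FrameSchedule", function(x) x@start)
#' @rdname accessors
setMethod("frameEnds", "FrameSchedule", function(x) x@end)
#' @rdname accessors
setMethod("frameDurations", "FrameSchedule", function(x) x@end - x@start)
#' @rdname accessors
setMethod("frameMidpoints", "FrameSchedule", function(x) (x@start + x@end) / 2)
#' @rdname accessors
setMethod("decayConstant", "FrameSchedule", function(x) x@lambda)

#' @rdname accessors
setMethod("counts", "SinogramSeries", function(x) x@y)
#' @rdname accessors
setMethod("background", "SinogramSeries", function(x) x@eps)
#' @rdname accessors
setMethod("geometry", "SinogramSeries", function(x) x@geometry)
#' @rdname accessors
setMethod("schedule", "SinogramSeries", function(x) x@schedule)
#' @rdname accessors
setMethod("schedule", "FrameSchedule", function(x) x)
#' @rdname accessors
setMethod("schedule", "ImageSeries", function(x) x@schedule)
#' @rdname accessors
setMethod("schedule", "BasisMatrix", function(x) x@schedule)
#' @rdname accessors
setMethod("nFrames", "SinogramSeries", function(x) length(x@schedule@start))
#' @rdname accessors
setMethod("nFrames", "ImageSeries", function(x) length(x@schedule@start))

#' @rdname accessors
setMethod("activity", "ImageSeries", function(x) x@values)
#' @rdname accessors
setMethod("basisValues", "BasisMatrix", function(x) x@B)
#' @rdname accessors
setMethod("regionLabels", "Phantom", function(x) x@labels)

setMethod("show", "FrameSchedule", function(object) {
  cat(sprintf("FrameSchedule: %d frames, %.0f-%.0f s, lambda=%.3e 1/s, injection at %.0f s\n",
              length(object@start), min(object@start), max(object@end),
              object@lambda, object@tInj))
})

setMethod("show", "AIFModel", function(object) {
  if (object@form == "feng3exp")
    cat(sprintf("AIFModel (feng3exp): tau=%.1f s, A=(%.3g, %.3g, %.3g)\n",
                object@params["tau"], object@params["A1"],
                object@params["A2"], object@params["A3"]))
  else
    cat(sprintf("AIFModel (sampled): %d samples over %.0f-%.0f s\n",
                length(object@times), min(object@times), max(object@times)))
})

setMethod("show", "BasisMatrix", function(object) {
  cat(sprintf("BasisMatrix '%s': %d frames x %d basis functions\n",
              object@kind, nrow(object@B), ncol(object@B)))
})

setMethod("show", "KineticParams", function(object) {
  ## report per minute at the boundary, store per second
  cat(sprintf("KineticParams (%s): K1=%.4g k2=%.4g k3=%.4g", object@model,
              object@K1 * 60, object@k2 * 60, object@k3 * 60))
  if (object@model == "3C5K")
    cat(sprintf(" k4=%.4g k5=%.4g", object@k4 * 60, object@k5 * 60))
  cat(sprintf(" (1/min), Vb=%.3f, kflux=%.4g 1/min\n",
              object@Vb, kineticFlux(object) * 60))
})

setMethod("show", "ScannerGeometry", function(object) {
  cat(sprintf("ScannerGeometry: %d angles x %d bins (%.2f mm), image %dx%d (%.2f mm)%s\n",
              object@nAngles, object@nBins, object@binWidth, object@n,
              object@n, object@voxelSize,
              if (is.null(object@attenuation)) "" else ", attenuated"))
})

setMethod("show", "Phantom", function(object) {
  cat(sprintf("Phantom (%s): %dx%d voxels (%.2f mm), regions: %s\n",
              object@kind, nrow(object@labels), ncol(object@labels),
              object@voxelSize, paste(names(object@regions), collapse = ", ")))
})

setMethod("show", "SinogramSeries", function(object) {
  cat(sprintf("SinogramSeries: %d bins x %d frames, %.3g total counts%s\n",
              nrow(object@y), ncol(object@y), sum(object@y),
              if (is.na(object@seed)) " (expected)"
              else sprintf(" (seed %d)", object@seed)))
})

setMethod("show", "ImageSeries", function(object) {
  cat(sprintf("ImageSeries: %dx%d voxels x %d frames, max %.3g Bq/cc\n",
              object@n, object@n, ncol(object@values), max(object@values)))
})

setMethod("show", "ReconResult", function(object) {
  cat(sprintf("ReconResult (%s%s): %d iterations, final objective %.6g\n",
              object@algorithm,
              if (!is.null(object@config$model))
                paste0(", ", object@config$model) else "",
              length(object@objective), tail(object@objective, 1)))
})
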