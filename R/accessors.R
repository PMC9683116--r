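#' @name accessors
#' @title Accessors for ringmetrics objects
#' @description Slot accessors for the core containers; user code should use
#'   these rather than \code{@}.
#' @param x a ringmetrics object.
#' @param object a ringmetrics object (show methods).
#' @return The requested slot value.
NULL

#' @rdname accessors
#' @export
setGeneric("movieData", function(x) standardGeneric("movieData"))
#' @rdname accessors
#' @export
setMethod("movieData", "Movie", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("movieData", "PlaneSeries", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("pixelSize", function(x) standardGeneric("pixelSize"))
#' @rdname accessors
#' @export
setMethod("pixelSize", "Movie", function(x) x@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSize", "PlaneSeries", function(x) x@pixelSizeUm)
#' @rdname accessors
#' @export
setMethod("pixelSize", "LinescanProfile", function(x) x@pixelSizeUm)

#' @rdname accessors
#' @export
setGeneric("frameInterval", function(x) standardGeneric("frameInterval"))
#' @rdname accessors
#' @export
setMethod("frameInterval", "Movie", function(x) x@frameIntervalMin)
#' @rdname accessors
#' @export
setMethod("frameInterval", "PlaneSeries", function(x) x@frameIntervalMin)

#' @rdname accessors
#' @export
setGeneric("nFrames", function(x) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setMethod("nFrames", "Movie", function(x) dim(x@data)[1L])
#' @rdname accessors
#' @export
setMethod("nFrames", "PlaneSeries", function(x) dim(x@data)[1L])

#' @rdname accessors
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))
#' @rdname accessors
#' @export
setMethod("nSlices", "Movie", function(x) dim(x@data)[2L])

#' @rdname accessors
#' @export
setGeneric("intensity", function(x) standardGeneric("intensity"))
#' @rdname accessors
#' @export
setMethod("intensity", "LinescanProfile", function(x) x@intensity)

#' @rdname accessors
#' @export
setGeneric("arcPosition", function(x) standardGeneric("arcPosition"))
#' @rdname accessors
#' @export
setMethod("arcPosition", "LinescanProfile", function(x) x@arcPositionPx)

#' @rdname accessors
#' @export
setGeneric("furrowOffset", function(x) standardGeneric("furrowOffset"))
#' @rdname accessors
#' @export
setMethod("furrowOffset", "LinescanProfile", function(x) x@furrowOffsetPx)

#' @rdname accessors
#' @export
setGeneric("baseline", function(x) standardGeneric("baseline"))
#' @rdname accessors
#' @export
setMethod("baseline", "LinescanProfile", function(x) x@baseline)

#' @rdname accessors
#' @export
setGeneric("peakHeight", function(x) standardGeneric("peakHeight"))
#' @rdname accessors
#' @export
setMethod("peakHeight", "LinescanProfile", function(x) x@peakHeight)

#' @rdname accessors
#' @export
setGeneric("peakIndex", function(x) standardGeneric("peakIndex"))
#' @rdname accessors
#' @export
setMethod("peakIndex", "LinescanProfile", function(x) x@peakIndex)

#' @rdname accessors
#' @export
setGeneric("breadthPx", function(x) standardGeneric("breadthPx"))
#' @rdname accessors
#' @export
setMethod("breadthPx", "BreadthResult", function(x) x@breadthPx)

#' @rdname accessors
#' @export
setGeneric("breadthUm", function(x) standardGeneric("breadthUm"))
#' @rdname accessors
#' @export
setMethod("breadthUm", "BreadthResult", function(x) x@breadthUm)

#' @rdname accessors
#' @export
setGeneric("peakRegion", function(x) standardGeneric("peakRegion"))
#' @rdname accessors
#' @export
setMethod("peakRegion", "BreadthResult", function(x) x@peakRegion)

#' @rdname accessors
#' @export
setGeneric("excludedPixelCount", function(x) standardGeneric("excludedPixelCount"))
#' @rdname accessors
#' @export
setMethod("excludedPixelCount", "BreadthResult", function(x) x@excludedPixelCount)

#' @rdname accessors
#' @export
setGeneric("enrichmentRatio", function(x) standardGeneric("enrichmentRatio"))
#' @rdname accessors
#' @export
setMethod("enrichmentRatio", "EnrichmentResult", function(x) x@enrichmentRatio)

#' @rdname accessors
#' @export
setGeneric("cortexCytosol", function(x) standardGeneric("cortexCytosol"))
#' @rdname accessors
#' @export
setMethod("cortexCytosol", "EnrichmentResult", function(x) x@cortexCytosolRatio)

#' @rdname accessors
#' @export
setGeneric("circleFits", function(x) standardGeneric("circleFits"))
#' @rdname accessors
#' @export
setMethod("circleFits", "RingTrajectory", function(x) x@fits)

#' @rdname accessors
#' @export
setGeneric("normalizedCenters", function(x) standardGeneric("normalizedCenters"))
#' @rdname accessors
#' @export
setMethod("normalizedCenters", "RingTrajectory", function(x) x@normalizedCenters)

#' @rdname accessors
#' @export
setGeneric("normalizedRadii", function(x) standardGeneric("normalizedRadii"))
#' @rdname accessors
#' @export
setMethod("normalizedRadii", "RingTrajectory", function(x) x@normalizedRadii)

#' @rdname accessors
#' @export
setGeneric("groundTruthParams", function(x) standardGeneric("groundTruthParams"))
#' @rdname accessors
#' @export
setMethod("groundTruthParams", "GroundTruth", function(x) x@params)

#' @rdname accessors
#' @export
setMethod("show", "Movie", function(object) {
  d <- dim(object@data)
  cat(sprintf("Movie [%s]: T=%d Z=%d Y=%d X=%d, %.3g um/px, dz=%.3g um, dt=%.3g min\n",
              object@channelName, d[1], d[2], d[3], d[4],
              object@pixelSizeUm, object@zStepUm, object@frameIntervalMin))
})

#' @rdname accessors
#' @export
setMethod("show", "PlaneSeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("PlaneSeries: T=%d Y=%d X=%d (%s)\n", d[1], d[2], d[3],
              paste(names(object@provenance), unlist(lapply(object@provenance, paste, collapse = ",")),
                    sep = "=", collapse = "; ")))
})

#' @rdname accessors
#' @export
setMethod("show", "LinescanProfile", function(object) {
  cat(sprintf("LinescanProfile: %d samples, %.3g um/px", length(object@intensity),
              object@pixelSizeUm))
  if (!is.na(object@baseline))
    cat(sprintf(", baseline=%.4g, peakHeight=%.4g at sample %d",
                object@baseline, object@peakHeight, object@peakIndex))
  if (!all(is.na(object@furrowOffsetPx))) cat(", furrow-registered")
  cat("\n")
})

#' @rdname accessors
#' @export
setMethod("show", "BreadthResult", function(object) {
  cat(sprintf("BreadthResult: %d px = %.3g um at %.0f%% cutoff (%d excluded)\n",
              object@breadthPx, object@breadthUm,
              100 * object@cutoffFraction, object@excludedPixelCount))
})

#' @rdname accessors
#' @export
setMethod("show", "EnrichmentResult", function(object) {
  if (!is.na(object@enrichmentRatio))
    cat(sprintf("EnrichmentResult: furrow/pole = %.4g (furrow %.4g, pole %.4g)\n",
                object@enrichmentRatio, object@furrowMean, object@poleMean))
  if (!is.na(object@cortexCytosolRatio))
    cat(sprintf("EnrichmentResult: cortex/cytosol = %.4g (cortex %.4g, cytosol %.4g)\n",
                object@cortexCytosolRatio, object@cortexMean, object@cytosolMean))
})

#' @rdname accessors
#' @export
setMethod("show", "RingTrajectory", function(object) {
  n <- nrow(object@fits)
  v <- sqrt(sum(object@normalizedCenters[n, ]^2))
  cat(sprintf("RingTrajectory: %d timepoints, final normalized centre offset %.3g\n",
              n, v))
})

#' @rdname accessors
#' @export
setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: breadth %.3g um (%.0f%% cutoff), fold %.3g, symmetry %.3g, ingression %s min\n",
    object@trueBreadthUm, 100 * object@breadthCutoffFraction,
    object@trueEnrichmentFold, object@trueSymmetryValue,
    format(object@trueIngressionDurationMin)))
})

#' @rdname accessors
#' @export
setMethod("show", "SimParams", function(object) {
  cat(sprintf(
    "SimParams: %dx%d px, Z=%d, T=%d, R=%.3g um, fold=%.3g, sigma=%.3g um, asym=%.2f, noise=%s, seed=%d\n",
    object@imageShape[1], object@imageShape[2], object@nSlices, object@nFrames,
    object@cellRadiusUm, object@equatorialEnrichmentFold,
    object@enrichmentSigmaUm, object@closureAsymmetry, object@noiseModel,
    object@seed))
})
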