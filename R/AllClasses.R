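#' @import methods
NULL

#' Simulation parameters for a synthetic dividing-cell movie
#'
#' Holds every generative parameter of the synthetic movie: imaging geometry
#' (image size, number of Z slices and frames, pixel size, Z step, frame
#' interval), cell geometry (radius, cortex shell thickness), fluorescence
#' levels (cytosol, cortex, background), the equatorial enrichment band
#' (fold-enrichment over the polar cortex and Gaussian breadth in arc length),
#' ingression kinetics (start frame, rate, closure asymmetry), photobleaching,
#' and the noise model.
#'
#' @slot imageShape integer(2), image size in pixels as (Y, X).
#' @slot nSlices integer(1), number of Z slices.
#' @slot nFrames integer(1), number of timepoints.
#' @slot pixelSizeUm numeric(1), lateral pixel size in micrometres.
#' @slot zStepUm numeric(1), Z slice spacing in micrometres.
#' @slot frameIntervalMin numeric(1), frame interval in minutes.
#' @slot cellRadiusUm numeric(1), cell radius in micrometres.
#' @slot cortexThicknessUm numeric(1), apparent cortical shell thickness in
#'   micrometres (the optically blurred shell, not the molecular cortex).
#' @slot cytosolLevel numeric(1), cytosolic intensity (a.u.).
#' @slot cortexLevel numeric(1), polar cortical intensity (a.u.).
#' @slot equatorialEnrichmentFold numeric(1), peak cortical intensity at the
#'   equator as a multiple of \code{cortexLevel}; must be >= 1.
#' @slot enrichmentSigmaUm numeric(1), Gaussian sigma of the equatorial band
#'   measured in arc length along the cortex, micrometres.
#' @slot enrichmentOnsetFrame integer(1), first frame (0-based) at which the
#'   equatorial band is present.
#' @slot ingressionStartFrame integer(1), first frame (0-based) of furrow
#'   ingression; also the time-zero used for the simulated ingression
#'   duration.
#' @slot ingressionRateUmPerMin numeric(1), rate of furrow radius decrease.
#' @slot closureAsymmetry numeric(1) in [0, 1]; 0 = concentric closure,
#'   1 = fully one-sided closure.
#' @slot bleachRatePerFrame numeric(1), fractional intensity loss per frame.
#' @slot backgroundLevel numeric(1), constant additive background (a.u.).
#' @slot noiseModel character(1), one of "none", "gaussian", "poisson".
#' @slot noiseSigma numeric(1), standard deviation for gaussian noise (a.u.).
#' @slot seed integer(1), RNG seed.
#'
#' @seealso [SimParams()] for the user-facing constructor with defaults,
#'   [simulateDivisionMovie()].
#' @export
setClass("SimParams", slots = c(
  imageShape = "integer",
  nSlices = "integer",
  nFrames = "integer",
  pixelSizeUm = "numeric",
  zStepUm = "numeric",
  frameIntervalMin = "numeric",
  cellRadiusUm = "numeric",
  cortexThicknessUm = "numeric",
  cytosolLevel = "numeric",
  cortexLevel = "numeric",
  equatorialEnrichmentFold = "numeric",
  enrichmentSigmaUm = "numeric",
  enrichmentOnsetFrame = "integer",
  ingressionStartFrame = "integer",
  ingressionRateUmPerMin = "numeric",
  closureAsymmetry = "numeric",
  bleachRatePerFrame = "numeric",
  backgroundLevel = "numeric",
  noiseModel = "character",
  noiseSigma = "numeric",
  seed = "integer"
))

setValidity("SimParams", function(object) {
  msg <- character()
  pos <- c(pixelSizeUm = object@pixelSizeUm, zStepUm = object@zStepUm,
           frameIntervalMin = object@frameIntervalMin,
           cellRadiusUm = object@cellRadiusUm,
           cortexThicknessUm = object@cortexThicknessUm,
           cytosolLevel = object@cytosolLevel,
           cortexLevel = object@cortexLevel,
           enrichmentSigmaUm = object@enrichmentSigmaUm,
           ingressionRateUmPerMin = object@ingressionRateUmPerMin)
  bad <- names(pos)[!is.finite(pos) | pos <= 0]
  if (length(bad))
    msg <- c(msg, paste0("must be > 0: ", paste(bad, collapse = ", ")))
  if (length(object@imageShape) != 2L || any(object@imageShape < 8L))
    msg <- c(msg, "imageShape must be two positive pixel counts (Y, X)")
  if (object@nSlices < 1L || object@nFrames < 1L)
    msg <- c(msg, "nSlices and nFrames must be >= 1")
  if (object@equatorialEnrichmentFold < 1)
    msg <- c(msg, "equatorialEnrichmentFold must be >= 1")
  if (object@closureAsymmetry < 0 || object@closureAsymmetry > 1)
    msg <- c(msg, "closureAsymmetry must lie in [0, 1]")
  if (object@bleachRatePerFrame < 0 || object@bleachRatePerFrame >= 1)
    msg <- c(msg, "bleachRatePerFrame must lie in [0, 1)")
  if (object@backgroundLevel < 0)
    msg <- c(msg, "backgroundLevel must be >= 0")
  if (!object@noiseModel %in% c("none", "gaussian", "poisson"))
    msg <- c(msg, "noiseModel must be one of none, gaussian, poisson")
  if (object@noiseModel == "gaussian" && object@noiseSigma < 0)
    msg <- c(msg, "noiseSigma must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Ground truth emitted alongside a synthetic movie
#'
#' Records the generative parameters of [simulateDivisionMovie()] in the
#' units the downstream estimators report, together with the per-frame
#' geometry (ring centre and radius, cortex midline path, furrow line) so
#' every estimator can be checked against a known answer.
#'
#' @slot trueBreadthUm numeric(1), full width of the equatorial band at
#'   \code{breadthCutoffFraction} of the normalized peak, micrometres.
#' @slot breadthCutoffFraction numeric(1), cutoff fraction the breadth truth
#'   refers to (see [gaussianBandWidthUm()] for other cutoffs).
#' @slot trueEnrichmentFold numeric(1), peak equatorial / polar cortex ratio.
#' @slot trueCortexCytosolRatio numeric(1), cortexLevel / cytosolLevel.
#' @slot trueIngressionDurationMin numeric(1), minutes from ingression start
#'   to the first frame whose furrow width is <= 1 pixel; NA if the movie
#'   ends before closure.
#' @slot trueSymmetryValue numeric(1), final ring-centre displacement divided
#'   by the initial ring radius.
#' @slot perFrameRingCenter numeric matrix (nFrames x 2), ring centre (x, y)
#'   in image pixels per frame.
#' @slot perFrameRingRadius numeric(nFrames), ring radius in pixels.
#' @slot furrowWidthTracePx numeric(nFrames), furrow diameter in pixels.
#' @slot cortexPath list of per-frame (x, y) vertex matrices tracing the
#'   cortex midline from pole to pole.
#' @slot furrowLine list of per-frame 2 x 2 matrices, furrow line endpoints.
#' @slot params the generating [SimParams-class].
#' @export
setClass("GroundTruth", slots = c(
  trueBreadthUm = "numeric",
  breadthCutoffFraction = "numeric",
  trueEnrichmentFold = "numeric",
  trueCortexCytosolRatio = "numeric",
  trueIngressionDurationMin = "numeric",
  trueSymmetryValue = "numeric",
  perFrameRingCenter = "matrix",
  perFrameRingRadius = "numeric",
  furrowWidthTracePx = "numeric",
  cortexPath = "list",
  furrowLine = "list",
  params = "SimParams"
))

setValidity("GroundTruth", function(object) {
  n <- object@params@nFrames
  msg <- character()
  if (nrow(object@perFrameRingCenter) != n || length(object@perFrameRingRadius) != n)
    msg <- c(msg, "per-frame arrays must have length nFrames")
  r <- object@perFrameRingRadius
  t0 <- object@params@ingressionStartFrame
  if (n > 1 && t0 < n - 1) {
    post <- r[(t0 + 1):n]
    if (any(diff(post) > 1e-9))
      msg <- c(msg, "ring radius must be non-increasing after ingression start")
  }
  if (length(msg)) msg else TRUE
})

#' A time-lapse Z-stack fluorescence movie
#'
#' The central raw-data container: a T x Z x Y x X intensity array with its
#' physical calibration. Intensities are arbitrary units and are kept as
#' floating point throughout.
#'
#' @slot data numeric 4-D array, dimensions (T, Z, Y, X).
#' @slot pixelSizeUm numeric(1), lateral pixel size (micrometres/pixel).
#' @slot zStepUm numeric(1), Z spacing (micrometres).
#' @slot frameIntervalMin numeric(1), time between frames (minutes).
#' @slot channelName character(1).
#' @slot axisOrder character(1), fixed to "TZYX".
#' @export
setClass("Movie", slots = c(
  data = "array",
  pixelSizeUm = "numeric",
  zStepUm = "numeric",
  frameIntervalMin = "numeric",
  channelName = "character",
  axisOrder = "character"
))

setValidity("Movie", function(object) {
  msg <- character()
  if (length(dim(object@data)) != 4L)
    msg <- c(msg, "data must be a 4-D (T, Z, Y, X) array")
  if (object@pixelSizeUm <= 0 || object@zStepUm <= 0 || object@frameIntervalMin <= 0)
    msg <- c(msg, "calibration values must be > 0")
  if (!identical(object@axisOrder, "TZYX"))
    msg <- c(msg, "axisOrder must be \"TZYX\" (reorder on read)")
  if (any(!is.finite(object@data)))
    msg <- c(msg, "intensities must be finite")
  if (length(msg)) msg else TRUE
})

#' A Z-projected movie: one plane per timepoint
#'
#' Result of [projectZ()] (or [resliceEndOn()]): a T x Y x X array plus the
#' provenance of the projection and the calibration inherited from the
#' parent [Movie-class].
#'
#' @slot data numeric 3-D array (T, Y, X).
#' @slot provenance list describing which slices / mode produced the planes.
#' @slot pixelSizeUm numeric(1).
#' @slot frameIntervalMin numeric(1).
#' @export
setClass("PlaneSeries", slots = c(
  data = "array",
  provenance = "list",
  pixelSizeUm = "numeric",
  frameIntervalMin = "numeric"
))

setValidity("PlaneSeries", function(object) {
  if (length(dim(object@data)) != 3L)
    return("data must be a 3-D (T, Y, X) array")
  TRUE
})

#' An ordered cortical path for linescan extraction
#'
#' A pole-to-pole polyline along the cell cortex, in pixel coordinates
#' (x = column, y = row, 0-based), with the averaging width of the linescan.
#'
#' @slot vertices numeric matrix (n x 2) of ordered (x, y) pixel coordinates.
#' @slot widthPx integer(1), odd linescan width in pixels (default 5).
#' @slot frameIndex integer(1), 0-based frame this path belongs to.
#' @export
setClass("CortexPath", slots = c(
  vertices = "matrix",
  widthPx = "integer",
  frameIndex = "integer"
))

setValidity("CortexPath", function(object) {
  msg <- character()
  v <- object@vertices
  if (!is.numeric(v) || ncol(v) != 2L || nrow(v) < 2L)
    msg <- c(msg, "vertices must be an n x 2 numeric matrix with n >= 2")
  else if (any(rowSums((v[-1, , drop = FALSE] - v[-nrow(v), , drop = FALSE])^2) == 0))
    msg <- c(msg, "consecutive vertices must be distinct")
  if (object@widthPx < 1L || object@widthPx %% 2L == 0L)
    msg <- c(msg, "widthPx must be odd and >= 1")
  if (length(msg)) msg else TRUE
})

#' A straight line crossing the cleavage furrow
#'
#' @slot endpoints 2 x 2 numeric matrix of (x, y) pixel coordinates.
#' @slot frameIndex integer(1), 0-based.
#' @export
setClass("FurrowLine", slots = c(
  endpoints = "matrix",
  frameIndex = "integer"
))

setValidity("FurrowLine", function(object) {
  e <- object@endpoints
  if (!is.numeric(e) || !all(dim(e) == c(2L, 2L)))
    return("endpoints must be a 2 x 2 numeric (x, y) matrix")
  if (sum((e[1, ] - e[2, ])^2) == 0)
    return("endpoints must be distinct")
  TRUE
})

#' A cortical (or midzone) intensity profile
#'
#' Ordered intensity samples along a traced path at 1-pixel arc-length
#' spacing, optionally registered to the furrow and normalized. Raw samples
#' are never altered: normalization stores baseline, peak height and peak
#' index alongside them.
#'
#' @slot arcPositionPx numeric, arc length of each sample from the first
#'   pole, pixels.
#' @slot intensity numeric, sample intensities (a.u.).
#' @slot furrowOffsetPx numeric, signed arc distance from the furrow
#'   crossing; NA until [registerToFurrow()] is applied.
#' @slot pixelSizeUm numeric(1).
#' @slot poleWindowPx integer(1), pole window length used for the baseline
#'   (default 50).
#' @slot baseline numeric(1), NA until [normalizeProfile()].
#' @slot peakHeight numeric(1), max intensity minus baseline; NA until
#'   normalized.
#' @slot peakIndex integer(1), 1-based sample index of the maximum (first
#'   maximum on ties); NA until normalized.
#' @slot baselineMode character(1), "min" or "both" (see
#'   [normalizeProfile()]).
#' @export
setClass("LinescanProfile", slots = c(
  arcPositionPx = "numeric",
  intensity = "numeric",
  furrowOffsetPx = "numeric",
  pixelSizeUm = "numeric",
  poleWindowPx = "integer",
  baseline = "numeric",
  peakHeight = "numeric",
  peakIndex = "integer",
  baselineMode = "character"
))

setValidity("LinescanProfile", function(object) {
  msg <- character()
  n <- length(object@arcPositionPx)
  if (length(object@intensity) != n)
    msg <- c(msg, "arcPositionPx and intensity must have equal length")
  if (!all(is.na(object@furrowOffsetPx)) && length(object@furrowOffsetPx) != n)
    msg <- c(msg, "furrowOffsetPx must match the sample count")
  if (is.unsorted(object@arcPositionPx, strictly = TRUE))
    msg <- c(msg, "samples must be ordered by increasing arc position")
  if (length(msg)) msg else TRUE
})

#' Quantification configuration
#'
#' All thresholds and conventions of the quantification stages in one
#' object, echoed into every output for provenance.
#'
#' @slot breadthCutoffFraction numeric(1) in (0, 1); 0.5 compares proteins
#'   with low peak intensity, 0.75 compares one protein across cell lines.
#' @slot poleWindowPx integer(1), baseline window length (default 50).
#' @slot linescanWidthPx integer(1), odd (default 5).
#' @slot symmetricCutoff numeric(1), symmetry value below which closure is
#'   symmetric (default 0.2).
#' @slot highAsymCutoff numeric(1), value above which closure is highly
#'   asymmetric (default 0.6). Boundary values fall in the asymmetric class.
#' @slot endOnRoiPx integer(2), end-on reslice ROI (width, height), default
#'   250 x 50.
#' @slot closureWidthPx numeric(1), furrow width at or below which the
#'   membrane counts as fully closed (default 1 pixel).
#' @slot baselineMode character(1), "min" (lower of the two pole-window
#'   means, default) or "both" (mean over both windows).
#' @slot circleRadiusRule character(1), "mean" ((a + b) / 2, default) or
#'   "geometric" (sqrt(ab)) when reducing a fitted ellipse to a circle.
#' @export
setClass("QuantConfig", slots = c(
  breadthCutoffFraction = "numeric",
  poleWindowPx = "integer",
  linescanWidthPx = "integer",
  symmetricCutoff = "numeric",
  highAsymCutoff = "numeric",
  endOnRoiPx = "integer",
  closureWidthPx = "numeric",
  baselineMode = "character",
  circleRadiusRule = "character"
))

setValidity("QuantConfig", function(object) {
  msg <- character()
  f <- object@breadthCutoffFraction
  if (f <= 0 || f >= 1)
    msg <- c(msg, "breadthCutoffFraction must lie in (0, 1)")
  if (object@symmetricCutoff <= 0 || object@symmetricCutoff >= object@highAsymCutoff)
    msg <- c(msg, "need 0 < symmetricCutoff < highAsymCutoff")
  if (object@linescanWidthPx %% 2L == 0L)
    msg <- c(msg, "linescanWidthPx must be odd")
  if (!object@baselineMode %in% c("min", "both"))
    msg <- c(msg, "baselineMode must be \"min\" or \"both\"")
  if (!object@circleRadiusRule %in% c("mean", "geometric"))
    msg <- c(msg, "circleRadiusRule must be \"mean\" or \"geometric\"")
  if (length(msg)) msg else TRUE
})

#' Peak-breadth measurement of a cortical profile
#'
#' @slot breadthPx integer(1), samples in the contiguous above-cutoff run
#'   containing the peak.
#' @slot breadthUm numeric(1), breadthPx converted to micrometres.
#' @slot breadthFraction numeric(1), breadth as a fraction of the cortical
#'   samples; NA until [breadthFraction()] is applied.
#' @slot cutoffFraction numeric(1), the cutoff used.
#' @slot peakRegion integer(2), first and last 1-based sample index of the
#'   peak run.
#' @slot excludedPixelCount integer(1), above-cutoff samples outside the
#'   peak run (excluded from the breadth).
#' @export
setClass("BreadthResult", slots = c(
  breadthPx = "integer",
  breadthUm = "numeric",
  breadthFraction = "numeric",
  cutoffFraction = "numeric",
  peakRegion = "integer",
  excludedPixelCount = "integer"
))

#' Enrichment ratios of a cortical profile
#'
#' Furrow-versus-pole enrichment (anaphase) and cortex-versus-cytosol ratio
#' (metaphase); slots irrelevant to the computation that produced the object
#' are NA.
#'
#' @slot furrowMean numeric(1), mean raw intensity over the peak region.
#' @slot poleMean numeric(1), mean raw intensity over the pole window(s).
#' @slot enrichmentRatio numeric(1), furrowMean / poleMean.
#' @slot cortexMean numeric(1).
#' @slot cytosolMean numeric(1).
#' @slot cortexCytosolRatio numeric(1), cortexMean / cytosolMean.
#' @export
setClass("EnrichmentResult", slots = c(
  furrowMean = "numeric",
  poleMean = "numeric",
  enrichmentRatio = "numeric",
  cortexMean = "numeric",
  cytosolMean = "numeric",
  cortexCytosolRatio = "numeric"
))

#' A circle fitted to one ring outline
#'
#' @slot frameIndex integer(1), 0-based.
#' @slot center numeric(2), (x, y) pixels.
#' @slot radius numeric(1), pixels.
#' @slot residual numeric(1), RMS distance of the outline points from the
#'   fitted circle (NA for parametric input).
#' @export
setClass("CircleFit", slots = c(
  frameIndex = "integer",
  center = "numeric",
  radius = "numeric",
  residual = "numeric"
))

setValidity("CircleFit", function(object) {
  if (object@radius <= 0) return("radius must be > 0")
  if (length(object@center) != 2L) return("center must be (x, y)")
  TRUE
})

#' A normalized ring-closure trajectory
#'
#' Ordered circle fits with the first-frame ring mapped to centre (0, 0) and
#' radius 1; subsequent centres and radii are expressed in units of the
#' first-frame radius.
#'
#' @slot fits data.frame with columns frame, cx, cy, radius, residual.
#' @slot normalizedCenters numeric matrix (n x 2).
#' @slot normalizedRadii numeric(n).
#' @export
setClass("RingTrajectory", slots = c(
  fits = "data.frame",
  normalizedCenters = "matrix",
  normalizedRadii = "numeric"
))

setValidity("RingTrajectory", function(object) {
  msg <- character()
  if (nrow(object@normalizedCenters) != nrow(object@fits) ||
      length(object@normalizedRadii) != nrow(object@fits))
    msg <- c(msg, "normalized arrays must match the number of fits")
  if (nrow(object@fits) > 0) {
    if (max(abs(object@normalizedCenters[1, ])) > 1e-9)
      msg <- c(msg, "first normalized centre must be (0, 0)")
    if (abs(object@normalizedRadii[1] - 1) > 1e-9)
      msg <- c(msg, "first normalized radius must be 1")
  }
  if (length(msg)) msg else TRUE
})
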