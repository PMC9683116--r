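#' Create simulation parameters
#'
#' User-facing constructor for [SimParams-class] with defaults describing a
#' rounded mitotic cell of radius 10 um imaged at 0.2 um/pixel with 1 um Z
#' steps every 2 min, a cortical shell of apparent thickness 1.6 um, an
#' 8-fold equatorial band of sigma 2 um, furrow ingression at 1 um/min, 2%
#' bleaching per frame, a constant background of 50 a.u. and gaussian shot
#' noise of sigma 10 a.u. (about 3% of the cortical level).
#'
#' @param imageShape integer(2), (Y, X) image size in pixels.
#' @param nSlices,nFrames stack depth and movie length.
#' @param pixelSizeUm,zStepUm,frameIntervalMin physical calibration.
#' @param cellRadiusUm,cortexThicknessUm cell geometry (micrometres).
#' @param cytosolLevel,cortexLevel,backgroundLevel intensity levels (a.u.).
#' @param equatorialEnrichmentFold peak equatorial / polar cortex ratio (>= 1).
#' @param enrichmentSigmaUm Gaussian arc-length sigma of the band.
#' @param enrichmentOnsetFrame,ingressionStartFrame 0-based frame indices.
#' @param ingressionRateUmPerMin furrow radius shrink rate.
#' @param closureAsymmetry 0 (concentric) to 1 (one-sided).
#' @param bleachRatePerFrame fractional bleaching per frame.
#' @param noiseModel "none", "gaussian" or "poisson".
#' @param noiseSigma gaussian noise sigma (a.u.), ignored otherwise.
#' @param seed integer RNG seed.
#' @return A validated [SimParams-class] object.
#' @examples
#' p <- SimParams(noiseModel = "none", bleachRatePerFrame = 0)
#' @export
SimParams <- function(imageShape = c(128L, 128L),
                      nSlices = 11L, nFrames = 15L,
                      pixelSizeUm = 0.2, zStepUm = 1,
                      frameIntervalMin = 2,
                      cellRadiusUm = 10, cortexThicknessUm = 1.6,
                      cytosolLevel = 120, cortexLevel = 300,
                      equatorialEnrichmentFold = 8,
                      enrichmentSigmaUm = 2,
                      enrichmentOnsetFrame = 1L,
                      ingressionStartFrame = 3L,
                      ingressionRateUmPerMin = 1,
                      closureAsymmetry = 0,
                      bleachRatePerFrame = 0.02,
                      backgroundLevel = 50,
                      noiseModel = "gaussian",
                      noiseSigma = 10,
                      seed = 1L) {
  new("SimParams",
      imageShape = as.integer(imageShape),
      nSlices = as.integer(nSlices), nFrames = as.integer(nFrames),
      pixelSizeUm = pixelSizeUm, zStepUm = zStepUm,
      frameIntervalMin = frameIntervalMin,
      cellRadiusUm = cellRadiusUm, cortexThicknessUm = cortexThicknessUm,
      cytosolLevel = cytosolLevel, cortexLevel = cortexLevel,
      equatorialEnrichmentFold = equatorialEnrichmentFold,
      enrichmentSigmaUm = enrichmentSigmaUm,
      enrichmentOnsetFrame = as.integer(enrichmentOnsetFrame),
      ingressionStartFrame = as.integer(ingressionStartFrame),
      ingressionRateUmPerMin = ingressionRateUmPerMin,
      closureAsymmetry = closureAsymmetry,
      bleachRatePerFrame = bleachRatePerFrame,
      backgroundLevel = backgroundLevel,
      noiseModel = noiseModel, noiseSigma = noiseSigma,
      seed = as.integer(seed))
}

#' Create a movie container
#'
#' @param data numeric 4-D array (T, Z, Y, X).
#' @param pixelSizeUm,zStepUm,frameIntervalMin physical calibration.
#' @param channelName channel label.
#' @return A [Movie-class] object.
#' @export
Movie <- function(data, pixelSizeUm, zStepUm = 1, frameIntervalMin = 1,
                  channelName = "green") {
  new("Movie", data = data, pixelSizeUm = pixelSizeUm, zStepUm = zStepUm,
      frameIntervalMin = frameIntervalMin, channelName = channelName,
      axisOrder = "TZYX")
}

#' Create a cortical path
#'
#' @param vertices n x 2 matrix (or data.frame) of ordered (x, y) pixel
#'   coordinates, pole to pole.
#' @param widthPx odd linescan width (default 5).
#' @param frameIndex 0-based frame index.
#' @return A [CortexPath-class] object.
#' @export
CortexPath <- function(vertices, widthPx = 5L, frameIndex = 0L) {
  v <- as.matrix(vertices)
  colnames(v) <- c("x", "y")
  new("CortexPath", vertices = v, widthPx = as.integer(widthPx),
      frameIndex = as.integer(frameIndex))
}

#' Create a furrow line
#'
#' @param p1,p2 (x, y) endpoints in pixel coordinates.
#' @param frameIndex 0-based frame index.
#' @return A [FurrowLine-class] object.
#' @export
FurrowLine <- function(p1, p2, frameIndex = 0L) {
  e <- rbind(as.numeric(p1), as.numeric(p2))
  colnames(e) <- c("x", "y")
  new("FurrowLine", endpoints = e, frameIndex = as.integer(frameIndex))
}

#' Create a quantification configuration
#'
#' @param breadthCutoffFraction cutoff as a fraction of the normalized peak
#'   (0.5 or 0.75 in standard use).
#' @param poleWindowPx baseline window length, pixels.
#' @param linescanWidthPx odd linescan width.
#' @param symmetricCutoff,highAsymCutoff symmetry classification thresholds.
#' @param endOnRoiPx end-on reslice ROI (width, height) in pixels.
#' @param closureWidthPx furrow width defining full closure.
#' @param baselineMode "min" or "both" pole-window convention.
#' @param circleRadiusRule "mean" or "geometric" ellipse-to-circle rule.
#' @return A validated [QuantConfig-class] object.
#' @examples
#' cfg <- QuantConfig(breadthCutoffFraction = 0.75)
#' @export
QuantConfig <- function(breadthCutoffFraction = 0.5,
                        poleWindowPx = 50L,
                        linescanWidthPx = 5L,
                        symmetricCutoff = 0.2,
                        highAsymCutoff = 0.6,
                        endOnRoiPx = c(250L, 50L),
                        closureWidthPx = 1,
                        baselineMode = "min",
                        circleRadiusRule = "mean") {
  new("QuantConfig",
      breadthCutoffFraction = breadthCutoffFraction,
      poleWindowPx = as.integer(poleWindowPx),
      linescanWidthPx = as.integer(linescanWidthPx),
      symmetricCutoff = symmetricCutoff,
      highAsymCutoff = highAsymCutoff,
      endOnRoiPx = as.integer(endOnRoiPx),
      closureWidthPx = closureWidthPx,
      baselineMode = baselineMode,
      circleRadiusRule = circleRadiusRule)
}

newProfile <- function(arcPositionPx, intensity, pixelSizeUm,
                       poleWindowPx = 50L,
                       furrowOffsetPx = NA_real_) {
  new("LinescanProfile",
      arcPositionPx = arcPositionPx, intensity = intensity,
      furrowOffsetPx = furrowOffsetPx, pixelSizeUm = pixelSizeUm,
      poleWindowPx = as.integer(poleWindowPx),
      baseline = NA_real_, peakHeight = NA_real_, peakIndex = NA_integer_,
      baselineMode = NA_character_)
}
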