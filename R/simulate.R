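#' Analytic full width of a Gaussian cortical band at a cutoff fraction
#'
#' For an equatorial band whose normalized profile is exp(-s^2 / (2 sigma^2))
#' in cortical arc length s, the full width of the region at or above a
#' fraction \code{cutoff} of the peak is \code{2 sigma sqrt(-2 log(cutoff))}
#' (the familiar FWHM \code{2 sigma sqrt(2 log 2)} when cutoff = 0.5).
#'
#' @param sigmaUm Gaussian sigma in micrometres.
#' @param cutoff fraction of the normalized peak, in (0, 1).
#' @return Band width in micrometres.
#' @examples
#' gaussianBandWidthUm(2, 0.5)   # 2 * 2 * sqrt(2 * log(2)) = 4.71
#' @export
gaussianBandWidthUm <- function(sigmaUm, cutoff = 0.5) {
  stopifnot(cutoff > 0, cutoff < 1, sigmaUm > 0)
  2 * sigmaUm * sqrt(-2 * log(cutoff))
}

ringRadiusUm <- function(p, t) {
  if (t < p@ingressionStartFrame) return(p@cellRadiusUm)
  max(0, p@cellRadiusUm -
        p@ingressionRateUmPerMin * p@frameIntervalMin * (t - p@ingressionStartFrame))
}

#' Simulate a dividing-cell fluorescence movie with ground truth
#'
#' Renders a rounded mitotic cell as a spherical shell (the cortex) around a
#' cytosolic pool, rasterized per Z slice. From the enrichment onset frame a
#' Gaussian band in cortical arc length, peaking at
#' \code{cortexLevel * equatorialEnrichmentFold}, sits at the equator. From
#' the ingression start frame the equatorial boundary constricts at the
#' given rate within a fixed furrow zone (Gaussian of sigma 1.5 um along the
#' division axis), and the ring centre drifts toward one side by
#' \code{closureAsymmetry * (R - ringRadius)}, reaching
#' \code{closureAsymmetry * R} at closure. Frames are multiplied by
#' \code{(1 - bleachRatePerFrame)^t}, offset by the background, then noised
#' (gaussian or poisson on the expected value). The returned
#' [GroundTruth-class] records every generative parameter plus the per-frame
#' ring geometry, cortex midline path and furrow line, so each downstream
#' estimator has a known answer.
#'
#' @param params a [SimParams-class] object.
#' @return A list with elements \code{movie} ([Movie-class]) and
#'   \code{truth} ([GroundTruth-class]).
#' @examples
#' sim <- simulateDivisionMovie(SimParams(imageShape = c(96L, 96L),
#'                                        cellRadiusUm = 7, nFrames = 4L,
#'                                        nSlices = 5L, noiseModel = "none"))
#' sim$truth
#' @export
simulateDivisionMovie <- function(params) {
  validObject(params)
  p <- params
  Y <- p@imageShape[1]; X <- p@imageShape[2]
  ps <- p@pixelSizeUm
  R <- p@cellRadiusUm
  Rpx <- R / ps
  if (2 * (Rpx + 2) > min(Y, X))
    stop(sprintf(paste0("image too small to contain the cell: need at least ",
                        "%d x %d pixels for a radius of %.3g um at %.3g um/px"),
                 ceiling(2 * (Rpx + 2)), ceiling(2 * (Rpx + 2)), R, ps))
  cx <- (X - 1) / 2; cy <- (Y - 1) / 2
  czSlice <- (p@nSlices - 1) / 2
  thick <- p@cortexThicknessUm
  sigma <- p@enrichmentSigmaUm
  fold <- p@equatorialEnrichmentFold
  furrowZoneUm <- 1.5

  # per-voxel coordinates in um, relative to the cell centre; the division
  # axis (furrow normal) is x, the drift direction is +y
  A <- matrix((0:(X - 1) - cx) * ps, nrow = Y, ncol = X, byrow = TRUE)
  DY <- matrix((0:(Y - 1) - cy) * ps, nrow = Y, ncol = X)
  fz <- exp(-A^2 / (2 * furrowZoneUm^2))

  data <- array(0, dim = c(p@nFrames, p@nSlices, Y, X))
  set.seed(p@seed)

  rTrace <- vapply(0:(p@nFrames - 1), function(t) ringRadiusUm(p, t), numeric(1))
  offTrace <- p@closureAsymmetry * (R - rTrace)

  for (t in seq_len(p@nFrames) - 1L) {
    rring <- rTrace[t + 1L]
    B <- R - (R - rring) * fz
    Yp <- DY - offTrace[t + 1L] * fz
    hasBand <- t >= p@enrichmentOnsetFrame
    bleach <- (1 - p@bleachRatePerFrame)^t
    for (z in seq_len(p@nSlices) - 1L) {
      dz <- (z - czSlice) * p@zStepUm
      r3 <- sqrt(A^2 + Yp^2 + dz^2)
      inside <- r3 <= B
      cortexMask <- inside & (r3 > B - thick)
      img <- matrix(0, Y, X)
      img[inside] <- p@cytosolLevel
      if (any(cortexMask)) {
        cI <- p@cortexLevel
        if (hasBand && fold > 1) {
          s <- R * asin(pmin(1, abs(A[cortexMask]) / pmax(r3[cortexMask], 1e-9)))
          cI <- p@cortexLevel * (1 + (fold - 1) * exp(-s^2 / (2 * sigma^2)))
        }
        img[cortexMask] <- cI
      }
      img <- img * bleach + p@backgroundLevel
      if (p@noiseModel == "gaussian" && p@noiseSigma > 0) {
        img <- img + matrix(stats::rnorm(Y * X, 0, p@noiseSigma), Y, X)
      } else if (p@noiseModel == "poisson") {
        img <- matrix(stats::rpois(Y * X, pmax(img, 0)), Y, X)
      }
      data[t + 1L, z + 1L, , ] <- pmax(img, 0)
    }
  }

  movie <- Movie(data, pixelSizeUm = ps, zStepUm = p@zStepUm,
                 frameIntervalMin = p@frameIntervalMin)

  truth <- makeGroundTruth(p, rTrace, offTrace, cx, cy)
  list(movie = movie, truth = truth)
}

# per-frame geometry and analytic recovery targets for a simulated movie
makeGroundTruth <- function(p, rTrace, offTrace, cx, cy) {
  ps <- p@pixelSizeUm
  R <- p@cellRadiusUm
  thick <- p@cortexThicknessUm
  furrowZoneUm <- 1.5
  nF <- p@nFrames

  centers <- cbind(x = rep(cx, nF), y = cy + offTrace / ps)
  radiiPx <- rTrace / ps
  widthPx <- 2 * radiiPx

  # cortex midline path: boundary minus half the shell thickness, sampled
  # at 1 degree; runs pole -> equator (+y side) -> pole
  theta <- seq(-pi / 2, pi / 2, length.out = 181L)
  paths <- vector("list", nF)
  furrows <- vector("list", nF)
  for (t in seq_len(nF)) {
    a0 <- (R - thick / 2) * sin(theta)
    Bv <- R - (R - rTrace[t]) * exp(-a0^2 / (2 * furrowZoneUm^2))
    rp <- pmax(Bv - thick / 2, 0.1)
    a <- rp * sin(theta)
    yy <- rp * cos(theta) + offTrace[t] * exp(-a^2 / (2 * furrowZoneUm^2))
    paths[[t]] <- cbind(x = cx + a / ps, y = cy + yy / ps)
    yEq <- yy[which.min(abs(theta))]
    furrows[[t]] <- rbind(c(cx, cy + (yEq - 3) / ps),
                          c(cx, cy + (yEq + 3) / ps))
  }

  closed <- which(widthPx <= 1)
  durMin <- if (length(closed))
    (closed[1] - 1 - p@ingressionStartFrame) * p@frameIntervalMin else NA_real_

  measurable <- which(radiiPx >= 2)
  tLast <- if (length(measurable)) max(measurable) else 1L
  symTrue <- sqrt(sum((centers[tLast, ] - centers[1, ])^2)) / radiiPx[1]

  new("GroundTruth",
      trueBreadthUm = gaussianBandWidthUm(p@enrichmentSigmaUm, 0.5),
      breadthCutoffFraction = 0.5,
      trueEnrichmentFold = p@equatorialEnrichmentFold,
      trueCortexCytosolRatio = p@cortexLevel / p@cytosolLevel,
      trueIngressionDurationMin = durMin,
      trueSymmetryValue = symTrue,
      perFrameRingCenter = centers,
      perFrameRingRadius = radiiPx,
      furrowWidthTracePx = widthPx,
      cortexPath = paths,
      furrowLine = furrows,
      params = p)
}

#' Simulate a closing-ring trajectory
#'
#' A fixture generator for the symmetry analysis: the ring radius shrinks
#' linearly from \code{initialRadius} to 2% of it over \code{nFrames}
#' timepoints while the centre drifts linearly so that the final centre is
#' offset from the initial centre by \code{asymmetry * initialRadius} (plus
#' optional gaussian jitter on every centre).
#'
#' @param nFrames number of timepoints (>= 2).
#' @param initialRadius starting ring radius, pixels.
#' @param asymmetry target normalized final offset, in [0, 1].
#' @param seed RNG seed (used when jitter > 0).
#' @param jitter gaussian sd added to each centre coordinate, pixels.
#' @param center0 initial centre (x, y), pixels.
#' @return data.frame with columns frame, cx, cy, radius.
#' @examples
#' tr <- simulateRingTrajectory(10, 20, asymmetry = 0.5)
#' tail(tr, 1)  # centre 10 px from the start
#' @export
simulateRingTrajectory <- function(nFrames, initialRadius, asymmetry,
                                   seed = 1L, jitter = 0,
                                   center0 = c(50, 50)) {
  stopifnot(nFrames >= 2, initialRadius > 0)
  if (asymmetry < 0 || asymmetry > 1)
    stop("asymmetry must lie in [0, 1]")
  frac <- (0:(nFrames - 1)) / (nFrames - 1)
  cx <- center0[1] + asymmetry * initialRadius * frac
  cy <- rep(center0[2], nFrames)
  radius <- initialRadius * (1 - 0.98 * frac)
  if (jitter > 0) {
    set.seed(as.integer(seed))
    cx <- cx + stats::rnorm(nFrames, 0, jitter)
    cy <- cy + stats::rnorm(nFrames, 0, jitter)
  }
  data.frame(frame = 0:(nFrames - 1), cx = cx, cy = cy, radius = radius)
}

#' Build a synthetic 1-D linescan profile fixture
#'
#' Returns baseline + a Gaussian bump + optional isolated spikes, as an
#' unnormalized [LinescanProfile-class]. Spikes are given as a list of
#' \code{c(index, value)} pairs (0-based arc index) and set the sample to
#' \code{value} absolutely, which makes them convenient decoys for the
#' off-peak exclusion rule of [peakBreadth()].
#'
#' @param length number of samples (> 100, so 50-pixel pole windows exist).
#' @param baseline baseline intensity (a.u.).
#' @param peakHeight Gaussian amplitude above baseline (a.u.).
#' @param peakCenter 0-based arc index of the bump centre.
#' @param peakSigma Gaussian sigma, pixels.
#' @param extraSpikes list of \code{c(index, value)} pairs, or NULL.
#' @param pixelSizeUm pixel size recorded on the profile.
#' @param poleWindowPx baseline window length.
#' @return A [LinescanProfile-class].
#' @examples
#' pr <- makeProfileFixture(300, baseline = 100, peakHeight = 200,
#'                          peakCenter = 150, peakSigma = 8)
#' max(intensity(pr))  # 300 at the centre
#' @export
makeProfileFixture <- function(length, baseline, peakHeight, peakCenter,
                               peakSigma, extraSpikes = NULL,
                               pixelSizeUm = 1, poleWindowPx = 50L) {
  if (length <= 100)
    stop("profile length must exceed 100 samples")
  if (peakCenter < 0 || peakCenter > length - 1)
    stop("peakCenter out of bounds")
  if (peakCenter < poleWindowPx || peakCenter > length - 1 - poleWindowPx)
    warning("peakCenter lies within a pole window; baseline will overlap the peak")
  arc <- 0:(length - 1)
  int <- baseline + peakHeight * exp(-(arc - peakCenter)^2 / (2 * peakSigma^2))
  for (sp in extraSpikes) {
    i <- as.integer(sp[1])
    if (i < 0 || i >= length) stop("spike index out of bounds")
    int[i + 1L] <- sp[2]
  }
  newProfile(as.numeric(arc), int, pixelSizeUm, poleWindowPx)
}

#' Ring outlines from simulator ground truth
#'
#' Generates per-frame point sets on the true ring perimeter in end-on view
#' coordinates (the ring plane), as a stand-in for the manual ellipse
#' outlines a user would draw. Frames whose ring has shrunk below
#' \code{minRadiusPx} are omitted (too small to outline).
#'
#' @param truth a [GroundTruth-class].
#' @param nPoints points per outline.
#' @param jitterPx gaussian sd added to each point, pixels.
#' @param seed RNG seed (used when jitterPx > 0).
#' @param minRadiusPx smallest outlineable ring radius.
#' @return Named list (frame index as name) of n x 2 (x, y) point matrices.
#' @export
ringOutlinesFromTruth <- function(truth, nPoints = 12L, jitterPx = 0,
                                  seed = 1L, minRadiusPx = 2) {
  p <- truth@params
  zScale <- p@zStepUm / p@pixelSizeUm
  vCenter <- (p@nSlices - 1) / 2 * zScale
  keep <- which(truth@perFrameRingRadius >= minRadiusPx)
  if (jitterPx > 0) set.seed(as.integer(seed))
  out <- lapply(keep, function(t) {
    ang <- seq(0, 2 * pi, length.out = nPoints + 1L)[-(nPoints + 1L)]
    u <- truth@perFrameRingCenter[t, "y"] +
      truth@perFrameRingRadius[t] * cos(ang)
    v <- vCenter + truth@perFrameRingRadius[t] * sin(ang)
    if (jitterPx > 0) {
      u <- u + stats::rnorm(nPoints, 0, jitterPx)
      v <- v + stats::rnorm(nPoints, 0, jitterPx)
    }
    cbind(x = u, y = v)
  })
  names(out) <- as.character(keep - 1L)
  out
}
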