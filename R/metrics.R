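#' Peak breadth of a normalized cortical profile
#'
#' Counts the samples whose intensity reaches the cutoff
#' \code{baseline + cutoffFraction * peakHeight} (samples exactly at the
#' cutoff count as above it) within the maximal contiguous run containing
#' the peak, and converts the count to micrometres. Above-cutoff samples
#' outside that run — isolated bright pixels away from the equatorial band —
#' are excluded from the breadth and reported in
#' \code{excludedPixelCount}. The cutoff is baseline-relative, so the
#' breadth is invariant under affine intensity transforms \code{a I + b}
#' with \code{a > 0}.
#'
#' @param profile a normalized [LinescanProfile-class] with
#'   \code{peakHeight > 0}.
#' @param config a [QuantConfig-class]; \code{breadthCutoffFraction} is 0.5
#'   for comparisons across proteins with low peaks and 0.75 for comparing
#'   one protein across cell lines.
#' @return A [BreadthResult-class].
#' @examples
#' pr <- makeProfileFixture(300, 0, 200, 150, 8)
#' pr <- normalizeProfile(pr)
#' peakBreadth(pr, QuantConfig())  # ~19 px: FWHM of a sigma-8 Gaussian
#' @export
peakBreadth <- function(profile, config = QuantConfig()) {
  if (is.na(profile@peakHeight))
    stop("profile must be normalized first (see normalizeProfile)")
  if (profile@peakHeight <= 0)
    stop("no measurable peak: peak height is not positive")
  cutoff <- profile@baseline + config@breadthCutoffFraction * profile@peakHeight
  above <- profile@intensity >= cutoff
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runIdx <- which(starts <= profile@peakIndex & ends >= profile@peakIndex)
  stopifnot(r$values[runIdx])  # the peak itself is always above its cutoff
  n <- r$lengths[runIdx]
  new("BreadthResult",
      breadthPx = as.integer(n),
      breadthUm = n * profile@pixelSizeUm,
      breadthFraction = NA_real_,
      cutoffFraction = config@breadthCutoffFraction,
      peakRegion = c(starts[runIdx], ends[runIdx]),
      excludedPixelCount = as.integer(sum(above) - n))
}

#' Breadth as a fraction of cortical length
#'
#' Controls for cell-size variation by expressing the breadth as a ratio of
#' the total cortical samples in the linescan.
#'
#' @param result a [BreadthResult-class].
#' @param totalSamples number of samples in the full pole-to-pole profile.
#' @return The fraction \code{breadthPx / totalSamples}.
#' @export
breadthFraction <- function(result, totalSamples) {
  if (totalSamples <= 0) stop("totalSamples must be positive")
  if (totalSamples < result@breadthPx)
    stop("totalSamples is smaller than the breadth")
  result@breadthPx / totalSamples
}

#' Furrow-versus-pole enrichment
#'
#' The ratio of the average raw intensity over the breadth (peak) region to
#' the average over the pole window(s) — the first or last 50 samples of
#' the linescan, combined per the same convention used to normalize the
#' profile. Being a ratio of raw means, it is invariant under
#' multiplicative intensity scaling but not under additive offsets, which
#' is why profiles must be background-subtracted first.
#'
#' @param profile the normalized [LinescanProfile-class] the breadth was
#'   computed on.
#' @param breadth the matching [BreadthResult-class].
#' @return An [EnrichmentResult-class] with the furrow/pole slots set.
#' @export
furrowEnrichment <- function(profile, breadth) {
  n <- length(profile@intensity)
  w <- profile@poleWindowPx
  first <- mean(profile@intensity[seq_len(w)])
  last <- mean(profile@intensity[seq(n - w + 1L, n)])
  mode <- if (is.na(profile@baselineMode)) "min" else profile@baselineMode
  poleMean <- if (mode == "min") min(first, last) else (first + last) / 2
  if (poleMean <= 0)
    stop("pole mean is not positive; was the background over-subtracted?")
  region <- seq(breadth@peakRegion[1], breadth@peakRegion[2])
  furrowMean <- mean(profile@intensity[region])
  new("EnrichmentResult",
      furrowMean = furrowMean, poleMean = poleMean,
      enrichmentRatio = furrowMean / poleMean,
      cortexMean = NA_real_, cytosolMean = NA_real_,
      cortexCytosolRatio = NA_real_)
}

#' Metaphase cortex-versus-cytosol ratio
#'
#' The mean intensity of a linescan drawn around the full metaphase cortex
#' divided by the mean over a cytosolic region of interest.
#'
#' @param cortexProfile a [LinescanProfile-class] traced around the cortex.
#' @param cytosolRegionMean mean cytosolic intensity (a.u., > 0).
#' @return An [EnrichmentResult-class] with the cortex/cytosol slots set.
#' @export
cortexCytosolRatio <- function(cortexProfile, cytosolRegionMean) {
  if (cytosolRegionMean <= 0) stop("cytosol mean must be positive")
  cortexMean <- mean(cortexProfile@intensity)
  new("EnrichmentResult",
      furrowMean = NA_real_, poleMean = NA_real_,
      enrichmentRatio = NA_real_,
      cortexMean = cortexMean, cytosolMean = cytosolRegionMean,
      cortexCytosolRatio = cortexMean / cytosolRegionMean)
}

#' Duration of furrow ingression
#'
#' Measures ring-closure duration from anaphase onset until the membrane is
#' fully closed: the first frame whose furrow width is at or below
#' \code{closureWidthPx} (1 pixel by default) defines closure, and the
#' duration is \code{(closureFrame - anaphaseFrame) * frameIntervalMin}.
#'
#' @param furrowWidthTracePx per-frame furrow width, pixels (from
#'   annotations or simulator ground truth).
#' @param anaphaseFrame 0-based anaphase-onset frame.
#' @param frameIntervalMin frame interval, minutes.
#' @param config a [QuantConfig-class] supplying \code{closureWidthPx}.
#' @return A list with \code{closed} (logical), \code{closureFrame}
#'   (0-based, NA if never closed) and \code{durationMin} (NA if never
#'   closed).
#' @export
ingressionDuration <- function(furrowWidthTracePx, anaphaseFrame,
                               frameIntervalMin, config = QuantConfig()) {
  if (anaphaseFrame < 0 || anaphaseFrame >= length(furrowWidthTracePx))
    stop("anaphaseFrame must index into the width trace")
  if (any(furrowWidthTracePx < 0)) stop("widths must be non-negative")
  hit <- which(furrowWidthTracePx <= config@closureWidthPx)
  if (!length(hit))
    return(list(closed = FALSE, closureFrame = NA_integer_,
                durationMin = NA_real_))
  cf <- hit[1] - 1L
  list(closed = TRUE, closureFrame = cf,
       durationMin = (cf - anaphaseFrame) * frameIntervalMin)
}

#' Descriptive per-group summaries
#'
#' Exact n, mean and sample SD per group, as a tidy data.frame. With a
#' single observation the SD is reported as 0 and flagged.
#'
#' @param perCellTable data.frame with a grouping column and a value column.
#' @param group,value column names (character).
#' @return data.frame with columns group, n, mean, sd, singleObservation.
#' @export
summarizeGroups <- function(perCellTable, group = "cell_line", value = "value") {
  if (!nrow(perCellTable)) stop("empty table")
  g <- factor(perCellTable[[group]])
  v <- perCellTable[[value]]
  out <- do.call(rbind, lapply(levels(g), function(lev) {
    x <- v[g == lev]
    data.frame(group = lev, n = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else 0,
               singleObservation = length(x) == 1L)
  }))
  rownames(out) <- NULL
  out
}
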