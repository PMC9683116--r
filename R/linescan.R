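# bilinear interpolation of img (Y x X matrix) at 0-based continuous
# coordinates; returns NA outside the image
bilinearSample <- function(img, x, y) {
  Y <- nrow(img); X <- ncol(img)
  out <- rep(NA_real_, length(x))
  ok <- x >= 0 & x <= X - 1 & y >= 0 & y <= Y - 1
  if (!any(ok)) return(out)
  xv <- x[ok]; yv <- y[ok]
  x0 <- pmin(floor(xv), X - 2); y0 <- pmin(floor(yv), Y - 2)
  fx <- xv - x0; fy <- yv - y0
  i00 <- cbind(y0 + 1, x0 + 1)
  i01 <- cbind(y0 + 1, x0 + 2)
  i10 <- cbind(y0 + 2, x0 + 1)
  i11 <- cbind(y0 + 2, x0 + 2)
  out[ok] <- img[i00] * (1 - fx) * (1 - fy) + img[i01] * fx * (1 - fy) +
    img[i10] * (1 - fx) * fy + img[i11] * fx * fy
  out
}

# resample a polyline at 1-pixel arc-length spacing; returns positions,
# coordinates and unit tangents
resamplePolyline <- function(vertices) {
  seg <- sqrt(rowSums((vertices[-1, , drop = FALSE] -
                         vertices[-nrow(vertices), , drop = FALSE])^2))
  cum <- c(0, cumsum(seg))
  total <- cum[length(cum)]
  arc <- 0:round(total)
  xs <- stats::approx(cum, vertices[, 1], xout = pmin(arc, total))$y
  ys <- stats::approx(cum, vertices[, 2], xout = pmin(arc, total))$y
  n <- length(arc)
  tx <- c(xs[2] - xs[1], (xs[-(1:2)] - xs[-((n - 1):n)]) / 2, xs[n] - xs[n - 1])
  ty <- c(ys[2] - ys[1], (ys[-(1:2)] - ys[-((n - 1):n)]) / 2, ys[n] - ys[n - 1])
  norm <- sqrt(tx^2 + ty^2)
  list(arc = as.numeric(arc), x = xs, y = ys, tx = tx / norm, ty = ty / norm)
}

extractAlongPath <- function(img, vertices, widthPx, pixelSizeUm,
                             poleWindowPx = 50L) {
  rs <- resamplePolyline(vertices)
  half <- (widthPx - 1) / 2
  offsets <- if (half > 0) seq(-half, half) else 0
  samples <- matrix(NA_real_, nrow = length(rs$arc), ncol = length(offsets))
  # perpendicular to the local tangent: (-ty, tx)
  for (j in seq_along(offsets)) {
    samples[, j] <- bilinearSample(img,
                                   rs$x - offsets[j] * rs$ty,
                                   rs$y + offsets[j] * rs$tx)
  }
  vals <- rowMeans(samples, na.rm = TRUE)
  if (any(!is.finite(vals)))
    stop("all perpendicular sub-samples fell outside the image for some sample")
  newProfile(rs$arc, vals, pixelSizeUm, poleWindowPx)
}

#' Extract a cortical linescan
#'
#' Samples a [PlaneSeries-class] frame along a pole-to-pole cortical path at
#' 1-pixel arc-length spacing. Each sample is the mean of \code{widthPx}
#' bilinear sub-samples placed perpendicular to the local path direction
#' (five by convention, matching a five-pixel-wide linescan). Sub-samples
#' falling outside the image are dropped from the mean; a sample with no
#' surviving sub-sample is an error.
#'
#' @param plane a [PlaneSeries-class].
#' @param path a [CortexPath-class]; its \code{frameIndex} selects the frame.
#' @param poleWindowPx baseline window recorded on the profile.
#' @return An unnormalized [LinescanProfile-class] with
#'   \code{round(arc length) + 1} samples.
#' @export
extractCorticalLinescan <- function(plane, path, poleWindowPx = 50L) {
  img <- movieData(plane)[path@frameIndex + 1L, , ]
  extractAlongPath(img, path@vertices, path@widthPx, pixelSize(plane),
                   poleWindowPx)
}

#' Extract a straight midzone linescan
#'
#' As [extractCorticalLinescan()] but along a straight line (typically on a
#' six-central-slice projection, to profile the central spindle across the
#' midzone). The furrow offset is measured from the line midpoint.
#'
#' @param plane a [PlaneSeries-class] (six-central-slice projection by
#'   convention).
#' @param line a [FurrowLine-class] giving the two endpoints.
#' @param widthPx odd averaging width.
#' @param poleWindowPx baseline window recorded on the profile.
#' @return A [LinescanProfile-class] with furrow offsets relative to the
#'   line midpoint.
#' @export
extractMidzoneLinescan <- function(plane, line, widthPx = 1L,
                                   poleWindowPx = 50L) {
  img <- movieData(plane)[line@frameIndex + 1L, , ]
  prof <- extractAlongPath(img, line@endpoints, as.integer(widthPx),
                           pixelSize(plane), poleWindowPx)
  mid <- max(prof@arcPositionPx) / 2
  prof@furrowOffsetPx <- prof@arcPositionPx - mid
  prof
}

#' Register a profile to the furrow
#'
#' Positions the samples relative to the furrow: finds where the furrow
#' line crosses the cortical path (sign change of the perpendicular
#' distance to the infinite furrow line; nearest approach if the line does
#' not formally intersect) and stores
#' \code{furrowOffsetPx = arcPosition - arc(crossing)}.
#'
#' @param profile a [LinescanProfile-class] extracted from a path.
#' @param path the [CortexPath-class] the profile came from.
#' @param furrow a [FurrowLine-class].
#' @param maxDistancePx registration fails if the furrow line is farther
#'   than this from every path sample (default 10).
#' @return The profile with \code{furrowOffsetPx} filled in; the crossing
#'   index is attached as \code{attr(., "crossingIndex")} (1-based).
#' @export
registerToFurrow <- function(profile, path, furrow, maxDistancePx = 10) {
  rs <- resamplePolyline(path@vertices)
  e <- furrow@endpoints
  dir <- e[2, ] - e[1, ]
  dir <- dir / sqrt(sum(dir^2))
  # signed perpendicular distance of each sample from the infinite line
  sgn <- (rs$x - e[1, 1]) * dir[2] - (rs$y - e[1, 2]) * dir[1]
  if (min(abs(sgn)) > maxDistancePx)
    stop(sprintf("furrow line is farther than %g px from every path sample",
                 maxDistancePx))
  flips <- which(sgn[-1] * sgn[-length(sgn)] <= 0)
  crossing <- if (length(flips)) {
    i <- flips[1]
    if (abs(sgn[i]) <= abs(sgn[i + 1])) i else i + 1L
  } else {
    which.min(abs(sgn))
  }
  profile@furrowOffsetPx <- profile@arcPositionPx - rs$arc[crossing]
  attr(profile, "crossingIndex") <- crossing
  profile
}

#' Normalize a linescan profile
#'
#' Computes the baseline as the average intensity of the first or last
#' \code{poleWindowPx} samples (50 by convention) and the peak height as
#' the maximum intensity minus the baseline. With \code{mode = "min"}
#' (default) the baseline is the lower of the two pole-window means, which
#' is robust when one pole abuts a neighbouring cell; \code{mode = "both"}
#' pools both windows. Raw samples are not altered; baseline, peak height
#' and the (first-on-ties) peak index are stored on the profile.
#'
#' @param profile a [LinescanProfile-class] with at least
#'   \code{2 * poleWindowPx + 1} samples.
#' @param mode "min" or "both".
#' @return The profile with \code{baseline}, \code{peakHeight} and
#'   \code{peakIndex} set.
#' @export
normalizeProfile <- function(profile, mode = c("min", "both")) {
  mode <- match.arg(mode)
  n <- length(profile@intensity)
  w <- profile@poleWindowPx
  if (n < 2L * w + 1L)
    stop(sprintf("profile has %d samples; need more than two %d-pixel pole windows",
                 n, w))
  first <- mean(profile@intensity[seq_len(w)])
  last <- mean(profile@intensity[seq(n - w + 1L, n)])
  profile@baseline <- if (mode == "min") min(first, last) else (first + last) / 2
  profile@peakIndex <- which.max(profile@intensity)  # first maximum on ties
  profile@peakHeight <- profile@intensity[profile@peakIndex] - profile@baseline
  profile@baselineMode <- mode
  profile
}

#' Reverse the direction of a profile
#'
#' Maps a pole-to-pole profile traced in the opposite direction: samples
#' are reversed, arc positions re-anchored at the new first pole, and
#' furrow offsets negated. Downstream breadth and enrichment are invariant
#' under reversal.
#'
#' @param profile a [LinescanProfile-class].
#' @return The reversed profile (normalization is recomputed if present).
#' @export
reverseProfile <- function(profile) {
  n <- length(profile@intensity)
  out <- newProfile(max(profile@arcPositionPx) - rev(profile@arcPositionPx),
                    rev(profile@intensity), profile@pixelSizeUm,
                    profile@poleWindowPx)
  if (!all(is.na(profile@furrowOffsetPx)))
    out@furrowOffsetPx <- -rev(profile@furrowOffsetPx)
  if (!is.na(profile@baseline))
    out <- normalizeProfile(out, profile@baselineMode)
  out
}
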