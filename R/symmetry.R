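# Direct least-squares ellipse fit (numerically stable partitioned form).
# Returns the conic coefficients (A, B, C, D, E, F) of
# A x^2 + B xy + C y^2 + D x + E y + F = 0 with the ellipse constraint
# 4AC - B^2 > 0 enforced by the generalized eigenproblem.
fitEllipseConic <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  mx <- mean(x); my <- mean(y)
  sc <- max(stats::sd(x), stats::sd(y), 1e-12)
  xs <- (x - mx) / sc; ys <- (y - my) / sc
  D1 <- cbind(xs^2, xs * ys, ys^2)
  D2 <- cbind(xs, ys, 1)
  S1 <- crossprod(D1)
  S2 <- crossprod(D1, D2)
  S3 <- crossprod(D2)
  T <- tryCatch(-solve(S3, t(S2)), error = function(e) NULL)
  if (is.null(T)) stop("degenerate or collinear outline points")
  M <- S1 + S2 %*% T
  M <- rbind(M[3, ] / 2, -M[2, ], M[1, ] / 2)
  ev <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(ev)) stop("degenerate or collinear outline points")
  V <- Re(ev$vectors)
  cond <- 4 * V[1, ] * V[3, ] - V[2, ]^2
  k <- which(cond > 1e-12)
  if (!length(k)) stop("degenerate or collinear outline points")
  a1 <- V[, k[1]]
  co <- c(a1, as.numeric(T %*% a1))  # coefficients in scaled coordinates
  # un-scale: substitute xs = (x - mx)/sc, ys = (y - my)/sc
  A <- co[1] / sc^2; B <- co[2] / sc^2; C <- co[3] / sc^2
  D <- co[4] / sc - 2 * co[1] * mx / sc^2 - co[2] * my / sc^2
  E <- co[5] / sc - 2 * co[3] * my / sc^2 - co[2] * mx / sc^2
  F <- co[6] + co[1] * mx^2 / sc^2 + co[2] * mx * my / sc^2 +
    co[3] * my^2 / sc^2 - co[4] * mx / sc - co[5] * my / sc
  c(A, B, C, D, E, F)
}

conicToEllipse <- function(co) {
  A <- co[1]; B <- co[2]; C <- co[3]; D <- co[4]; E <- co[5]; F <- co[6]
  den <- 4 * A * C - B^2
  if (den <= 0) stop("conic is not an ellipse")
  cx <- (B * E - 2 * C * D) / den
  cy <- (B * D - 2 * A * E) / den
  F0 <- A * cx^2 + B * cx * cy + C * cy^2 + D * cx + E * cy + F
  Q <- matrix(c(A, B / 2, B / 2, C), 2, 2)
  lam <- eigen(Q, symmetric = TRUE, only.values = TRUE)$values
  ax <- sqrt(-F0 / lam)
  if (any(!is.finite(ax)))
    stop("degenerate or collinear outline points")
  list(center = c(cx, cy), a = max(ax), b = min(ax))
}

#' Fit a circle to a ring outline
#'
#' Outlines are fitted as ellipses by direct least squares (at least five
#' perimeter points) or supplied directly as ellipse parameters, then
#' reduced to a best-fit circle: centre = ellipse centre, radius =
#' \code{(a + b) / 2} (or \code{sqrt(a b)} with
#' \code{circleRadiusRule = "geometric"}).
#'
#' @param outline an n x 2 matrix of (x, y) perimeter points (n >= 5), or a
#'   list with elements \code{center} (x, y), \code{a}, \code{b}.
#' @param frameIndex 0-based frame index recorded on the fit.
#' @param config a [QuantConfig-class] (for the radius rule).
#' @return A [CircleFit-class]; the residual is the RMS distance of the
#'   points from the fitted circle (NA for parametric input).
#' @examples
#' ang <- seq(0, 2 * pi, length.out = 9)[-9]
#' fitCircle(cbind(1 + 5 * cos(ang), 2 + 5 * sin(ang)))
#' @export
fitCircle <- function(outline, frameIndex = 0L, config = QuantConfig()) {
  if (is.list(outline) && !is.null(outline$center)) {
    a <- outline$a; b <- outline$b
    if (is.null(a) || is.null(b) || a < b || b <= 0)
      stop("ellipse parameters require a >= b > 0")
    el <- list(center = as.numeric(outline$center), a = a, b = b)
    residual <- NA_real_
    pts <- NULL
  } else {
    pts <- as.matrix(outline)
    if (nrow(pts) < 5L) stop("need at least 5 outline points")
    el <- conicToEllipse(fitEllipseConic(pts))
  }
  radius <- switch(config@circleRadiusRule,
                   mean = (el$a + el$b) / 2,
                   geometric = sqrt(el$a * el$b))
  if (!is.null(pts)) {
    d <- sqrt((pts[, 1] - el$center[1])^2 + (pts[, 2] - el$center[2])^2)
    residual <- sqrt(mean((d - radius)^2))
  }
  new("CircleFit", frameIndex = as.integer(frameIndex),
      center = el$center, radius = radius, residual = residual)
}

#' Normalize a ring-closure trajectory to its first timepoint
#'
#' Sets the first-frame ring centre to (0, 0) and radius to 1 and expresses
#' every subsequent centre and radius in units of the first-frame radius:
#' \code{center_t' = (center_t - center_0) / radius_0},
#' \code{radius_t' = radius_t / radius_0}.
#'
#' @param fits a data.frame with columns frame, cx, cy, radius (and
#'   optionally residual), or a list of [CircleFit-class] objects, ordered
#'   in time.
#' @return A [RingTrajectory-class].
#' @export
normalizeTrajectory <- function(fits) {
  if (is.list(fits) && !is.data.frame(fits)) {
    fits <- do.call(rbind, lapply(fits, function(f)
      data.frame(frame = f@frameIndex, cx = f@center[1], cy = f@center[2],
                 radius = f@radius, residual = f@residual)))
  }
  if (nrow(fits) < 2L) stop("need at least 2 timepoints")
  if (!"residual" %in% names(fits)) fits$residual <- NA_real_
  r0 <- fits$radius[1]
  if (r0 <= 0) stop("first-frame radius must be positive")
  centers <- cbind(x = (fits$cx - fits$cx[1]) / r0,
                   y = (fits$cy - fits$cy[1]) / r0)
  new("RingTrajectory", fits = fits, normalizedCenters = centers,
      normalizedRadii = fits$radius / r0)
}

#' Ring-closure symmetry value
#'
#' The Euclidean distance between the cell centre at the first timepoint
#' (0, 0, after normalization) and the ring centre at the last measured
#' timepoint, in units of the initial ring radius. 0 means perfectly
#' concentric closure; 1 means the ring closed at the original perimeter.
#'
#' @param trajectory a [RingTrajectory-class].
#' @return The symmetry value (dimensionless, >= 0).
#' @export
symmetryValue <- function(trajectory) {
  n <- nrow(trajectory@normalizedCenters)
  sqrt(sum(trajectory@normalizedCenters[n, ]^2))
}

#' Classify ring-closure symmetry
#'
#' Values below \code{symmetricCutoff} (0.2) are symmetric; values above
#' \code{highAsymCutoff} (0.6) are highly asymmetric; everything between —
#' including both boundaries — is asymmetric.
#'
#' @param value symmetry value(s), >= 0.
#' @param config a [QuantConfig-class].
#' @return Character vector of "symmetric", "asymmetric" or
#'   "highly_asymmetric".
#' @examples
#' classifySymmetry(c(0.1, 0.4, 0.7))
#' @export
classifySymmetry <- function(value, config = QuantConfig()) {
  if (any(value < 0)) stop("symmetry values must be non-negative")
  ifelse(value < config@symmetricCutoff, "symmetric",
         ifelse(value > config@highAsymCutoff, "highly_asymmetric",
                "asymmetric"))
}

#' Summarize symmetry classes across cells
#'
#' Per-category counts and percentages (count / total x 100, reported to
#' one decimal).
#'
#' @param x symmetry categories (character) or numeric symmetry values
#'   (classified with \code{config} first).
#' @param config a [QuantConfig-class], used when \code{x} is numeric.
#' @return data.frame with columns category, count, percent, covering all
#'   three categories in severity order.
#' @examples
#' summarizeSymmetryClasses(rep(c("symmetric", "asymmetric", "highly_asymmetric"),
#'                              c(1, 13, 7)))
#' @export
summarizeSymmetryClasses <- function(x, config = QuantConfig()) {
  if (!length(x)) stop("no symmetry results")
  if (is.numeric(x)) x <- classifySymmetry(x, config)
  levs <- c("symmetric", "asymmetric", "highly_asymmetric")
  if (!all(x %in% levs)) stop("unknown symmetry category")
  counts <- table(factor(x, levels = levs))
  data.frame(category = levs,
             count = as.integer(counts),
             percent = round(100 * as.integer(counts) / length(x), 1))
}

#' Reslice a movie to an end-on view of the ring
#'
#' Resamples a rectangular region so that Z becomes an in-plane axis,
#' turning the side view of the closing ring into a face-on view. The
#' region is averaged along the viewing axis, then the Z axis is rescaled
#' by \code{zStepUm / pixelSizeUm} with linear interpolation so the output
#' is isotropic.
#'
#' @param movie a [Movie-class] with at least 2 slices.
#' @param roi integer(4) rectangle \code{c(x, y, w, h)} (0-based) containing
#'   the ring; NULL uses a centred 250 x 50 rectangle clipped to the image.
#' @param axis "YZ" (view along x: output columns span the ROI's y extent)
#'   or "XZ" (view along y: columns span the x extent).
#' @return A [PlaneSeries-class] of end-on images (rows = rescaled Z);
#'   provenance records the ROI, axis and Z scale factor.
#' @export
resliceEndOn <- function(movie, roi = NULL, axis = c("YZ", "XZ")) {
  axis <- match.arg(axis)
  d <- movieData(movie)
  Z <- dim(d)[2L]; Y <- dim(d)[3L]; X <- dim(d)[4L]
  if (Z < 2L) stop("cannot reslice a single-slice movie")
  zScale <- movie@zStepUm / pixelSize(movie)
  if (!is.finite(zScale) || zScale <= 0) stop("anisotropy factor must be > 0")
  if (is.null(roi)) {
    w <- min(250L, X); h <- min(50L, Y)
    roi <- c(floor((X - w) / 2), floor((Y - h) / 2), w, h)
  }
  x0 <- roi[1] + 1L; y0 <- roi[2] + 1L
  x1 <- roi[1] + roi[3]; y1 <- roi[2] + roi[4]
  if (x0 < 1 || y0 < 1 || x1 > X || y1 > Y) stop("ROI lies outside the image")
  zIn <- (0:(Z - 1)) * zScale
  zOut <- seq(0, zIn[Z], by = 1)
  nT <- dim(d)[1L]
  nCols <- if (axis == "YZ") y1 - y0 + 1L else x1 - x0 + 1L
  out <- array(0, dim = c(nT, length(zOut), nCols))
  for (t in seq_len(nT)) {
    sub <- d[t, , y0:y1, x0:x1, drop = FALSE][1, , , ]
    zy <- if (axis == "YZ") apply(sub, c(1L, 2L), mean)
          else apply(sub, c(1L, 3L), mean)
    for (j in seq_len(nCols))
      out[t, , j] <- stats::approx(zIn, zy[, j], xout = zOut)$y
  }
  new("PlaneSeries", data = out,
      provenance = list(mode = "end_on_reslice", axis = axis, roi = roi,
                        zScale = zScale),
      pixelSizeUm = pixelSize(movie), frameIntervalMin = frameInterval(movie))
}

#' Plot a normalized ring-closure trajectory
#'
#' Concentric circles coloured by time, first frame outermost, in
#' normalized coordinates.
#'
#' @param trajectory a [RingTrajectory-class].
#' @param file optional PNG path; NULL draws on the current device.
#' @return Invisibly, the trajectory.
#' @export
plotTrajectory <- function(trajectory, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 480, height = 480)
    on.exit(grDevices::dev.off())
  }
  n <- nrow(trajectory@fits)
  cols <- grDevices::hcl.colors(n, "Viridis")
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 xlab = "x / R0", ylab = "y / R0",
                 main = "Ring closure (first frame outermost)")
  for (i in seq_len(n)) {
    ang <- seq(0, 2 * pi, length.out = 120)
    graphics::lines(trajectory@normalizedCenters[i, 1] +
                      trajectory@normalizedRadii[i] * cos(ang),
                    trajectory@normalizedCenters[i, 2] +
                      trajectory@normalizedRadii[i] * sin(ang),
                    col = cols[i])
  }
  invisible(trajectory)
}
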