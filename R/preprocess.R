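#' Subtract background from a movie
#'
#' Estimates and subtracts a per-frame background. Methods:
#' \describe{
#'   \item{constant}{a fixed value, subtracted from every frame.}
#'   \item{percentile}{the per-frame p-th percentile of all voxel
#'     intensities (default p = 5, a parameter-free estimate when most of
#'     the field of view is background).}
#'   \item{roi}{the per-frame mean over a user-supplied rectangle known to
#'     lie outside the cell; \code{roi = c(x, y, w, h)} in 0-based pixels.}
#' }
#' Negative results are clamped to zero. Per-frame estimates are attached as
#' \code{attr(result, "background")}.
#'
#' @param movie a [Movie-class].
#' @param method "constant", "percentile" or "roi".
#' @param value constant background (a.u.) for method = "constant".
#' @param p percentile in (0, 100) for method = "percentile".
#' @param roi integer(4) rectangle (x, y, width, height) for method = "roi".
#' @return A background-subtracted [Movie-class] with a "background"
#'   attribute (numeric, one estimate per frame).
#' @export
subtractBackground <- function(movie, method = c("percentile", "constant", "roi"),
                               value = 0, p = 5, roi = NULL) {
  method <- match.arg(method)
  d <- movieData(movie)
  nT <- dim(d)[1L]
  bg <- switch(method,
    constant = rep(value, nT),
    percentile = {
      if (p <= 0 || p >= 100) stop("percentile p must lie in (0, 100)")
      vapply(seq_len(nT), function(t)
        stats::quantile(d[t, , , ], p / 100, names = FALSE), numeric(1))
    },
    roi = {
      if (is.null(roi) || length(roi) != 4L) stop("roi must be c(x, y, w, h)")
      x0 <- roi[1] + 1L; y0 <- roi[2] + 1L
      x1 <- roi[1] + roi[3]; y1 <- roi[2] + roi[4]
      if (x0 > x1 || y0 > y1) stop("empty ROI")
      if (x0 < 1 || y0 < 1 || y1 > dim(d)[3L] || x1 > dim(d)[4L])
        stop("ROI lies outside the image")
      vapply(seq_len(nT), function(t)
        mean(d[t, , y0:y1, x0:x1]), numeric(1))
    })
  for (t in seq_len(nT)) d[t, , , ] <- pmax(d[t, , , ] - bg[t], 0)
  out <- Movie(d, pixelSizeUm = pixelSize(movie), zStepUm = movie@zStepUm,
               frameIntervalMin = frameInterval(movie),
               channelName = movie@channelName)
  attr(out, "background") <- bg
  out
}

#' Correct photobleaching
#'
#' Rescales frames to compensate for fluorophore decay. With
#' \code{method = "simple_ratio"} each frame is scaled so that its mean
#' equals the first frame's mean. With \code{method = "exponential_fit"} a
#' single exponential \code{A * exp(-k t)} is fitted to the frame means and
#' each frame is divided by the fitted decay factor \code{exp(-k t)}.
#' Apply after [subtractBackground()]: residual background biases the frame
#' means and hence the correction. Scale factors are attached as
#' \code{attr(result, "scale")}; for the exponential fit the per-frame decay
#' \code{(1 - rate)} estimate is attached as \code{attr(result, "decayPerFrame")}.
#'
#' @param movie a background-subtracted [Movie-class].
#' @param method "simple_ratio" or "exponential_fit".
#' @return A bleach-corrected [Movie-class].
#' @export
correctBleaching <- function(movie, method = c("simple_ratio", "exponential_fit")) {
  method <- match.arg(method)
  d <- movieData(movie)
  nT <- dim(d)[1L]
  means <- vapply(seq_len(nT), function(t) mean(d[t, , , ]), numeric(1))
  if (means[1] <= 0) stop("first-frame mean is zero; cannot normalize")
  if (method == "simple_ratio") {
    scale <- means[1] / means
  } else {
    tt <- 0:(nT - 1)
    if (nT < 3 || any(means <= 0)) {
      fit <- stats::lm(log(pmax(means, .Machine$double.eps)) ~ tt)
      k <- -stats::coef(fit)[2]
    } else {
      start <- stats::coef(stats::lm(log(means) ~ tt))
      fit <- try(stats::nls(means ~ A * exp(-k * tt),
                            start = list(A = exp(start[1]), k = -start[2])),
                 silent = TRUE)
      k <- if (inherits(fit, "try-error")) -start[2] else stats::coef(fit)[["k"]]
    }
    scale <- exp(k * tt)
  }
  for (t in seq_len(nT)) d[t, , , ] <- d[t, , , ] * scale[t]
  out <- Movie(d, pixelSizeUm = pixelSize(movie), zStepUm = movie@zStepUm,
               frameIntervalMin = frameInterval(movie),
               channelName = movie@channelName)
  attr(out, "scale") <- scale
  if (method == "exponential_fit") attr(out, "decayPerFrame") <- exp(-k)
  out
}

#' Average-intensity projection of central Z slices
#'
#' Per frame, the mean over the n central slices. The central block starts
#' at slice \code{floor((Z - n) / 2)} (0-based), which is symmetric about
#' the stack midpoint when Z and n have equal parity. Two central slices
#' are the standard choice for cortical linescans; six for midzone
#' (central-spindle) linescans.
#'
#' @param movie a [Movie-class].
#' @param nCentralSlices number of central slices to average (>= 1, <= Z).
#' @return A [PlaneSeries-class]; provenance records the 0-based slice
#'   indices used.
#' @export
projectZ <- function(movie, nCentralSlices = 2L) {
  n <- as.integer(nCentralSlices)
  Z <- nSlices(movie)
  if (n < 1L) stop("nCentralSlices must be >= 1")
  if (n > Z) stop("nCentralSlices exceeds the stack depth")
  start <- floor((Z - n) / 2)
  idx <- start + seq_len(n)          # 1-based slice indices
  d <- movieData(movie)
  proj <- array(0, dim = dim(d)[c(1L, 3L, 4L)])
  for (t in seq_len(dim(d)[1L]))
    proj[t, , ] <- apply(d[t, idx, , , drop = FALSE], c(3L, 4L), mean)
  new("PlaneSeries", data = proj,
      provenance = list(mode = "average", slices = idx - 1L),
      pixelSizeUm = pixelSize(movie), frameIntervalMin = frameInterval(movie))
}
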