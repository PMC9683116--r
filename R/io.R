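#' Write a movie as multi-page TIFF with a JSON sidecar
#'
#' Pages are written in TZYX order (frame-major) as 32-bit samples scaled
#' to [0, 1]; the scale factor, calibration and axis order go into a JSON
#' sidecar at \code{<path>.json} so the round trip is lossless to float
#' precision.
#'
#' @param movie a [Movie-class].
#' @param path output .tif path.
#' @return Invisibly, the path.
#' @export
writeMovie <- function(movie, path) {
  d <- movieData(movie)
  nT <- dim(d)[1L]; Z <- dim(d)[2L]
  scale <- max(d, 1e-12)
  pages <- vector("list", nT * Z)
  k <- 1L
  for (t in seq_len(nT)) for (z in seq_len(Z)) {
    pages[[k]] <- d[t, z, , ] / scale
    k <- k + 1L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  meta <- list(axisOrder = "TZYX", nFrames = nT, nSlices = Z,
               height = dim(d)[3L], width = dim(d)[4L],
               intensityScale = scale,
               pixelSizeUm = pixelSize(movie), zStepUm = movie@zStepUm,
               frameIntervalMin = frameInterval(movie),
               channelName = movie@channelName)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by [writeMovie()]
#'
#' @param path the .tif path (the \code{<path>.json} sidecar must exist).
#' @param axisOrder expected axis order; must match the sidecar.
#' @return A [Movie-class].
#' @export
readMovie <- function(path, axisOrder = "TZYX") {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar))
    stop("missing calibration sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (!identical(meta$axisOrder, axisOrder))
    stop(sprintf("axis order mismatch: file is %s, expected %s",
                 meta$axisOrder, axisOrder))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != meta$nFrames * meta$nSlices)
    stop("page count does not match the sidecar dimensions")
  d <- array(0, dim = c(meta$nFrames, meta$nSlices, meta$height, meta$width))
  k <- 1L
  for (t in seq_len(meta$nFrames)) for (z in seq_len(meta$nSlices)) {
    d[t, z, , ] <- pages[[k]] * meta$intensityScale
    k <- k + 1L
  }
  Movie(d, pixelSizeUm = meta$pixelSizeUm, zStepUm = meta$zStepUm,
        frameIntervalMin = meta$frameIntervalMin,
        channelName = meta$channelName)
}

#' Write ground truth to JSON
#'
#' @param truth a [GroundTruth-class].
#' @param path output .json path.
#' @return Invisibly, the path.
#' @export
writeGroundTruth <- function(truth, path) {
  p <- truth@params
  obj <- list(
    trueBreadthUm = truth@trueBreadthUm,
    breadthCutoffFraction = truth@breadthCutoffFraction,
    trueEnrichmentFold = truth@trueEnrichmentFold,
    trueCortexCytosolRatio = truth@trueCortexCytosolRatio,
    trueIngressionDurationMin = truth@trueIngressionDurationMin,
    trueSymmetryValue = truth@trueSymmetryValue,
    perFrameRingCenter = unname(truth@perFrameRingCenter),
    perFrameRingRadius = truth@perFrameRingRadius,
    furrowWidthTracePx = truth@furrowWidthTracePx,
    cortexPath = lapply(truth@cortexPath, unname),
    furrowLine = lapply(truth@furrowLine, unname),
    params = simParamsToList(p))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

# a JSON list of equal-shaped matrices simplifies to a 3-D array on read;
# restore the per-frame matrix list either way
matrixList <- function(x) {
  if (is.array(x) && length(dim(x)) == 3L)
    lapply(seq_len(dim(x)[1L]), function(i) x[i, , ])
  else lapply(x, as.matrix)
}

simParamsToList <- function(p) {
  nm <- slotNames(p)
  stats::setNames(lapply(nm, function(s) slot(p, s)), nm)
}

#' Read ground truth written by [writeGroundTruth()]
#'
#' @param path the .json path.
#' @return A [GroundTruth-class].
#' @export
readGroundTruth <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  pl <- o$params
  params <- SimParams(imageShape = pl$imageShape, nSlices = pl$nSlices,
                      nFrames = pl$nFrames, pixelSizeUm = pl$pixelSizeUm,
                      zStepUm = pl$zStepUm,
                      frameIntervalMin = pl$frameIntervalMin,
                      cellRadiusUm = pl$cellRadiusUm,
                      cortexThicknessUm = pl$cortexThicknessUm,
                      cytosolLevel = pl$cytosolLevel,
                      cortexLevel = pl$cortexLevel,
                      equatorialEnrichmentFold = pl$equatorialEnrichmentFold,
                      enrichmentSigmaUm = pl$enrichmentSigmaUm,
                      enrichmentOnsetFrame = pl$enrichmentOnsetFrame,
                      ingressionStartFrame = pl$ingressionStartFrame,
                      ingressionRateUmPerMin = pl$ingressionRateUmPerMin,
                      closureAsymmetry = pl$closureAsymmetry,
                      bleachRatePerFrame = pl$bleachRatePerFrame,
                      backgroundLevel = pl$backgroundLevel,
                      noiseModel = pl$noiseModel, noiseSigma = pl$noiseSigma,
                      seed = pl$seed)
  centers <- as.matrix(o$perFrameRingCenter)
  colnames(centers) <- c("x", "y")
  new("GroundTruth",
      trueBreadthUm = o$trueBreadthUm,
      breadthCutoffFraction = o$breadthCutoffFraction,
      trueEnrichmentFold = o$trueEnrichmentFold,
      trueCortexCytosolRatio = o$trueCortexCytosolRatio,
      trueIngressionDurationMin = if (is.null(o$trueIngressionDurationMin))
        NA_real_ else o$trueIngressionDurationMin,
      trueSymmetryValue = o$trueSymmetryValue,
      perFrameRingCenter = centers,
      perFrameRingRadius = o$perFrameRingRadius,
      furrowWidthTracePx = o$furrowWidthTracePx,
      cortexPath = lapply(matrixList(o$cortexPath), function(m) {
        colnames(m) <- c("x", "y"); m
      }),
      furrowLine = matrixList(o$furrowLine),
      params = params)
}

#' Read point annotations (paths, lines, outlines) from JSON or CSV
#'
#' JSON files hold either a single array of (x, y) pairs or an object
#' keyed by frame index, each value an array of (x, y) pairs. CSV files
#' need columns x and y (and optionally frame). All coordinates are 0-based
#' pixels.
#'
#' @param path .json or .csv file.
#' @return A named list (frame index as name) of n x 2 (x, y) matrices.
#' @export
readAnnotations <- function(path) {
  asXY <- function(m, where) {
    m <- as.matrix(m)
    if (ncol(m) != 2L || !is.numeric(m))
      stop("malformed annotation in ", where, ": expected (x, y) pairs")
    colnames(m) <- c("x", "y")
    m
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    o <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (is.matrix(o) || is.data.frame(o))
      return(list("0" = asXY(o, path)))
    out <- lapply(names(o), function(k) asXY(o[[k]], paste0(path, " key ", k)))
    names(out) <- names(o)
    return(out)
  }
  df <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(df)))
    stop("CSV annotation needs x and y columns: ", path)
  bad <- which(!is.finite(df$x) | !is.finite(df$y))
  if (length(bad))
    stop(sprintf("non-numeric coordinate in %s at row %d", path, bad[1]))
  if (!"frame" %in% names(df)) df$frame <- 0L
  out <- lapply(split(df[, c("x", "y")], df$frame), asXY, where = path)
  out
}

#' Write a tidy result table with provenance header
#'
#' Prepends '#'-comment lines carrying the software version, a hash of the
#' quantification config, and every threshold, then the CSV body.
#'
#' @param rows a data.frame.
#' @param path output .csv path.
#' @param config optional [QuantConfig-class] echoed into the header.
#' @return Invisibly, the path.
#' @export
writeTable <- function(rows, path, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ringmetrics %s",
                     as.character(utils::packageVersion("ringmetrics"))), con)
  if (!is.null(config)) {
    cfg <- stats::setNames(lapply(slotNames(config), function(s) slot(config, s)),
                           slotNames(config))
    js <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
    tf <- tempfile(); writeLines(js, tf)
    writeLines(sprintf("# config_hash %s", unname(tools::md5sum(tf))), con)
    unlink(tf)
    writeLines(sprintf("# config %s", js), con)
  }
  utils::write.csv(rows, con, row.names = FALSE)
  invisible(path)
}

#' Write a linescan profile to CSV
#'
#' Columns arc_position_px, furrow_offset_px, intensity; baseline and peak
#' fields (when the profile is normalized) go into the '#' header.
#'
#' @param profile a [LinescanProfile-class].
#' @param path output .csv path.
#' @return Invisibly, the path.
#' @export
writeProfile <- function(profile, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# ringmetrics %s",
                     as.character(utils::packageVersion("ringmetrics"))), con)
  writeLines(sprintf("# pixel_size_um %.17g", profile@pixelSizeUm), con)
  if (!is.na(profile@baseline))
    writeLines(sprintf("# baseline %.17g peak_height %.17g peak_index %d mode %s",
                       profile@baseline, profile@peakHeight,
                       profile@peakIndex, profile@baselineMode), con)
  utils::write.csv(data.frame(arc_position_px = profile@arcPositionPx,
                              furrow_offset_px = profile@furrowOffsetPx,
                              intensity = profile@intensity),
                   con, row.names = FALSE)
  invisible(path)
}

#' Read a table written by [writeTable()]
#'
#' @param path the .csv path.
#' @return data.frame (header comments skipped).
#' @export
readTable <- function(path) {
  utils::read.csv(path, comment.char = "#")
}
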