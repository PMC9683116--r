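#' Read an analysis manifest
#'
#' A manifest is a JSON or YAML file (or an equivalent named list)
#' describing one analysis batch: the movie, its annotations, the anaphase
#' frame, calibration overrides and quantification config. Recognized
#' fields:
#' \describe{
#'   \item{movie}{path to a .tif written by [writeMovie()] (sidecar
#'     required).}
#'   \item{cortexPaths, furrowLines, ringOutlines}{annotation files for
#'     [readAnnotations()]; each optional — stages without their
#'     annotations are skipped.}
#'   \item{furrowWidthTrace}{CSV with columns frame, width_px (optional).}
#'   \item{anaphaseFrame}{0-based anaphase-onset frame (default 0).}
#'   \item{pixelSizeUm, frameIntervalMin}{calibration overrides; physical
#'     units must come from the movie sidecar or the manifest, never from
#'     silent defaults.}
#'   \item{config}{named list of [QuantConfig()] arguments.}
#'   \item{outDir}{output directory.}
#'   \item{seed}{integer seed echoed into outputs.}
#' }
#'
#' @param manifest a path to .json/.yaml/.yml, or a named list.
#' @return The manifest as a named list with a built QuantConfig attached
#'   as \code{$quantConfig}.
#' @export
readManifest <- function(manifest) {
  if (is.character(manifest)) {
    m <- if (grepl("\\.ya?ml$", manifest, ignore.case = TRUE))
      yaml::read_yaml(manifest)
    else jsonlite::read_json(manifest, simplifyVector = TRUE)
  } else m <- manifest
  for (f in c("movie", "cortexPaths", "furrowLines", "ringOutlines",
              "furrowWidthTrace")) {
    if (!is.null(m[[f]]) && !file.exists(m[[f]]))
      stop("manifest references a missing file: ", m[[f]])
  }
  m$quantConfig <- do.call(QuantConfig, as.list(m$config))
  if (is.null(m$anaphaseFrame)) m$anaphaseFrame <- 0L
  if (is.null(m$seed)) m$seed <- 1L
  m
}

#' Run the full quantification pipeline
#'
#' Chains the stages over one movie: preprocessing (percentile background
#' subtraction, simple-ratio bleach correction, two-central-slice
#' projection), per-frame cortical linescans with furrow registration and
#' normalization, peak breadth and furrow enrichment, ingression duration
#' from a furrow-width trace, and ring-closure symmetry from ring
#' outlines. Stages whose annotations are absent are skipped with a logged
#' reason; per-cell failures (e.g. "not closed") are recorded without
#' aborting the batch. Outputs are deterministic given identical inputs
#' and seed.
#'
#' @param manifest path or list for [readManifest()].
#' @return Invisibly, a list with elements \code{metrics} (per-frame tidy
#'   data.frame), \code{symmetry} (data.frame or NULL), \code{duration}
#'   (list or NULL), \code{skipped} (character log), \code{outDir}.
#' @export
runPipeline <- function(manifest) {
  m <- readManifest(manifest)
  cfg <- m$quantConfig
  log <- character()
  if (is.null(m$movie)) stop("manifest must name a movie")
  movie <- readMovie(m$movie)
  if (!is.null(m$pixelSizeUm)) movie@pixelSizeUm <- m$pixelSizeUm
  if (!is.null(m$frameIntervalMin)) movie@frameIntervalMin <- m$frameIntervalMin

  pre <- correctBleaching(subtractBackground(movie, "percentile"),
                          "simple_ratio")
  planes <- projectZ(pre, 2L)

  metrics <- NULL
  if (!is.null(m$cortexPaths)) {
    paths <- readAnnotations(m$cortexPaths)
    furrows <- if (!is.null(m$furrowLines)) readAnnotations(m$furrowLines)
    rows <- list()
    profiles <- list()
    for (k in names(paths)) {
      fr <- as.integer(k)
      path <- CortexPath(paths[[k]], widthPx = cfg@linescanWidthPx,
                         frameIndex = fr)
      prof <- extractCorticalLinescan(planes, path,
                                      poleWindowPx = cfg@poleWindowPx)
      if (!is.null(furrows) && k %in% names(furrows)) {
        fl <- FurrowLine(furrows[[k]][1, ], furrows[[k]][2, ], fr)
        prof <- registerToFurrow(prof, path, fl)
      }
      prof <- normalizeProfile(prof, cfg@baselineMode)
      profiles[[k]] <- prof
      res <- tryCatch({
        br <- peakBreadth(prof, cfg)
        en <- furrowEnrichment(prof, br)
        data.frame(frame = fr,
                   metric = c("breadth_px", "breadth_um", "breadth_fraction",
                              "enrichment_ratio", "excluded_pixels"),
                   value = c(breadthPx(br), breadthUm(br),
                             breadthFraction(br, length(intensity(prof))),
                             enrichmentRatio(en),
                             excludedPixelCount(br)))
      }, error = function(e) {
        log <<- c(log, sprintf("frame %d: %s", fr, conditionMessage(e)))
        NULL
      })
      rows[[k]] <- res
    }
    metrics <- do.call(rbind, rows)
    rownames(metrics) <- NULL
    out0 <- m$outDir
    if (!is.null(out0)) {
      dir.create(out0, recursive = TRUE, showWarnings = FALSE)
      for (k in names(profiles))
        writeProfile(profiles[[k]],
                     file.path(out0, sprintf("profile_frame%03d.csv",
                                             as.integer(k))))
    }
  } else {
    log <- c(log, "linescan metrics skipped: no cortexPaths annotation")
  }

  duration <- NULL
  if (!is.null(m$furrowWidthTrace)) {
    tr <- utils::read.csv(m$furrowWidthTrace, comment.char = "#")
    duration <- ingressionDuration(tr$width_px[order(tr$frame)],
                                   m$anaphaseFrame,
                                   frameInterval(movie), cfg)
    if (!duration$closed)
      log <- c(log, "ingression: not closed within the movie")
  } else {
    log <- c(log, "ingression duration skipped: no furrowWidthTrace")
  }

  symmetry <- NULL
  if (!is.null(m$ringOutlines)) {
    outlines <- readAnnotations(m$ringOutlines)
    fits <- lapply(names(outlines), function(k)
      fitCircle(outlines[[k]], frameIndex = as.integer(k), config = cfg))
    traj <- normalizeTrajectory(fits[order(vapply(fits, function(f)
      f@frameIndex, integer(1)))])
    v <- symmetryValue(traj)
    symmetry <- data.frame(symmetry_value = v,
                           category = classifySymmetry(v, cfg))
  } else {
    log <- c(log, "symmetry skipped: no ringOutlines annotation")
  }

  out <- list(metrics = metrics, symmetry = symmetry, duration = duration,
              skipped = log)
  if (!is.null(m$outDir)) {
    dir.create(m$outDir, recursive = TRUE, showWarnings = FALSE)
    if (!is.null(metrics))
      writeTable(metrics, file.path(m$outDir, "linescan_metrics.csv"), cfg)
    if (!is.null(symmetry))
      writeTable(symmetry, file.path(m$outDir, "symmetry.csv"), cfg)
    if (!is.null(duration))
      writeTable(data.frame(closed = duration$closed,
                            closure_frame = duration$closureFrame,
                            duration_min = duration$durationMin),
                 file.path(m$outDir, "ingression.csv"), cfg)
    writeLines(log, file.path(m$outDir, "pipeline.log"))
    out$outDir <- m$outDir
  }
  invisible(out)
}
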