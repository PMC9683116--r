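planeFromMatrix <- function(img, pixelSizeUm = 0.2) {
  d <- array(0, dim = c(1, nrow(img), ncol(img)))
  d[1, , ] <- img
  new("PlaneSeries", data = d, provenance = list(mode = "test"),
      pixelSizeUm = pixelSizeUm, frameIntervalMin = 1)
}

test_that("linescan sampling honours the arc-length and width contracts", {
  uni <- planeFromMatrix(matrix(7, 60, 60))
  path <- CortexPath(cbind(c(10, 50), c(30, 30)))
  prof <- extractCorticalLinescan(uni, path)
  expect_equal(length(intensity(prof)), 41L)  # round(arc) + 1 samples
  expect_equal(intensity(prof), rep(7, 41))

  # constant along y, linear along x: a vertical 5-px-wide path averages
  # symmetric perpendicular offsets and returns the gradient value at x = c
  grad <- matrix(rep(0:59, each = 60), 60, 60)  # value = 0-based column (x)
  gradPlane <- planeFromMatrix(grad)
  vpath <- CortexPath(cbind(c(25, 25), c(5, 55)))
  vprof <- extractCorticalLinescan(gradPlane, vpath)
  expect_equal(intensity(vprof), rep(25, 51))

  # straight line of length 100 px gives 101 samples
  line <- FurrowLine(c(5, 20), c(105, 20))
  mid <- extractMidzoneLinescan(planeFromMatrix(matrix(3, 40, 120)), line)
  expect_equal(length(intensity(mid)), 101L)
  expect_equal(intensity(mid), rep(3, 101))
  expect_equal(furrowOffset(mid), -50:50)  # offsets from the line midpoint
})

test_that("profiles on simulated cells peak at the ground-truth equator", {
  sim <- simulateDivisionMovie(SimParams(seed = 3))
  fr <- sim$truth@params@ingressionStartFrame
  planes <- projectZ(correctBleaching(
    subtractBackground(sim$movie, "percentile"), "simple_ratio"), 2L)
  path <- CortexPath(sim$truth@cortexPath[[fr + 1L]], frameIndex = fr)
  prof <- extractCorticalLinescan(planes, path)
  fl <- sim$truth@furrowLine[[fr + 1L]]
  prof <- registerToFurrow(prof, path, FurrowLine(fl[1, ], fl[2, ], fr))
  prof <- normalizeProfile(prof)
  # the path is pole-equator-pole, so the equator sits at half the arc
  equatorArc <- max(arcPosition(prof)) / 2
  expect_lte(abs(arcPosition(prof)[peakIndex(prof)] - equatorArc), 2)
  # the offset-0 sample is the registered furrow crossing, also equatorial
  zeroIdx <- which.min(abs(furrowOffset(prof)))
  expect_lte(abs(arcPosition(prof)[zeroIdx] - equatorArc), 2)
  expect_true(all(diff(furrowOffset(prof)) > 0))
})

test_that("furrow registration finds the crossing and rejects distant lines", {
  uni <- planeFromMatrix(matrix(1, 80, 200))
  path <- CortexPath(cbind(c(10, 190), c(40, 40)))
  prof <- extractCorticalLinescan(uni, path)
  furrow <- FurrowLine(c(130, 10), c(130, 70))  # crosses at arc 120
  reg <- registerToFurrow(prof, path, furrow)
  expect_equal(furrowOffset(reg)[arcPosition(reg) == 120], 0)
  far <- FurrowLine(c(500, 10), c(500, 70))
  expect_error(registerToFurrow(prof, path, far), "farther")
})

test_that("normalization computes baseline and peak height per convention", {
  pr <- makeProfileFixture(300, baseline = 100, peakHeight = 200,
                           peakCenter = 150, peakSigma = 8)
  pr <- normalizeProfile(pr)
  expect_equal(baseline(pr), 100)
  expect_equal(peakHeight(pr), 200)
  expect_equal(peakIndex(pr), 151L)

  flat <- normalizeProfile(makeProfileFixture(200, 50, 0, 100, 5))
  expect_equal(peakHeight(flat), 0)

  # pole windows >= 3 sigma from the peak recover the height within 1%
  g <- normalizeProfile(makeProfileFixture(301, 50, 450, 150, 8))
  expect_lt(abs(peakHeight(g) - 450) / 450, 0.01)

  short <- suppressWarnings(
    makeProfileFixture(110, 0, 10, 55, 5, poleWindowPx = 60L))
  expect_error(normalizeProfile(short), "pole windows")

  # the "min" convention guards against a bright neighbouring cell
  bright <- makeProfileFixture(300, 100, 200, 150, 8,
                               extraSpikes = lapply(0:49, function(i) c(i, 900)))
  expect_equal(baseline(normalizeProfile(bright, "min")), 100)
  expect_equal(baseline(normalizeProfile(bright, "both")), 500)
})

test_that("normalization responds correctly to affine intensity changes", {
  base <- makeProfileFixture(300, 100, 200, 150, 8)
  shifted <- makeProfileFixture(300, 100 + 37, 200, 150, 8)
  scaled <- makeProfileFixture(300, 100 * 2.5, 200 * 2.5, 150, 8)
  b <- normalizeProfile(base); s <- normalizeProfile(shifted)
  m <- normalizeProfile(scaled)
  expect_equal(baseline(s), baseline(b) + 37)
  expect_equal(peakHeight(s), peakHeight(b))
  expect_equal(peakHeight(m), 2.5 * peakHeight(b))
})

test_that("path reversal flips offsets but preserves breadth and enrichment", {
  pr <- makeProfileFixture(301, 80, 400, 170, 9)
  pr@furrowOffsetPx <- arcPosition(pr) - 170
  pr <- normalizeProfile(pr)
  rv <- reverseProfile(pr)
  expect_equal(intensity(rv), rev(intensity(pr)))
  expect_equal(furrowOffset(rv), -rev(furrowOffset(pr)))
  cfg <- QuantConfig()
  expect_equal(breadthPx(peakBreadth(rv, cfg)), breadthPx(peakBreadth(pr, cfg)))
  expect_equal(enrichmentRatio(furrowEnrichment(rv, peakBreadth(rv, cfg))),
               enrichmentRatio(furrowEnrichment(pr, peakBreadth(pr, cfg))))
})
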