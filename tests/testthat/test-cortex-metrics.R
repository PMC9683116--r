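# rectangular peak: 10 contiguous samples at `level` on a flat baseline
rectProfile <- function(level = 200, baseline = 0, at = 95:104,
                        pixelSizeUm = 0.133, extra = NULL) {
  spikes <- c(lapply(at, function(i) c(i, level)), extra)
  pr <- makeProfileFixture(200, baseline, 0, 100, 5, extraSpikes = spikes,
                           pixelSizeUm = pixelSizeUm)
  normalizeProfile(pr)
}

test_that("peak breadth counts the contiguous above-cutoff run at the peak", {
  pr <- rectProfile()
  br <- peakBreadth(pr, QuantConfig(breadthCutoffFraction = 0.5))
  expect_equal(breadthPx(br), 10L)
  expect_equal(breadthUm(br), 10 * 0.133)
  expect_equal(excludedPixelCount(br), 0L)

  # an isolated equal-intensity sample far from the peak is excluded
  # (placed after the peak: on ties the peak is the lowest arc position)
  withSpike <- rectProfile(extra = list(c(130, 200)))
  br2 <- peakBreadth(withSpike, QuantConfig(breadthCutoffFraction = 0.5))
  expect_equal(breadthPx(br2), 10L)
  expect_equal(excludedPixelCount(br2), 1L)

  flat <- normalizeProfile(makeProfileFixture(200, 50, 0, 100, 5))
  expect_error(peakBreadth(flat, QuantConfig()), "no measurable peak")
  expect_error(peakBreadth(makeProfileFixture(200, 0, 10, 100, 5),
                           QuantConfig()), "normalized")
})

test_that("breadth of a Gaussian peak matches the analytic width", {
  pr <- normalizeProfile(makeProfileFixture(301, 0, 400, 150, 8))
  br <- peakBreadth(pr, QuantConfig(breadthCutoffFraction = 0.5))
  fwhm <- 2 * 8 * sqrt(2 * log(2))  # 18.85 px
  expect_lte(abs(breadthPx(br) - fwhm), 1)
  # the same fixture, counted by the independent brute-force oracle
  o <- bruteBreadth(intensity(pr), baseline(pr), 0.5)
  expect_equal(breadthPx(br), o$n)
})

test_that("breadth agrees with the brute-force oracle on random fixtures", {
  set.seed(7)
  cfgPool <- c(0.5, 0.75)
  for (i in 1:1000) {
    basel <- stats::runif(1, 0, 200)
    h <- stats::runif(1, 10, 1000)
    sig <- stats::runif(1, 2, 25)
    ctr <- sample(80:220, 1)
    spikes <- NULL
    if (i %% 3 == 0)  # isolated decoys above the cutoff, away from the peak
      spikes <- lapply(sample(c(55:70, 240:260), sample(1:3, 1)),
                       function(j) c(j, basel + stats::runif(1, 0.6, 1.2) * h))
    pr <- suppressWarnings(
      makeProfileFixture(301, basel, h, ctr, sig, extraSpikes = spikes))
    pr <- normalizeProfile(pr)
    cfg <- QuantConfig(breadthCutoffFraction = cfgPool[i %% 2 + 1])
    br <- peakBreadth(pr, cfg)
    o <- bruteBreadth(intensity(pr), baseline(pr), cfg@breadthCutoffFraction)
    expect_identical(breadthPx(br), o$n)
    expect_identical(excludedPixelCount(br), o$excluded)
    expect_identical(unname(peakRegion(br)), c(o$lo, o$hi))
  }
})

test_that("breadth is invariant under affine intensity transforms", {
  pr <- normalizeProfile(makeProfileFixture(301, 120, 500, 160, 12))
  aff <- pr
  aff@intensity <- 3.1 * intensity(pr) + 45
  aff <- normalizeProfile(aff)
  for (f in c(0.5, 0.75)) {
    cfg <- QuantConfig(breadthCutoffFraction = f)
    expect_identical(breadthPx(peakBreadth(aff, cfg)),
                     breadthPx(peakBreadth(pr, cfg)))
  }
})

test_that("breadth fraction normalizes for cell size", {
  pr <- rectProfile()
  br <- peakBreadth(pr, QuantConfig(breadthCutoffFraction = 0.5))
  expect_equal(breadthFraction(br, 200), 0.05)
  expect_equal(breadthFraction(br, breadthPx(br)), 1.0)
  expect_error(breadthFraction(br, 0), "positive")
  expect_error(breadthFraction(br, 5), "smaller")
})

test_that("same band sigma in differently sized cells: equal um, scaled fraction", {
  mk <- function(radius, shape) simulateDivisionMovie(
    quietParams(cellRadiusUm = radius, imageShape = shape,
                enrichmentOnsetFrame = 0L, ingressionStartFrame = 99L,
                nFrames = 1L, bleachRatePerFrame = 0))
  small <- mk(10, c(128L, 128L))
  large <- mk(15, c(168L, 168L))
  gs <- measureSimulatedCell(small, cutoff = 0.5, frame = 0L)
  gl <- measureSimulatedCell(large, cutoff = 0.5, frame = 0L)
  expect_lt(abs(gs$breadthUm / gl$breadthUm - 1), 0.1)
  fs <- breadthFraction(gs$breadth, length(intensity(gs$profile)))
  fl <- breadthFraction(gl$breadth, length(intensity(gl$profile)))
  expect_lt(abs(fs / fl - 15 / 10), 0.2)
})

test_that("furrow enrichment is the peak-region to pole-window intensity ratio", {
  pr <- rectProfile(level = 500, baseline = 100)
  br <- peakBreadth(pr, QuantConfig(breadthCutoffFraction = 0.5))
  en <- furrowEnrichment(pr, br)
  expect_equal(enrichmentRatio(en), 5.0)

  # near-uniform profile: ratio collapses to ~1
  pr1 <- rectProfile(level = 100.5, baseline = 100)
  en1 <- furrowEnrichment(pr1, peakBreadth(pr1, QuantConfig()))
  expect_equal(enrichmentRatio(en1), 100.5 / 100)

  # multiplicative scaling leaves the ratio unchanged; offsets do not
  prS <- rectProfile(level = 500 * 3, baseline = 100 * 3)
  expect_equal(enrichmentRatio(furrowEnrichment(prS,
    peakBreadth(prS, QuantConfig()))), 5.0)
  prO <- rectProfile(level = 500 + 100, baseline = 100 + 100)
  expect_false(isTRUE(all.equal(
    enrichmentRatio(furrowEnrichment(prO, peakBreadth(prO, QuantConfig()))),
    5.0)))

  zero <- rectProfile(level = 10, baseline = 0)
  expect_error(furrowEnrichment(zero, peakBreadth(zero, QuantConfig())),
               "pole mean")
})

test_that("metaphase cortex/cytosol ratio recovers the simulated truth", {
  expect_equal(cortexCytosol(cortexCytosolRatio(
    normalizeProfile(makeProfileFixture(200, 100, 0, 100, 5)), 100)), 1.0)
  expect_equal(cortexCytosol(cortexCytosolRatio(
    normalizeProfile(makeProfileFixture(200, 160, 0, 100, 5)), 100)), 1.6)
  expect_error(cortexCytosolRatio(
    normalizeProfile(makeProfileFixture(200, 160, 0, 100, 5)), 0), "positive")

  sim <- simulateDivisionMovie(quietParams(
    equatorialEnrichmentFold = 1, cortexLevel = 72, cytosolLevel = 120,
    ingressionStartFrame = 99L, nFrames = 1L))
  planes <- projectZ(sim$movie, 2L)
  prof <- extractCorticalLinescan(planes,
                                  CortexPath(sim$truth@cortexPath[[1]]))
  cyto <- mean(movieData(planes)[1, 60:68, 60:68])
  r <- cortexCytosol(cortexCytosolRatio(prof, cyto))
  expect_lt(abs(r - sim$truth@trueCortexCytosolRatio) /
              sim$truth@trueCortexCytosolRatio, 0.1)
})

test_that("ingression duration runs from anaphase onset to closure", {
  width <- c(40, 36, 30, 22, 14, 8, 4, 2, 1, 0.5, 0.5)
  d <- ingressionDuration(width, anaphaseFrame = 0, frameIntervalMin = 2)
  expect_true(d$closed)
  expect_equal(d$closureFrame, 8L)
  expect_equal(d$durationMin, 16)

  open <- ingressionDuration(seq(40, 20, length.out = 10), 0, 2)
  expect_false(open$closed)
  expect_true(is.na(open$durationMin))

  expect_error(ingressionDuration(width, anaphaseFrame = 50, 2), "index")

  sim <- simulateDivisionMovie(SimParams(seed = 9))
  tr <- sim$truth
  d2 <- ingressionDuration(tr@furrowWidthTracePx,
                           tr@params@ingressionStartFrame,
                           tr@params@frameIntervalMin)
  expect_lte(abs(d2$durationMin - tr@trueIngressionDurationMin),
             tr@params@frameIntervalMin)
})

test_that("group summaries report exact n, mean and sample SD", {
  one <- summarizeGroups(data.frame(cell_line = "a", value = 5))
  expect_equal(one$n, 1L); expect_equal(one$mean, 5)
  expect_equal(one$sd, 0); expect_true(one$singleObservation)

  two <- summarizeGroups(data.frame(cell_line = "b", value = c(1, 3)))
  expect_equal(two$mean, 2); expect_equal(two$sd, sqrt(2))

  set.seed(11)
  mc <- summarizeGroups(data.frame(cell_line = "c",
                                   value = stats::rnorm(100, 20, 2)))
  expect_lt(abs(mc$mean - 20), 3 * 2 / sqrt(100))
  expect_lt(abs(mc$sd - 2), 0.6)
  expect_error(summarizeGroups(data.frame(cell_line = character(),
                                          value = numeric())), "empty")
})
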