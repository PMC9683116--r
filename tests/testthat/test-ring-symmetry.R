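circlePoints <- function(cx, cy, r, n = 8, a = r, b = r, phi = 0) {
  ang <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  x <- a * cos(ang); y <- b * sin(ang)
  cbind(cx + x * cos(phi) - y * sin(phi),
        cy + x * sin(phi) + y * cos(phi))
}

test_that("circle fitting recovers exact circles and reduces ellipses", {
  f <- fitCircle(circlePoints(1, 2, 5))
  expect_equal(f@center, c(1, 2), tolerance = 1e-6)
  expect_equal(f@radius, 5, tolerance = 1e-6)
  expect_lt(f@residual, 1e-6)

  # tilted ellipse a=4, b=2 reduces to a circle of radius (a + b)/2 = 3
  e <- fitCircle(circlePoints(0, 0, NA, n = 12, a = 4, b = 2, phi = 0.7))
  expect_equal(e@center, c(0, 0), tolerance = 1e-6)
  expect_equal(e@radius, 3, tolerance = 1e-6)

  # parametric input takes the same reduction
  pf <- fitCircle(list(center = c(0, 0), a = 4, b = 2))
  expect_equal(pf@radius, 3)
  expect_equal(fitCircle(list(center = c(1, 1), a = 4, b = 2),
                         config = QuantConfig(circleRadiusRule = "geometric"))@radius,
               sqrt(8))

  expect_error(fitCircle(cbind(1:10, 2 * (1:10))), "collinear")
  expect_error(fitCircle(circlePoints(0, 0, 5, n = 4)), "at least 5")
  expect_error(fitCircle(list(center = c(0, 0), a = 2, b = 4)), "a >= b")
})

test_that("noisy circle outlines are fitted to sub-pixel centre accuracy", {
  set.seed(21)
  errs <- vapply(1:100, function(i) {
    pts <- circlePoints(10, -4, 15, n = 20) + matrix(stats::rnorm(40, 0, 0.2),
                                                     ncol = 2)
    sqrt(sum((fitCircle(pts)@center - c(10, -4))^2))
  }, numeric(1))
  expect_lt(mean(errs), 0.1)
})

test_that("trajectory normalization maps the first ring to ((0,0), 1)", {
  fits <- data.frame(frame = 0:1, cx = c(30, 36), cy = c(40, 48),
                     radius = c(20, 10))
  tr <- normalizeTrajectory(fits)
  expect_equal(unname(normalizedCenters(tr)[1, ]), c(0, 0))
  expect_equal(normalizedRadii(tr)[1], 1)
  expect_equal(unname(normalizedCenters(tr)[2, ]), c(0.3, 0.4))
  expect_equal(normalizedRadii(tr)[2], 0.5)
  expect_equal(symmetryValue(tr), 0.5)  # 3-4-5 triangle
  expect_error(normalizeTrajectory(data.frame(frame = 0, cx = 1, cy = 1,
                                              radius = 5)), "2 timepoints")
  expect_error(normalizeTrajectory(data.frame(frame = 0:1, cx = 0, cy = 0,
                                              radius = c(0, 1))), "positive")
})

test_that("symmetry value is the endpoint displacement after normalization", {
  conc <- normalizeTrajectory(data.frame(frame = 0:2, cx = 5, cy = 5,
                                         radius = c(8, 4, 2)))
  expect_equal(symmetryValue(conc), 0)
  tr <- simulateRingTrajectory(12, 20, asymmetry = 0.65, jitter = 0)
  traj <- normalizeTrajectory(tr)
  expect_equal(symmetryValue(traj), 0.65)
})

test_that("symmetry value is invariant under rigid motion and uniform scaling", {
  tr <- simulateRingTrajectory(9, 20, asymmetry = 0.45, jitter = 0.4,
                               seed = 2)
  v0 <- symmetryValue(normalizeTrajectory(tr))
  for (theta in c(0.3, 1.2, 2.9)) {
    rot <- tr
    rot$cx <- cos(theta) * tr$cx - sin(theta) * tr$cy + 100
    rot$cy <- sin(theta) * tr$cx + cos(theta) * tr$cy - 55
    expect_equal(symmetryValue(normalizeTrajectory(rot)), v0)
  }
  sc <- tr
  sc$cx <- tr$cx * 4.2; sc$cy <- tr$cy * 4.2; sc$radius <- tr$radius * 4.2
  expect_equal(symmetryValue(normalizeTrajectory(sc)), v0)
})

test_that("round trip: constructed asymmetry is returned to machine precision", {
  for (s in seq(0, 1, by = 0.1)) {
    tr <- simulateRingTrajectory(11, 20, asymmetry = s, jitter = 0)
    expect_equal(symmetryValue(normalizeTrajectory(tr)), s,
                 tolerance = 1e-12)
  }
})

test_that("classification follows the stated cutoffs and boundary convention", {
  expect_equal(classifySymmetry(0.1), "symmetric")
  expect_equal(classifySymmetry(0.4), "asymmetric")
  expect_equal(classifySymmetry(0.7), "highly_asymmetric")
  expect_equal(classifySymmetry(c(0.2, 0.6)), rep("asymmetric", 2))
  expect_error(classifySymmetry(-0.1), "non-negative")
  # piecewise-constant and monotone non-decreasing in severity
  ranks <- match(classifySymmetry(seq(0, 1, by = 0.01)),
                 c("symmetric", "asymmetric", "highly_asymmetric"))
  expect_true(all(diff(ranks) >= 0))
})

test_that("class summaries report counts and one-decimal percentages", {
  s <- summarizeSymmetryClasses(rep(c("symmetric", "asymmetric",
                                      "highly_asymmetric"), c(1, 13, 7)))
  expect_equal(s$percent, c(4.8, 61.9, 33.3))
  expect_equal(s$count, c(1L, 13L, 7L))

  all1 <- summarizeSymmetryClasses(rep("symmetric", 4))
  expect_equal(all1$percent, c(100, 0, 0))

  set.seed(3)
  u <- summarizeSymmetryClasses(stats::runif(1000))
  expect_equal(u$percent / 100, c(0.2, 0.4, 0.4), tolerance = 0.2)
  expect_error(summarizeSymmetryClasses(character()), "no symmetry")
})

test_that("end-on reslicing turns the Z axis into an isotropic in-plane axis", {
  # thin-shell isotropic sphere: the end-on section through the equator is
  # a circle at the ground-truth ring radius
  p <- SimParams(imageShape = c(48L, 48L), nSlices = 41L, nFrames = 1L,
                 pixelSizeUm = 0.25, zStepUm = 0.25, cellRadiusUm = 4,
                 cortexThicknessUm = 0.4, equatorialEnrichmentFold = 1,
                 noiseModel = "none", bleachRatePerFrame = 0,
                 backgroundLevel = 0, ingressionStartFrame = 99L)
  sim <- simulateDivisionMovie(p)
  es <- resliceEndOn(sim$movie, roi = c(21L, 0L, 6L, 48L), axis = "YZ")
  img <- movieData(es)[1, , ]
  bright <- which(img >= max(img) / 2, arr.ind = TRUE)
  cen <- colMeans(bright)
  rad <- mean(sqrt((bright[, 1] - cen[1])^2 + (bright[, 2] - cen[2])^2))
  expect_lte(abs(rad - sim$truth@perFrameRingRadius[1]), 1)

  single <- Movie(array(1, dim = c(1, 1, 8, 8)), pixelSizeUm = 1)
  expect_error(resliceEndOn(single), "single-slice")

  uni <- Movie(array(3, dim = c(1, 4, 20, 20)), pixelSizeUm = 1, zStepUm = 2)
  out <- movieData(resliceEndOn(uni, roi = c(0L, 0L, 20L, 20L)))
  expect_equal(unique(as.vector(out)), 3)
  expect_equal(dim(out)[2], 7L)  # (4 - 1) * 2 + 1 isotropic rows
})
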