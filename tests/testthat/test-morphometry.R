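flatMap <- function(pu, pb, d = c(16L, 16L), valid = NULL) {
  if (is.null(valid)) valid <- matrix(TRUE, d[1], d[2])
  InterfaceMap(puGrid = matrix(pu, d[1], d[2]),
               pbGrid = matrix(pb, d[1], d[2]), validMask = valid)
}

test_that("per-pixel thickness converts optical path to physical depth", {
  g <- AcquisitionGeometry(axialPitch = 3.5, refractiveIndex = 1.38,
                           nX = 16, nY = 16, nZ = 64)
  th1 <- thicknessMap(flatMap(100, 101), g)
  expect_equal(meanThickness(th1), 3.5 / 1.38)          # 2.536 um per pixel
  expect_lt(abs(meanThickness(th1) - 2.53), 0.01)
  th40 <- thicknessMap(flatMap(100, 140), g)
  expect_equal(meanThickness(th40), 3.5 * 40 / 1.38)    # 101.45 um
})

test_that("invalid cells are excluded from thickness statistics", {
  g <- smallGeom(nX = 4L, nY = 4L, nZ = 64L)
  valid <- matrix(TRUE, 4, 4); valid[1, 1] <- FALSE
  pu <- matrix(10, 4, 4); pb <- matrix(50, 4, 4)
  pu[1, 1] <- NA; pb[1, 1] <- NA
  th <- thicknessMap(InterfaceMap(pu, pb, valid), g)
  expect_true(is.na(thicknessGrid(th)[1, 1]))
  expect_equal(sum(validMask(th)), 15L)
  ifmNone <- InterfaceMap(matrix(NA_real_, 2, 2), matrix(NA_real_, 2, 2),
                          matrix(FALSE, 2, 2))
  expect_error(thicknessMap(ifmNone, g), "no valid cells")
})

test_that("surface heights are air-scaled, up-positive, with physical lateral coords", {
  g <- AcquisitionGeometry(axialPitch = 3.5, nX = 8, nY = 8, nZ = 64)
  sh <- surfaceHeights(flatMap(100, 140, c(8L, 8L)), g)
  expect_true(all(heights(sh) == heights(sh)[1, 1]))     # flat in, flat out
  pu <- matrix(rep(100:107, 8), 8, 8)                    # +1 px per column (x)
  ifm <- InterfaceMap(pu, pu + 40, matrix(TRUE, 8, 8))
  z <- heights(surfaceHeights(ifm, g))
  expect_equal(unique(diff(z[, 1])), -3.5)               # slope delta per column
})

test_that("detected heights reproduce the generated surface within half a pixel", {
  g <- smallGeom(nX = 32L, nY = 32L)
  up <- makeSkinSurface(21, 36, 2.5, 0.5, c(0, 0), c(32, 32), 9)
  ph <- renderTwoLayer(up, g, gapPx = 50L, model = SignalModel(seed = 4))
  ifm <- detectMap(ph$volume, fullFieldROI(g), DetectionParams(t1 = 10))
  v <- validMask(ifm)
  got <- -(upperIndex(ifm)[v] - 1) * axialPitch(g)
  want <- -ph$truth@upperDepthUm[v]
  expect_lte(max(abs(got - want)), axialPitch(g) / 2 + 1e-9)
})

test_that("an exact cubic surface is interpolated with vanishing residuals", {
  g <- smallGeom(nX = 24L, nY = 24L, nZ = 64L)
  x <- (0:23) * 9; y <- (0:23) * 9
  z <- outer(x, y, function(x, y)
    5 + 1e-2 * x - 2e-2 * y + 1e-5 * x * y + 2e-7 * x^3 - 1e-7 * x * y^2)
  sh <- fitReferenceSurface(heightsFromGrid(z, g))
  expect_lt(max(abs(residuals(sh)), na.rm = TRUE), 1e-6)
})

test_that("adding a constant height offset leaves the residuals unchanged", {
  g <- smallGeom(nX = 16L, nY = 16L, nZ = 64L)
  set.seed(31)
  z <- matrix(rnorm(256), 16, 16)
  r1 <- residuals(fitReferenceSurface(heightsFromGrid(z, g)))
  r2 <- residuals(fitReferenceSurface(heightsFromGrid(z + 50, g)))
  expect_equal(r1, r2, tolerance = 1e-9)
})

test_that("tilt removal recovers the roughness of the underlying noise field", {
  g <- smallGeom(nX = 32L, nY = 32L, nZ = 64L)
  set.seed(17)
  noise <- matrix(rnorm(1024, sd = 1.5), 32, 32)
  x <- (0:31) * 9
  plane <- outer(2e-2 * x, rep(1, 32)) + outer(rep(1, 32), 3e-2 * x)
  sh <- fitReferenceSurface(heightsFromGrid(noise + plane, g))
  roi <- fullFieldROI(g)
  raFit <- Ra(roughness(sh, roi, flatten = TRUE))
  d <- dim(noise)
  mask <- outer((seq_len(d[1]) - roi@center[1])^2,
                (seq_len(d[2]) - roi@center[2])^2, "+") < roi@radius^2
  raOracle <- directRoughness(noise, mask)$ra
  expect_lt(abs(raFit - raOracle) / raOracle, 0.01)
})

test_that("a rank-deficient design degrades with a warning instead of failing", {
  g <- smallGeom(nX = 16L, nY = 16L, nZ = 64L)
  valid <- matrix(FALSE, 16, 16); valid[, 3] <- TRUE   # collinear points
  z <- matrix(NA_real_, 16, 16); z[, 3] <- rnorm(16)
  expect_warning(sh <- fitReferenceSurface(heightsFromGrid(z, g, valid)),
                 "rank-deficient")
  expect_equal(sum(!is.na(residuals(sh))), 16L)
})

test_that("fewer than ten points cannot support the cubic fit", {
  g <- smallGeom(nX = 3L, nY = 3L, nZ = 64L)
  z <- matrix(1:9 + 0, 3, 3)
  expect_error(fitReferenceSurface(heightsFromGrid(z, g)), "at least 10")
})

test_that("constant heights give zero roughness and undefined skewness", {
  g <- smallGeom(nX = 16L, nY = 16L, nZ = 64L)
  sh <- heightsFromGrid(matrix(5, 16, 16), g)
  rr <- roughness(sh, fullFieldROI(g), flatten = FALSE)
  expect_equal(Ra(rr), 0)
  expect_equal(Rq(rr), 0)
  expect_true(is.na(Rsk(rr)))
  expect_false(rr@rskDefined)
})

test_that("a symmetric two-level surface has Ra = Rq = 1 and zero skewness", {
  g <- smallGeom(nX = 16L, nY = 16L, nZ = 64L)
  z <- matrix(rep(c(1, -1), 128), 16, 16)
  rr <- roughness(heightsFromGrid(z, g), fullFieldROI(g), flatten = FALSE)
  expect_equal(Ra(rr), 1)
  expect_equal(Rq(rr), 1)
  expect_equal(Rsk(rr), 0)
})

test_that("a dense triangular groove with 4 um peak-to-valley has Ra = 1", {
  g <- AcquisitionGeometry(nX = 200, nY = 200, nZ = 64, lateralPitchX = 1,
                           lateralPitchY = 1)
  z <- makePlateSurface("triangle", 1, 8, c(200, 200), 1)
  expect_equal(max(z) - min(z), 4)
  roi <- ROISpec(1, 64, 1, 200, 1, 200, center = c(100.5, 100.5), radius = 95)
  rr <- roughness(heightsFromGrid(z, g), roi, flatten = FALSE)
  expect_lt(abs(Ra(rr) - 1), 0.005)
  d <- dim(z)
  mask <- outer((seq_len(d[1]) - roi@center[1])^2,
                (seq_len(d[2]) - roi@center[2])^2, "+") < roi@radius^2
  oracle <- directRoughness(z, mask)
  expect_lt(abs(Ra(rr) - oracle$ra) / oracle$ra, 0.005)
})

test_that("roughness matches the direct-summation oracle to 1e-9 on random surfaces", {
  g <- smallGeom(nX = 20L, nY = 20L, nZ = 64L)
  roi <- fullFieldROI(g)
  d <- c(20L, 20L)
  mask <- outer((seq_len(d[1]) - roi@center[1])^2,
                (seq_len(d[2]) - roi@center[2])^2, "+") < roi@radius^2
  set.seed(77)
  for (rep in 1:20) {
    z <- matrix(rnorm(400, sd = runif(1, 0.5, 5)), 20, 20)
    rr <- roughness(heightsFromGrid(z, g), roi, flatten = FALSE)
    oracle <- directRoughness(z, mask)
    expect_equal(Ra(rr), oracle$ra, tolerance = 1e-9)
    expect_equal(Rq(rr), oracle$rq, tolerance = 1e-9)
    expect_equal(Rsk(rr), oracle$rsk, tolerance = 1e-9)
    expect_equal(rr@pn, oracle$pn)
  }
})

test_that("roughness obeys the Jensen, sign-flip and scaling laws", {
  g <- smallGeom(nX = 20L, nY = 20L, nZ = 64L)
  roi <- fullFieldROI(g)
  set.seed(55)
  for (rep in 1:10) {
    z <- matrix(rexp(400) - rnorm(400)^2, 20, 20)
    rr <- roughness(heightsFromGrid(z, g), roi, flatten = FALSE)
    expect_lte(Ra(rr), Rq(rr) + 1e-12)
    neg <- roughness(heightsFromGrid(-z, g), roi, flatten = FALSE)
    expect_equal(Ra(neg), Ra(rr)); expect_equal(Rq(neg), Rq(rr))
    expect_equal(Rsk(neg), -Rsk(rr))
    c3 <- roughness(heightsFromGrid(3 * z, g), roi, flatten = FALSE)
    expect_equal(Ra(c3), 3 * Ra(rr)); expect_equal(Rq(c3), 3 * Rq(rr))
    expect_equal(Rsk(c3), Rsk(rr), tolerance = 1e-9)
  }
})

test_that("flattened roughness is invariant under adding any cubic trend", {
  g <- smallGeom(nX = 24L, nY = 24L, nZ = 64L)
  roi <- fullFieldROI(g)
  set.seed(88)
  z <- matrix(rnorm(576, sd = 2), 24, 24)
  base <- roughness(fitReferenceSurface(heightsFromGrid(z, g)), roi)
  x <- (0:23) * 9
  cubic <- outer(x, x, function(x, y)
    10 - 0.05 * x + 0.02 * y + 1e-4 * x^2 - 2e-5 * x * y + 3e-7 * y^3 + 1e-7 * x^2 * y)
  trended <- roughness(fitReferenceSurface(heightsFromGrid(z + cubic, g)), roi)
  expect_equal(Ra(trended), Ra(base), tolerance = 1e-6)
  expect_equal(Rq(trended), Rq(base), tolerance = 1e-6)
  expect_equal(Rsk(trended), Rsk(base), tolerance = 1e-6)
})

test_that("verification statistics reproduce the plate-comparison summary", {
  nominal <- c(1, 1.6, 3.2, 5.8)
  algorithm <- c(1.35, 1.92, 3.14, 5.16)
  imageBased <- c(1.05, 1.03, 1.22, 1.78)
  vs <- verificationStats(nominal, algorithm)
  expect_equal(vs$maxDeviation, 0.64)             # at the 5.8 um plate
  expect_equal(vs$relativeErrorAtMax, 100 * 0.64 / 5.8)  # ~11.0%
  expect_equal(vs$olsSlope, unname(coef(lm(algorithm ~ nominal))[2]))
  expect_equal(vs$olsSlope, 0.7859, tolerance = 1e-4)
  vsImg <- verificationStats(nominal, imageBased)
  expect_equal(vsImg$olsSlope, 0.1590, tolerance = 1e-4)
  ident <- verificationStats(nominal, nominal)
  expect_equal(ident$maxDeviation, 0)
  expect_equal(ident$relativeErrorAtMax, 0)
  expect_equal(ident$olsSlope, 1)
  expect_error(verificationStats(1:3, 1:4), "equal length")
})
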