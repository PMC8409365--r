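test_that("findPeaks returns strict local maxima with plateau-first indices", {
  expect_identical(findPeaks(c(0, 1, 0, 2, 2, 1, 0)), c(2L, 4L))
  expect_identical(findPeaks(rep(5, 10)), integer())   # constant: no peaks
  expect_identical(findPeaks(c(1, 2, 3, 4)), integer())  # monotone: no peaks
  expect_identical(findPeaks(c(0, 3, 0, 3, 0)), c(2L, 4L))
})

test_that("coarse detection pairs the two isolated interface peaks", {
  a <- numeric(200); a[100] <- 1000; a[140] <- 800
  pr <- coarseDetect(a, c(1, 200), t1 = 10)
  expect_true(pr$valid)
  expect_equal(pr$pu, 100)
  expect_equal(pr$pb, 140)
})

test_that("coarse detection skips candidates closer than the separation threshold", {
  a <- numeric(200); a[100] <- 1000; a[106] <- 950; a[150] <- 700
  pr <- coarseDetect(a, c(1, 200), t1 = 10)
  expect_equal(c(pr$pu, pr$pb), c(100, 150))  # 106 rejected: separation 6 < 10
})

test_that("degenerate signals yield an invalid pair, not an error", {
  expect_false(coarseDetect(numeric(100), c(1, 100), t1 = 10)$valid)
  expect_false(coarseDetect(rep(7, 100), c(1, 100), t1 = 10)$valid)
  a <- numeric(100); a[50] <- 10  # single peak: no partner
  expect_false(coarseDetect(a, c(1, 100), t1 = 10)$valid)
})

test_that("coarse detection matches the brute-force enumeration oracle", {
  set.seed(42)
  for (rep in 1:200) {
    n <- sample(40:120, 1)
    # mix of smooth continuous noise and quantised signals (ties, plateaus)
    a <- if (rep %% 2) runif(n) else round(runif(n) * 10)
    t1 <- sample(2:15, 1)
    got <- coarseDetect(a, c(1, n), t1)
    want <- bruteCoarse(a, c(1, n), t1)
    expect_identical(got$valid, want$valid)
    if (want$valid) {
      expect_equal(got$pu, want$pu)
      expect_equal(got$pb, want$pb)
    }
  }
})

test_that("coarse detection is deterministic", {
  set.seed(9)
  a <- runif(80)
  expect_identical(coarseDetect(a, c(1, 80), 5), coarseDetect(a, c(1, 80), 5))
})

test_that("fine refinement is idempotent when the coarse peak is the only candidate", {
  a <- numeric(200); a[100] <- 1000; a[160] <- 800
  pr <- coarseDetect(a, c(1, 200), t1 = 10)
  fr <- fineRefine(a, pr, c(1, 200), t2Fraction = 0.2)
  expect_equal(c(fr$pu, fr$pb), c(100, 160))
})

test_that("fine refinement moves the upper index to a shallower qualifying maximum", {
  a <- numeric(200); a[90] <- 850; a[100] <- 1000; a[150] <- 700; a[160] <- 900
  pr <- list(pu = 100, pb = 160, valid = TRUE)
  fr <- fineRefine(a, pr, c(1, 200), t2Fraction = 0.2)
  expect_equal(fr$pu, 90)   # 850 >= 0.8 * 1000, shallower wins
})

test_that("fine refinement rejects shallower maxima below the intensity tolerance", {
  a <- numeric(200); a[90] <- 700; a[100] <- 1000; a[160] <- 900
  pr <- list(pu = 100, pb = 160, valid = TRUE)
  fr <- fineRefine(a, pr, c(1, 200), t2Fraction = 0.2)
  expect_equal(fr$pu, 100)  # 700 < 800: stays
})

test_that("fine refinement never deepens either index and preserves invariants", {
  set.seed(101)
  for (rep in 1:100) {
    n <- 120
    a <- round(runif(n) * 100)
    t1 <- sample(3:12, 1)
    pr <- coarseDetect(a, c(1, n), t1)
    if (!pr$valid) next
    fr <- fineRefine(a, pr, c(1, n), t2Fraction = 0.2, t1 = t1)
    if (fr$valid) {
      expect_lte(fr$pu, pr$pu)
      expect_lte(fr$pb, pr$pb)
      expect_true(1 <= fr$pu && fr$pu < fr$pb && fr$pb <= n)
      expect_gte(fr$pb - fr$pu, t1)
    }
  }
})

test_that("lateral margins are recovered from the edge drop of a disc sample", {
  nX <- 1000L; nY <- 1000L
  g <- AcquisitionGeometry(nX = nX, nY = nY, nZ = 4L)
  ctr <- c((nX + 1) / 2, (nY + 1) / 2)
  rpx <- 2500 / 9                       # 2.5 mm disc at 9 um pitch
  disc <- outer((seq_len(nX) - ctr[1])^2,
                (seq_len(nY) - ctr[2])^2, "+") < rpx^2
  arr <- array(0, dim = c(nX, nY, 4L))
  arr[, , 2] <- disc * 1000
  roi <- determineROI(OCTVolume(arr, g), c(1, 4), circleRadiusMm = 1)
  expect_lte(abs(roi@rbLx - (ctr[1] - rpx)), 2)
  expect_lte(abs(roi@rbRx - (ctr[1] + rpx)), 2)
  expect_lte(abs(roi@rbLy - (ctr[2] - rpx)), 2)
  expect_lte(abs(roi@rbRy - (ctr[2] + rpx)), 2)
})

test_that("a full-field sample yields full-extent margins and converted circle radius", {
  g <- smallGeom(nZ = 16L)
  arr <- array(0, dim = c(64, 64, 16))
  arr[, , 8] <- 1000
  roi <- determineROI(OCTVolume(arr, g), c(1, 16), circleRadiusMm = 0.2)
  expect_equal(c(roi@rbLx, roi@rbRx), c(1L, 64L))
  expect_equal(c(roi@rbLy, roi@rbRy), c(1L, 64L))
  expect_equal(roi@radius, round(200 / 9))   # unit conversion, px
})

test_that("an empty window raises a detection error naming the failure", {
  g <- smallGeom(nX = 16L, nY = 16L, nZ = 16L)
  arr <- array(0, dim = c(16, 16, 16))
  expect_error(determineROI(OCTVolume(arr, g), c(1, 16)), "no sample found")
})

test_that("a noise-free two-layer phantom is recovered exactly at every valid cell", {
  g <- smallGeom(nX = 32L, nY = 32L)
  up <- makePlateSurface("sine", 3, 180, c(32, 32), 9)
  ph <- renderTwoLayer(up, g, gapPx = 40L, model = SignalModel(seed = 3))
  roi <- fullFieldROI(g)
  ifm <- detectMap(ph$volume, roi, DetectionParams(t1 = 10))
  v <- validMask(ifm)
  expect_gt(sum(v), 0)
  expect_equal(upperIndex(ifm)[v], upperIndex(ph$truth)[v] + 0)
  expect_equal(lowerIndex(ifm)[v], lowerIndex(ph$truth)[v] + 0)
})

test_that("an all-zero volume yields an all-invalid map without crashing", {
  g <- smallGeom(nX = 16L, nY = 16L, nZ = 32L)
  vol <- OCTVolume(array(0, dim = c(16, 16, 32)), g)
  roi <- fullFieldROI(g)
  expect_warning(
    ifm <- suppressMessages(extractSurfaces(vol, roi, DetectionParams())),
    "fewer than half")
  expect_false(any(validMask(ifm)))
})

test_that("surface RMSE stays below one pixel under speckle and is monotone in noise", {
  g <- smallGeom(nX = 32L, nY = 32L)
  up <- makeSkinSurface(5, 36, 2, 0, c(0, 0), c(32, 32), 9)
  roi <- fullFieldROI(g)
  rmse <- sapply(c(1e-3, 200, 500, 1000), function(noise) {
    m <- SignalModel(noiseSigma = noise, spuriousProb = 0.05,
                     spuriousAmp = 5000, seed = 11)
    ph <- renderTwoLayer(up, g, gapPx = 40L, model = m)
    ifm <- detectMap(ph$volume, roi, DetectionParams(t1 = 10))
    v <- validMask(ifm)
    sqrt(mean((upperIndex(ifm)[v] - upperIndex(ph$truth)[v])^2))
  })
  # peak-SNR 10 corresponds to noise sigma 1000 at amplitude 10000
  expect_lte(rmse[4], 1)
  expect_true(all(diff(rmse) >= 0))
})
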