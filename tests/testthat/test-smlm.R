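test_that("blank frames yield no localizations; non-2D input errors", {
  frames <- array(0, dim = c(16L, 16L, 4L))
  expect_equal(nrow(fitEvents(frames)), 0L)
  expect_error(fitEvents(array(0, dim = c(4L, 4L, 4L, 4L))), "schema")
})

test_that("Gaussian fitting localizes emitters near the CRLB scale", {
  # ~1000-photon events at sigma_psf = 1.3 px, 200+ Monte-Carlo repeats:
  # per-axis RMS error must stay below twice the photon-limited bound
  # sigma_psf * px / sqrt(N)
  err2 <- numeric(0)
  uncs <- numeric(0)
  sigmaPsf <- 1.3
  for (r in 1:60) {
    cfg <- smlmSimConfig(nFrames = 12L, frameDimPx = c(24L, 24L),
                         nClusters = 1L, clusterRadiusNm = 1,
                         emittersPerCluster = 1L, meanStreakLen = 8,
                         sigmaLocNm = 0, driftNmPerFrame = c(0, 0),
                         nFiducials = 0L, photonBudget = 1000,
                         psfSigmaPx = sigmaPsf, bgPhotons = 1,
                         seed = 600L + r)
    sim <- simulateSmlm(cfg, renderFrames = TRUE)
    fits <- fitEvents(sim$frames, rawPixelNm = cfg$rawPixelNm,
                      psfSigmaPx = sigmaPsf)
    if (nrow(fits) == 0L) next
    err2 <- c(err2, (fits$x - sim$truth$emitters$x[1])^2 +
                (fits$y - sim$truth$emitters$y[1])^2)
    uncs <- c(uncs, fits$uncertainty)
  }
  expect_gt(length(err2), 200L)
  rms <- sqrt(mean(err2) / 2)  # per axis
  bound <- 2 * sigmaPsf * 144 / sqrt(1000)
  expect_lt(rms, bound)
  # reported uncertainties are on the photon-statistics scale
  expect_true(all(uncs > 1 & uncs < 3 * bound))
})

test_that("two well-separated emitters give two matched localizations", {
  set.seed(9)
  fr <- matrix(2, 32L, 32L)
  s <- 1.3
  for (p in list(c(10, 12), c(20, 22))) {  # (row, col), 10 px apart
    gx <- exp(-((1:32 - 0.5) - (p[2] - 0.5))^2 / (2 * s^2))
    gy <- exp(-((1:32 - 0.5) - (p[1] - 0.5))^2 / (2 * s^2))
    fr <- fr + 1500 / (2 * pi * s^2) * outer(gy, gx)
  }
  fr[] <- rpois(length(fr), fr)
  fits <- fitEvents(fr, rawPixelNm = 100, psfSigmaPx = s)
  expect_equal(nrow(fits), 2L)
  fits <- fits[order(fits$x), ]
  expect_lt(abs(fits$x[1] - (12 - 0.5) * 100), 100)
  expect_lt(abs(fits$y[1] - (10 - 0.5) * 100), 100)
  expect_lt(abs(fits$x[2] - (22 - 0.5) * 100), 100)
})

test_that("zero injected drift leaves positions essentially unchanged", {
  cfg <- smlmSimConfig(nFrames = 400L, driftNmPerFrame = c(0, 0), seed = 4L)
  sim <- simulateSmlm(cfg)
  dc <- correctDrift(sim$locs)
  shift <- sqrt((dc$locs$x - sim$locs$x)^2 + (dc$locs$y - sim$locs$y)^2)
  expect_lt(max(shift), cfg$sigmaLocNm)  # smoothing noise only
  expect_equal(dc$drift$dx[1], 0)
  expect_equal(dc$drift$dy[1], 0)
})

test_that("linear drift is recovered within 2 nm RMS and corrected", {
  cfg <- smlmSimConfig(nFrames = 2000L, driftNmPerFrame = c(0.5, 0),
                       seed = 5L)
  sim <- simulateSmlm(cfg)
  dc <- correctDrift(sim$locs)
  tr <- sim$truth$drift
  rms <- sqrt(mean((dc$drift$dx - tr$dx)^2 + (dc$drift$dy - tr$dy)^2))
  expect_lt(rms, 2)
  # corrected emitter scatter returns to the localization noise scale
  em <- expectNoFiducials(dc$locs)
  em$res <- sqrt((em$x - sim$truth$emitters$x[em$emitterId])^2 +
                   (em$y - sim$truth$emitters$y[em$emitterId])^2)
  expect_lt(sqrt(mean(em$res^2) / 2), 1.3 * cfg$sigmaLocNm)
  # correcting twice: the second pass finds ~zero drift
  dc2 <- correctDrift(dc$locs)
  expect_lt(max(abs(dc2$drift$dx)), 2)
  expect_lt(max(abs(dc2$drift$dy)), 2)
  # count conservation
  expect_equal(nrow(dc$locs), nrow(sim$locs))
})

test_that("merging collapses chains with inverse-variance statistics", {
  one <- data.frame(frame = 0L, x = 10, y = 20, uncertainty = 5,
                    sigma = 150, photons = 100, fiducial = FALSE)
  expect_equal(nrow(mergeConsecutive(one)), 1L)

  chain <- data.frame(frame = c(3L, 4L, 5L), x = 100, y = 200,
                      uncertainty = 12, sigma = 150, photons = c(50, 60, 70),
                      fiducial = FALSE)
  m <- mergeConsecutive(chain, radiusNm = 50)
  expect_equal(nrow(m), 1L)
  expect_equal(m$photons, 180)
  expect_equal(m$uncertainty, 12 / sqrt(3))
  expect_equal(m$mergedN, 3L)
  expect_equal(m$frame, 3L)

  far <- data.frame(frame = c(0L, 1L), x = c(0, 500), y = 0,
                    uncertainty = 10, sigma = 150, photons = 1,
                    fiducial = FALSE)
  expect_equal(nrow(mergeConsecutive(far, radiusNm = 50)), 2L)
  expect_error(mergeConsecutive(far, radiusNm = -1), "radius")
})

test_that("merging respects the dark-frame gap and never adds records", {
  gap <- data.frame(frame = c(0L, 2L), x = 1, y = 1, uncertainty = 10,
                    sigma = 150, photons = 1, fiducial = FALSE)
  expect_equal(nrow(mergeConsecutive(gap, radiusNm = 50, maxGapFrames = 1L)),
               1L)
  expect_equal(nrow(mergeConsecutive(gap, radiusNm = 50, maxGapFrames = 0L)),
               2L)
  set.seed(31)
  rnd <- data.frame(frame = sample(0:20, 60, TRUE),
                    x = runif(60, 0, 2000), y = runif(60, 0, 2000),
                    uncertainty = 15, sigma = 150, photons = 1,
                    fiducial = FALSE)
  expect_lte(nrow(mergeConsecutive(rnd)), nrow(rnd))
})

test_that("rendering adds unit-amplitude Gaussians on the fine canvas", {
  empty <- renderSuperRes(emptyLocs <- data.frame(
    frame = integer(0), x = numeric(0), y = numeric(0),
    uncertainty = numeric(0)), frameDimPx = c(8L, 8L))
  expect_true(all(canvasData(empty) == 0))
  expect_equal(pixelSizeNm(empty), 14.4)

  # position on an exact canvas pixel centre: unit amplitudes add to 2
  at <- (35 - 0.5) * 14.4
  two <- data.frame(frame = 0L, x = c(at, at), y = c(at, at),
                    uncertainty = 20)
  img <- renderSuperRes(two, frameDimPx = c(8L, 8L))
  expect_equal(max(canvasData(img)), 2.0, tolerance = 1e-6)

  one <- data.frame(frame = 0L, x = 600, y = 600, uncertainty = 20)
  img1 <- renderSuperRes(one, frameDimPx = c(8L, 8L))
  expect_equal(sum(canvasData(img1)), 2 * pi * (20 / 14.4)^2,
               tolerance = 0.01)
})

test_that("cluster area matches the worked 3x3 example and its bounds", {
  m <- matrix(0, 3, 3)
  m[1, 1] <- 1.0; m[1, 2] <- 0.6; m[2, 1] <- 0.4
  img <- SuperResImage(m, pixelSizeNm = 14.4)
  roi <- c(0, 3 * 14.4, 0, 3 * 14.4)
  a <- clusterArea(img, roi, 0.5)
  expect_equal(a$pixelCount, 2L)
  expect_equal(a$areaUm2, 2 * 0.0144^2, tolerance = 1e-9)  # 4.147e-4

  expect_equal(clusterArea(img, roi, 1.0)$pixelCount, 1L)
  # scale invariance through max-normalization
  img2 <- SuperResImage(m * 37.5, pixelSizeNm = 14.4)
  expect_equal(clusterArea(img2, roi, 0.5)$areaUm2, a$areaUm2)
  expect_error(clusterArea(img, roi, 0), "threshold")
  dark <- SuperResImage(matrix(0, 3, 3), pixelSizeNm = 14.4)
  expect_error(clusterArea(dark, roi, 0.5), "undefined area")
})

test_that("cluster area is monotone non-increasing in the threshold", {
  set.seed(77)
  for (i in 1:25) {
    m <- matrix(runif(400), 20, 20)
    img <- SuperResImage(m, pixelSizeNm = 10)
    roi <- c(0, 200, 0, 200)
    ts <- seq(0.05, 1, by = 0.05)
    areas <- vapply(ts, function(t) clusterArea(img, roi, t)$areaUm2, 0)
    expect_true(all(diff(areas) <= 1e-12))
  }
})

test_that("camera geometry helper reproduces the object-plane pixel", {
  expect_equal(objectPixelSizeNm(16, 111), 16000 / 111)
  expect_equal(round(objectPixelSizeNm(16, 111)), 144)
})
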