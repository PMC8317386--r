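test_that("volume measurement is exact arithmetic", {
  expect_equal(measureVolume(1000, c(0.23, 0.1, 0.1)), 2.3)
  expect_equal(measureVolume(0, c(0.23, 0.1, 0.1)), 0)
  expect_equal(measureVolume(1, c(1, 1, 1)), 1)
  expect_error(measureVolume(-1, c(1, 1, 1)), "voxelCount")
})

test_that("a blank stack yields zero nuclei with a warning", {
  g <- VoxelGrid(array(5, dim = c(8L, 24L, 24L)), channelNames = "dna")
  expect_warning(seg <- segmentNuclei(g), "no nuclei")
  expect_equal(nrow(seg$records), 0L)
  expect_true(all(seg$labels == 0L))

  set.seed(1)
  gn <- VoxelGrid(array(abs(rnorm(8 * 24 * 24, 5, 1)), dim = c(8L, 24L, 24L)),
                  channelNames = "dna")
  expect_warning(segN <- segmentNuclei(gn), "no")
  expect_equal(nrow(segN$records), 0L)
})

test_that("a noise-free ellipsoid recovers its analytic volume", {
  cfg <- stackSimConfig(dim = c(30L, 72L, 72L), nNuclei = 1L,
                        semiAxesUm = rbind(c(2.0, 2.0), c(1.4, 1.4),
                                           c(1.4, 1.4)),
                        fociPerNucleus = 0L, poissonGain = 0,
                        readNoiseSd = 0, textureAmplitude = 0, seed = 21L)
  sim <- simulateIfStack(cfg)
  seg <- segmentNuclei(sim$grid)
  expect_equal(nrow(seg$records), 1L)
  vTrue <- 4 / 3 * pi * 2.0 * 1.4 * 1.4   # 16.42 um^3
  expect_lt(abs(seg$records$volumeUm3 - vTrue) / vTrue, 0.10)
  # record invariant: volume = voxel count x voxel volume
  expect_equal(seg$records$volumeUm3,
               measureVolume(seg$records$voxelCount, voxelSize(sim$grid)))
})

test_that("two separated nuclei give two truth-matched labels", {
  cfg <- stackSimConfig(dim = c(26L, 128L, 128L), nNuclei = 2L,
                        fociPerNucleus = 0L, seed = 8L)
  sim <- simulateIfStack(cfg)
  seg <- segmentNuclei(sim$grid)
  expect_equal(nrow(seg$records), 2L)
  expect_setequal(unique(as.integer(seg$labels[seg$labels > 0L])), 1:2)
  # match each truth centre to a segmented object via the label map
  vs <- voxelSize(sim$grid)
  for (i in 1:2) {
    vox <- pmax(1L, round(c(sim$truth$nuclei$zUm[i] / vs[1],
                            sim$truth$nuclei$yUm[i] / vs[2],
                            sim$truth$nuclei$xUm[i] / vs[3])))
    expect_gt(seg$labels[vox[1], vox[2], vox[3]], 0L)
  }
  atTruth <- seg$labels[cbind(
    pmax(1L, round(sim$truth$nuclei$zUm / vs[1])),
    pmax(1L, round(sim$truth$nuclei$yUm / vs[2])),
    pmax(1L, round(sim$truth$nuclei$xUm / vs[3])))]
  expect_setequal(as.integer(atTruth), 1:2)
})

test_that("foci are recovered per nucleus with accurate centroids", {
  cfg <- stackSimConfig(dim = c(26L, 128L, 128L), nNuclei = 2L,
                        fociPerNucleus = 4L, poissonGain = 0,
                        readNoiseSd = 0, textureAmplitude = 0, seed = 12L)
  sim <- simulateIfStack(cfg)
  seg <- segmentNuclei(sim$grid)
  foci <- segmentFoci(sim$grid, "marker1", seg)
  expect_equal(nrow(foci$records), 8L)
  expect_equal(as.integer(table(foci$records$nucleus)), c(4L, 4L))
  # each truth focus has a segmented centroid within one voxel
  vs <- voxelSize(sim$grid)
  for (i in seq_len(nrow(sim$truth$foci))) {
    dz <- abs(foci$records$centroid_z - sim$truth$foci$zUm[i]) / vs[1]
    dy <- abs(foci$records$centroid_y - sim$truth$foci$yUm[i]) / vs[2]
    dx <- abs(foci$records$centroid_x - sim$truth$foci$xUm[i]) / vs[3]
    expect_true(any(dz < 1 & dy < 1 & dx < 1))
  }
})

test_that("touching blobs 2.5 sigma apart are split by the watershed", {
  d <- c(16L, 48L, 48L)
  vs <- c(0.23, 0.1, 0.1)
  arr <- array(50, dim = d)  # uniform nucleus background
  sg <- 0.2
  centres <- list(c(1.84, 2.4, 2.15), c(1.84, 2.4, 2.15 + 2.5 * sg))
  zc <- (seq_len(d[1]) - 0.5) * vs[1]
  yc <- (seq_len(d[2]) - 0.5) * vs[2]
  xc <- (seq_len(d[3]) - 0.5) * vs[3]
  for (p in centres) {
    r2 <- outer(outer((zc - p[1])^2, (yc - p[2])^2, `+`), (xc - p[3])^2, `+`)
    arr <- arr + 250 * exp(-r2 / (2 * sg^2))
  }
  g <- VoxelGrid(arr, voxelSize = vs, channelNames = "marker1")
  nucLab <- array(1L, dim = d)
  foci <- segmentFoci(g, "marker1", nucLab)
  expect_equal(nrow(foci$records), 2L)
})

test_that("a blank focus channel yields zero foci", {
  d <- c(12L, 32L, 32L)
  g <- VoxelGrid(array(rep(c(100, 50), each = prod(d)), dim = c(d, 2L)),
                 channelNames = c("dna", "marker1"))
  nucLab <- array(1L, dim = d)
  foci <- segmentFoci(g, "marker1", nucLab)
  expect_equal(nrow(foci$records), 0L)
  expect_error(segmentFoci(g, "marker9", nucLab), "channel")
})

test_that("segmentation masks are invariant under intensity rescaling", {
  cfg <- tinyStackConfig(seed = 33L)
  sim <- simulateIfStack(cfg)
  seg1 <- segmentNuclei(sim$grid)
  foci1 <- segmentFoci(sim$grid, "marker1", seg1)
  scaled <- VoxelGrid(voxelData(sim$grid) * 7.3, voxelSize(sim$grid),
                      channelNames(sim$grid))
  seg2 <- segmentNuclei(scaled)
  foci2 <- segmentFoci(scaled, "marker1", seg2)
  expect_identical(seg1$labels, seg2$labels)
  expect_identical(foci1$labels, foci2$labels)
})

test_that("label maps satisfy disjointness and containment", {
  cfg <- stackSimConfig(dim = c(26L, 128L, 128L), nNuclei = 2L, seed = 77L)
  sim <- simulateIfStack(cfg)
  seg <- segmentNuclei(sim$grid)
  foci <- segmentFoci(sim$grid, "marker1", seg)
  inFocus <- foci$labels > 0L
  # every focus voxel lies inside its parent nucleus
  expect_true(all(seg$labels[inFocus] > 0L))
  parent <- foci$records$nucleus[foci$labels[inFocus]]
  expect_identical(as.integer(seg$labels[inFocus]), as.integer(parent))
  # per-channel focus signal never exceeds the parent nuclear signal
  for (i in seq_len(nrow(foci$records))) {
    nuc <- seg$records[seg$records$label == foci$records$nucleus[i], ]
    expect_lte(foci$records$signal[i], nuc$signal_marker1)
  }
})
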