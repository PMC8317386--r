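test_that("normalized density reproduces direct arithmetic", {
  foci <- data.frame(nucleus = 1L, channel = "m", volumeUm3 = 2, signal = 8)
  nuc <- data.frame(label = 1L, volumeUm3 = 10, signal_m = 20)
  expect_equal(normalizedDensity(foci, nuc)$density, 2.0)

  # uniform nucleus: any focus subset has density exactly 1
  foci2 <- data.frame(nucleus = 1L, channel = "m",
                      volumeUm3 = c(0.5, 1.5), signal = c(0.5, 1.5) * 7)
  nuc2 <- data.frame(label = 1L, volumeUm3 = 30, signal_m = 30 * 7)
  expect_equal(normalizedDensity(foci2, nuc2)$density, 1.0)

  # zero-signal foci in a bright nucleus
  foci3 <- data.frame(nucleus = 1L, channel = "m", volumeUm3 = 2, signal = 0)
  expect_equal(normalizedDensity(foci3, nuc)$density, 0)

  expect_error(normalizedDensity(
    data.frame(nucleus = 1L, channel = "m", volumeUm3 = 0, signal = 1), nuc),
    "zero focus volume")
})

test_that("density is scale-invariant and pools before the ratio", {
  set.seed(101)
  for (i in 1:1000) {
    k <- sample(2:5, 1)
    vols <- runif(k, 0.1, 2)
    sigs <- runif(k, 1, 50)
    nv <- sum(vols) + runif(1, 5, 40)
    ns <- sum(sigs) + runif(1, 10, 400)
    foci <- data.frame(nucleus = 1L, channel = "m", volumeUm3 = vols,
                       signal = sigs)
    nuc <- data.frame(label = 1L, volumeUm3 = nv, signal_m = ns)
    d <- normalizedDensity(foci, nuc)$density
    # pooled-ratio identity (not the mean of per-focus densities)
    expect_equal(d, (sum(sigs) / sum(vols)) / (ns / nv))
    # global intensity rescaling leaves the density unchanged
    c0 <- runif(1, 0.1, 10)
    fociC <- transform(foci, signal = signal * c0)
    nucC <- transform(nuc, signal_m = signal_m * c0)
    expect_equal(normalizedDensity(fociC, nucC)$density, d)
    if (k > 1) {
      perFocus <- mean((sigs / vols) / (ns / nv))
      if (abs(perFocus - d) > 1e-8)
        expect_false(isTRUE(all.equal(perFocus, d)))
    }
  }
})

test_that("exclusive nuclear reference subtracts the foci pool", {
  foci <- data.frame(nucleus = 1L, channel = "m", volumeUm3 = 2, signal = 8)
  nuc <- data.frame(label = 1L, volumeUm3 = 10, signal_m = 20)
  d <- normalizedDensity(foci, nuc, nucleusSignal = "exclusive")$density
  expect_equal(d, (8 / 2) / ((20 - 8) / (10 - 2)))
})

test_that("spot mean intensity is signal over volume", {
  expect_equal(spotMeanIntensity(data.frame(signal = 46, volumeUm3 = 2.3)),
               20)
  expect_equal(spotMeanIntensity(data.frame(signal = 0, volumeUm3 = 1)), 0)
  expect_equal(spotMeanIntensity(data.frame(signal = 92, volumeUm3 = 4.6)),
               20)  # doubling both leaves the ratio unchanged
  expect_error(spotMeanIntensity(data.frame(signal = 1, volumeUm3 = 0)),
               "zero focus volume")
})

test_that("largest-overlap selection matches the worked example", {
  d <- c(4L, 4L, 4L)
  cand <- array(0L, dim = d)
  ref <- 1:8
  cand[1:2] <- 1L   # overlaps 2 voxels
  cand[9] <- 2L     # overlaps 1 voxel (index 9 not in ref? it is not)
  cand[8] <- 2L     # make candidate 2 overlap 1 voxel of ref
  res <- overlapFraction(ref, cand)
  expect_equal(res$partner, 1L)
  expect_equal(res$overlapPercent, 25)  # 2/8

  # identical candidate: 100 %
  cand2 <- array(0L, dim = d); cand2[ref] <- 3L
  expect_equal(overlapFraction(ref, cand2)$overlapPercent, 100)

  # disjoint candidate: no partner
  cand3 <- array(0L, dim = d); cand3[20:25] <- 1L
  res3 <- overlapFraction(ref, cand3)
  expect_true(is.na(res3$partner))
  expect_equal(res3$overlapPercent, 0)

  expect_error(overlapFraction(integer(0), cand), "empty reference")
})

test_that("overlap agrees with a brute-force set-intersection oracle", {
  set.seed(202)
  d <- c(5L, 6L, 6L)
  for (i in 1:200) {
    ref <- sample(prod(d), sample(3:20, 1))
    cand <- array(0L, dim = d)
    for (l in 1:3) cand[sample(prod(d), sample(0:30, 1))] <- l
    got <- overlapFraction(ref, cand)
    oracle <- overlapOracle(ref, cand)
    expect_equal(got$overlapPercent, oracle$percent)
    if (oracle$percent > 0) {
      # partner must achieve the oracle maximum (ties: lowest label)
      nGot <- sum(cand[ref] == got$partner)
      expect_equal(100 * nGot / length(ref), oracle$percent)
    }
  }
})

test_that("overlap ties break toward the lowest candidate label", {
  d <- c(3L, 3L, 3L)
  cand <- array(0L, dim = d)
  cand[1] <- 5L
  cand[2] <- 2L   # both overlap exactly 1 voxel of ref
  res <- overlapFraction(1:4, cand)
  expect_equal(res$partner, 2L)
})

test_that("rank-sum test matches its exact worked example and symmetry", {
  r <- rankSumTest(c(1, 2, 3), c(4, 5, 6))
  expect_true(r$exact)
  expect_equal(r$p, 0.1)      # 2 of the 20 labelings are as extreme
  expect_equal(rankSumTest(c(1, 2, 3), c(1, 2, 3))$p, 1.0)
  a <- c(1.2, 5.3, 2.2, 7.1); b <- c(0.5, 3.3, 9.9)
  expect_equal(rankSumTest(a, b)$p, rankSumTest(b, a)$p)
  expect_equal(rankSumTest(a, b)$U, length(a) * length(b) -
                 rankSumTest(b, a)$U)
  expect_error(rankSumTest(numeric(0), 1), "non-empty")
})

test_that("exact rank-sum branch equals full enumeration for n,m <= 6", {
  set.seed(303)
  for (i in 1:60) {
    n <- sample(2:6, 1); m <- sample(2:6, 1)
    vals <- sample(1000, n + m)  # distinct: no ties
    a <- vals[seq_len(n)]; b <- vals[-seq_len(n)]
    expect_equal(rankSumTest(a, b)$p, rankSumEnumOracle(a, b),
                 tolerance = 1e-12)
  }
})

test_that("group summary follows the 1.5 IQR whisker convention", {
  s <- summarizeGroup(c(1, 2, 3, 4, 5))
  expect_equal(s$median, 3)
  expect_equal(s$q1, 2)
  expect_equal(s$q3, 4)
  expect_equal(s$whiskerLow, 1)
  expect_equal(s$whiskerHigh, 5)

  s2 <- summarizeGroup(c(7, 7, 7))
  expect_equal(s2$median, 7)
  expect_equal(s2$iqr, 0)
  expect_equal(s2$whiskerLow, 7)
  expect_equal(s2$whiskerHigh, 7)

  base <- c(1, 2, 3, 4, 5)
  sOut <- summarizeGroup(c(base, 100))  # outlier beyond Q3 + 1.5 IQR
  expect_equal(sOut$whiskerHigh, 5)
  expect_error(summarizeGroup(numeric(0)), "empty")
})
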