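test_that("8-copy exclusion uses and/or semantics and flags, not deletes", {
  r <- data.frame(count_ch7 = c(4, 4, 8, 4, 8, 3, 4, 4, 4, 4),
                  count_ch11 = c(4, 8, 4, 4, 8, 4, 4, 4, 4, 4),
                  group = "uninduced")
  out <- applyExclusions(r, volumeRule = FALSE)
  expect_equal(nrow(out), 10L)                    # flagged, not deleted
  expect_equal(sum(!out$excluded), 7L)
  expect_equal(out$exclusionReason[c(2, 3, 5)], rep("s_g2", 3))
  # full 2x2 of the and/or rule
  combos <- expand.grid(c7 = c(4L, 8L), c11 = c(4L, 8L))
  flags <- applyExclusions(
    data.frame(count_ch7 = combos$c7, count_ch11 = combos$c11,
               group = "g"), volumeRule = FALSE)$excluded
  expect_identical(flags, c(FALSE, TRUE, TRUE, TRUE))

  empty <- applyExclusions(r[0, ], volumeRule = FALSE)
  expect_equal(nrow(empty), 0L)
})

test_that("volume exclusion flags robust outliers and is idempotent", {
  set.seed(50)
  r <- data.frame(count_ch7 = 4L, count_ch11 = 4L,
                  volume = c(rlnorm(200, log(700), 0.1), 3000, 3500),
                  group = "uninduced")
  out <- applyExclusions(r)
  expect_true(all(out$exclusionReason[201:202] == "volume"))
  expect_identical(applyExclusions(out), out)
  expect_error(applyExclusions(r[, -3], volumeRule = TRUE), "volume")
})

test_that("instability rate counts aberrant among usable nuclei", {
  r <- data.frame(count_ch7 = c(4, 4, 3, 5, 4), count_ch11 = 4, group = "g")
  r <- applyExclusions(r, volumeRule = FALSE)
  expect_equal(instabilityRate(r, "ch7")$ratePercent, 40)

  allEu <- applyExclusions(
    data.frame(count_ch7 = rep(4, 6), count_ch11 = 4, group = "g"),
    volumeRule = FALSE)
  expect_equal(instabilityRate(allEu, "ch7")$ratePercent, 0)

  # an excluded 8 is neither usable nor aberrant
  mix <- applyExclusions(
    data.frame(count_ch7 = c(4, 8, 3), count_ch11 = 4, group = "g"),
    volumeRule = FALSE)
  rate <- instabilityRate(mix, "ch7")
  expect_equal(rate$usable, 2L)
  expect_equal(rate$aberrant, 1L)
  expect_equal(rate$ratePercent, 50)

  all8 <- applyExclusions(
    data.frame(count_ch7 = 8, count_ch11 = 8, group = "g"),
    volumeRule = FALSE)
  expect_error(instabilityRate(all8, "ch7"), "no usable")
})

test_that("chi-squared test matches closed form and reconstructed counts", {
  flat <- chi2Test2x2(matrix(c(10, 10, 10, 10), 2))
  expect_equal(flat$statistic, 0)
  expect_equal(flat$p, 1)

  tab <- matrix(c(45, 1109, 76, 1130), 2)
  got <- chi2Test2x2(tab)
  expect_equal(got$statistic, chi2ClosedForm(45, 76, 1109, 1130),
               tolerance = 1e-12)
  expect_equal(got$statistic, 6.98, tolerance = 0.01)
  expect_equal(got$p, 0.008, tolerance = 0.01)
  expect_lt(got$p, 0.01)

  # transposing the groups leaves the statistic unchanged
  swapped <- chi2Test2x2(tab[, 2:1])
  expect_equal(swapped$statistic, got$statistic)
  expect_equal(swapped$p, got$p)

  # the corrected variant is available and less significant
  expect_gt(chi2Test2x2(tab, correct = TRUE)$p, got$p)
  expect_error(chi2Test2x2(matrix(c(0, 0, 1, 2), 2)), "margin")
})

test_that("chi-squared evidence ordering agrees with the hypergeometric
          oracle within each tail", {
  set.seed(60)
  margins <- list(c(10, 10, 8), c(15, 25, 12), c(20, 20, 20), c(5, 35, 10),
                  c(18, 22, 15))
  for (mg in margins) {
    r1 <- mg[1]; r2 <- mg[2]; c1 <- mg[3]
    aRange <- max(0, c1 - r2):min(r1, c1)
    stat <- vapply(aRange, function(a) {
      tab <- matrix(c(a, r1 - a, c1 - a, r2 - c1 + a), 2)
      if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(NA_real_)
      chi2Test2x2(tab)$statistic
    }, 0)
    lik <- dhyper(aRange, r1, r2, c1)
    # the chi-squared minimum and the hypergeometric mode may sit one
    # cell apart; outside the band between them both orderings agree:
    # moving away from the centre, likelihood falls and chi-squared rises
    lo <- min(which.max(lik), which.min(stat))
    hi <- max(which.max(lik), which.min(stat))
    up <- which(!is.na(stat) & seq_along(stat) >= hi)
    dn <- which(!is.na(stat) & seq_along(stat) <= lo)
    expect_true(all(diff(stat[up]) >= -1e-9))
    expect_true(all(diff(lik[up]) <= 1e-12))
    expect_true(all(diff(stat[dn]) <= 1e-9))
    expect_true(all(diff(lik[dn]) >= -1e-12))
  }
})

test_that("percent change matches the printed-rate worked example", {
  expect_equal(percentChange(3.9, 6.3), 61.5, tolerance = 0.05)
  expect_equal(round(percentChange(3.9, 6.3)), 62)
  expect_equal(percentChange(5, 5), 0)
  expect_equal(percentChange(2, 1), -50)
  expect_error(percentChange(0, 5), "zero baseline")
})

test_that("the instability report composes the full pipeline", {
  un <- simulatePloidyPopulation(ploidySimConfig(
    nNuclei = 3000L, instability = 0.04, group = "uninduced", seed = 70L))
  ind <- simulatePloidyPopulation(ploidySimConfig(
    nNuclei = 3000L, instability = 0.08, group = "induced", seed = 71L))
  rep <- instabilityReport(rbind(un, ind), "ch7")
  expect_equal(rep$rates$group, c("uninduced", "induced"))
  expect_equal(rep$rates$ratePercent[1], 4, tolerance = 0.35)
  expect_equal(rep$rates$ratePercent[2], 8, tolerance = 0.35)
  expect_gt(rep$percentChange, 50)
  expect_lt(rep$p, 0.01)
  expect_true(all(rep$rates$excludedSG2 > 0))
})
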