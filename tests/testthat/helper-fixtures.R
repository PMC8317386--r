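# Shared fixtures and independent oracles for the test suite.

# small config builders ------------------------------------------------

tinyStackConfig <- function(...) {
  stackSimConfig(dim = c(24L, 96L, 96L), nNuclei = 1L,
                 semiAxesUm = rbind(c(1.2, 1.2), c(1.8, 1.8), c(1.8, 1.8)),
                 ...)
}

noiselessArgs <- list(poissonGain = 0, readNoiseSd = 0, textureAmplitude = 0)

# brute-force voxel-set overlap oracle: returns (partner, percent) by
# explicit set intersection over every candidate label
overlapOracle <- function(refIdx, candArr) {
  labs <- sort(unique(candArr[candArr > 0L]))
  best <- NA_integer_; bestN <- 0L
  for (l in labs) {
    n <- length(intersect(refIdx, which(candArr == l)))
    if (n > bestN) { best <- l; bestN <- n }
  }
  list(partner = best, percent = 100 * bestN / length(refIdx))
}

# exact two-sided rank-sum p by full enumeration over all labelings
rankSumEnumOracle <- function(a, b) {
  pooled <- c(a, b)
  n <- length(a); N <- length(pooled)
  U <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, `>`)) + 0.5 * sum(outer(x, y, `==`))
  }
  uObs <- U(seq_len(n))
  mid <- n * (N - n) / 2
  combs <- utils::combn(N, n)
  us <- apply(combs, 2L, U)
  mean(abs(us - mid) >= abs(uObs - mid) - 1e-12)
}

# Pearson chi-squared statistic computed from the closed form (no
# library call), for cross-checking chi2Test2x2
chi2ClosedForm <- function(a, b, c, d) {
  n <- a + b + c + d
  n * (a * d - b * c)^2 / ((a + b) * (c + d) * (a + c) * (b + d))
}

expectNoFiducials <- function(locs) locs[!locs$fiducial, , drop = FALSE]
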