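#' Configuration for the ploidy-population simulator
#'
#' Parameters of [simulatePloidyPopulation()], which emulates per-nucleus
#' FISH copy counts of a target chromosome (chromosome 7) and a control
#' chromosome (chromosome 11) in a near-tetraploid cell population.
#'
#' @param nNuclei number of nuclei.
#' @param euploidCount euploid copy number (default 4: U2OS cells are
#'   near-tetraploid for chromosomes 7 and 11).
#' @param instability probability that a (non-S/G2) nucleus carries an
#'   aberrant copy number of the target chromosome.
#' @param instabilityControl same, for the control chromosome.
#' @param aberrantCounts candidate aberrant copy numbers.
#' @param aberrantWeights sampling weights over \code{aberrantCounts}
#'   (normalized internally). The default (55, 14, 3)/72 over counts
#'   (3, 5, 6) mirrors the observed preponderance of single-copy losses
#'   over gains.
#' @param sg2Fraction probability \code{rho} that a nucleus is in S/G2 and
#'   shows 8 copies of both chromosomes. \code{instability + sg2Fraction}
#'   must be <= 1.
#' @param volumeMedianUm3,volumeSigmaLog nucleus volumes are log-normal
#'   with this median and log-sd.
#' @param volumeInflationSG2 multiplicative volume factor for S/G2 nuclei.
#' @param group group label attached to every record, \code{"uninduced"}
#'   or \code{"induced"}.
#' @param seed integer seed.
#' @return A validated list of class \code{PloidySimConfig}.
#' @export
ploidySimConfig <- function(nNuclei = 1200L,
                            euploidCount = 4L,
                            instability = 0.039,
                            instabilityControl = 0.023,
                            aberrantCounts = c(3L, 5L, 6L),
                            aberrantWeights = c(55, 14, 3) / 72,
                            sg2Fraction = 0.05,
                            volumeMedianUm3 = 700,
                            volumeSigmaLog = 0.25,
                            volumeInflationSG2 = 1.6,
                            group = c("uninduced", "induced"),
                            seed = 1L) {
  group <- match.arg(group)
  cfg <- list(nNuclei = as.integer(nNuclei),
              euploidCount = as.integer(euploidCount),
              instability = instability,
              instabilityControl = instabilityControl,
              aberrantCounts = as.integer(aberrantCounts),
              aberrantWeights = aberrantWeights / sum(aberrantWeights),
              sg2Fraction = sg2Fraction,
              volumeMedianUm3 = volumeMedianUm3,
              volumeSigmaLog = volumeSigmaLog,
              volumeInflationSG2 = volumeInflationSG2,
              group = group, seed = as.integer(seed))
  class(cfg) <- "PloidySimConfig"
  validatePloidySimConfig(cfg)
  cfg
}

validatePloidySimConfig <- function(cfg) {
  with(cfg, {
    if (nNuclei < 0L) stop("nNuclei must be >= 0")
    if (euploidCount < 0L) stop("euploidCount must be >= 0")
    if (instability < 0 || instabilityControl < 0 || sg2Fraction < 0)
      stop("probabilities must be >= 0")
    if (instability + sg2Fraction > 1)
      stop("instability + sg2Fraction must be <= 1")
    if (instabilityControl + sg2Fraction > 1)
      stop("instabilityControl + sg2Fraction must be <= 1")
    if (length(aberrantCounts) != length(aberrantWeights) ||
        any(aberrantWeights < 0) || sum(aberrantWeights) == 0)
      stop("aberrantWeights must be non-negative and match aberrantCounts")
    if (any(aberrantCounts == euploidCount))
      stop("aberrantCounts must differ from euploidCount")
    if (volumeMedianUm3 <= 0 || volumeSigmaLog < 0 ||
        volumeInflationSG2 <= 0)
      stop("volume parameters must be positive")
  })
  invisible(cfg)
}

#' Simulate per-nucleus chromosome copy counts with volumes
#'
#' Each nucleus is independently S/G2 with probability \code{sg2Fraction}
#' (8 copies of both chromosomes, inflated volume); otherwise each
#' chromosome's count is aberrant with its instability probability (drawn
#' from \code{aberrantCounts} by weight) or euploid. Because S/G2 status
#' is drawn first, the aberrant fraction among non-S/G2 nuclei equals the
#' configured instability exactly in expectation, matching how instability
#' rates are reported after 8-copy exclusion.
#'
#' @param cfg a [ploidySimConfig()] object.
#' @return A data frame of per-nucleus records: \code{nucleus},
#'   \code{count_ch7}, \code{count_ch11}, \code{volume} (um^3),
#'   \code{group}, and the ground-truth annotation \code{phase}
#'   (\code{"G1"} or \code{"SG2"}; not used by the scoring pipeline).
#' @examples
#' cfg <- ploidySimConfig(nNuclei = 10L, instability = 0, sg2Fraction = 0)
#' table(simulatePloidyPopulation(cfg)$count_ch7)  # all 4
#' @export
simulatePloidyPopulation <- function(cfg) {
  stopifnot(inherits(cfg, "PloidySimConfig"))
  validatePloidySimConfig(cfg)
  set.seed(cfg$seed)
  n <- cfg$nNuclei
  if (n == 0L)
    return(data.frame(nucleus = integer(0), count_ch7 = integer(0),
                      count_ch11 = integer(0), volume = numeric(0),
                      group = character(0), phase = character(0)))

  sg2 <- stats::runif(n) < cfg$sg2Fraction
  drawCounts <- function(p) {
    ab <- stats::runif(n) < p
    cnt <- rep(cfg$euploidCount, n)
    k <- sum(ab)
    if (k > 0L)
      cnt[ab] <- sample(cfg$aberrantCounts, k, replace = TRUE,
                        prob = cfg$aberrantWeights)
    cnt
  }
  ch7 <- drawCounts(cfg$instability)
  ch11 <- drawCounts(cfg$instabilityControl)
  ch7[sg2] <- 8L
  ch11[sg2] <- 8L

  vol <- stats::rlnorm(n, meanlog = log(cfg$volumeMedianUm3),
                       sdlog = cfg$volumeSigmaLog)
  vol[sg2] <- vol[sg2] * cfg$volumeInflationSG2

  data.frame(nucleus = seq_len(n), count_ch7 = as.integer(ch7),
             count_ch11 = as.integer(ch11), volume = vol,
             group = cfg$group, phase = ifelse(sg2, "SG2", "G1"))
}
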