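#' Normalized foci density of one nucleus
#'
#' The central enrichment statistic: the ratio of the mean fluorescence
#' intensity inside the foci of a nucleus over the mean intensity of the
#' whole nucleus,
#' \deqn{(Signal_{foci}/Volume_{foci}) / (Signal_{nucleus}/Volume_{nucleus}),}
#' where the focus signals and volumes of the nucleus are pooled (summed)
#' before the ratio is formed — one density value per nucleus, not a mean
#' of per-focus ratios. A density greater than one indicates that the
#' signal is higher within the foci; a uniform-intensity nucleus has
#' density exactly 1. The statistic is invariant under global positive
#' rescaling of intensities.
#'
#' By default \code{Signal_nucleus} is the total nuclear signal including
#' the foci; set \code{nucleusSignal = "exclusive"} to subtract the pooled
#' foci signal and volume from the nuclear reference first.
#'
#' @param foci focus records of one nucleus and one channel (rows of a
#'   [segmentFoci()] record table).
#' @param nucleus one nucleus record row (from [segmentNuclei()]).
#' @param group optional group label to attach (e.g. the experimental
#'   condition).
#' @param nucleusSignal \code{"inclusive"} (default) or \code{"exclusive"}.
#' @return A one-row data frame: \code{nucleus}, \code{channel},
#'   \code{density}, \code{group}.
#' @examples
#' foci <- data.frame(nucleus = 1L, channel = "marker1", volumeUm3 = 2,
#'                    signal = 8)
#' nuc <- data.frame(label = 1L, volumeUm3 = 10, signal_marker1 = 20)
#' normalizedDensity(foci, nuc)$density  # (8/2)/(20/10) = 2
#' @export
normalizedDensity <- function(foci, nucleus, group = NA_character_,
                              nucleusSignal = c("inclusive", "exclusive")) {
  nucleusSignal <- match.arg(nucleusSignal)
  stopifnot(is.data.frame(foci), is.data.frame(nucleus),
            nrow(nucleus) == 1L)
  if (nrow(foci) == 0L) stop("no foci supplied for the nucleus")
  chan <- unique(foci$channel)
  if (length(chan) != 1L)
    stop("foci must belong to a single channel; got: ",
         paste(chan, collapse = ", "))
  if (!all(foci$nucleus == nucleus$label))
    stop("foci do not belong to nucleus ", nucleus$label)

  sf <- sum(foci$signal)
  vf <- sum(foci$volumeUm3)
  sn <- nucleus[[paste0("signal_", chan)]]
  vn <- nucleus$volumeUm3
  if (is.null(sn)) stop("nucleus record lacks column signal_", chan)
  if (nucleusSignal == "exclusive") {
    sn <- sn - sf
    vn <- vn - vf
  }
  if (vf <= 0) stop("undefined density: zero focus volume")
  if (sn <= 0 || vn <= 0)
    stop("undefined density: non-positive nuclear signal or volume")
  data.frame(nucleus = nucleus$label, channel = chan,
             density = (sf / vf) / (sn / vn), group = group)
}

#' Per-nucleus normalized densities over a segmented stack
#'
#' Applies [normalizedDensity()] to every nucleus that carries at least
#' one focus of the requested channel.
#'
#' @param foci focus record table ([segmentFoci()]).
#' @param nuclei nucleus record table ([segmentNuclei()]).
#' @param channel channel name (defaults to the single channel present in
#'   \code{foci}).
#' @param group,nucleusSignal passed to [normalizedDensity()].
#' @return Data frame with one row per nucleus with foci.
#' @export
nucleusDensities <- function(foci, nuclei, channel = NULL,
                             group = NA_character_,
                             nucleusSignal = "inclusive") {
  if (is.null(channel)) {
    channel <- unique(foci$channel)
    if (length(channel) != 1L)
      stop("specify `channel`: foci table holds ",
           length(channel), " channels")
  }
  f <- foci[foci$channel == channel, , drop = FALSE]
  ids <- intersect(unique(f$nucleus), nuclei$label)
  rows <- lapply(ids, function(nid)
    normalizedDensity(f[f$nucleus == nid, , drop = FALSE],
                      nuclei[nuclei$label == nid, , drop = FALSE],
                      group = group, nucleusSignal = nucleusSignal))
  if (length(rows) == 0L)
    return(data.frame(nucleus = integer(0), channel = character(0),
                      density = numeric(0), group = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Group effect size on normalized densities
#'
#' Relative reduction of the density excess above 1 between a control and
#' a treated group: \code{1 - (mean(treated) - 1) / (mean(control) - 1)}.
#' A density of 1 means "no enrichment at the foci" (the dashed unity
#' line of the group boxplots), so the excess above 1 is the enrichment
#' signal itself and its relative reduction estimates the fractional loss
#' of marker at the foci; measuring the reduction on the excess rather
#' than on the raw ratio makes the estimator insensitive to the shared
#' optical dilution (PSF, segmentation mask) of both groups.
#'
#' @param control,treated numeric vectors of per-nucleus normalized
#'   densities ([nucleusDensities()]).
#' @return The estimated fractional marker loss (0.2 = 20\% loss);
#'   negative values indicate a gain.
#' @export
densityEffectSize <- function(control, treated) {
  mc <- mean(control, na.rm = TRUE)
  mt <- mean(treated, na.rm = TRUE)
  if (mc <= 1) stop("control group shows no enrichment (mean density <= 1)")
  1 - (mt - 1) / (mc - 1)
}

#' Volume-normalized spot intensity
#'
#' Integrated focus signal divided by focus volume (a.u. per um^3), the
#' per-spot normalization that removes the effect of size differences
#' between foci (used for core-centromere spot intensities).
#'
#' @param focus focus record row(s) with \code{signal} and
#'   \code{volumeUm3}.
#' @return Numeric vector of mean intensities.
#' @examples
#' spotMeanIntensity(data.frame(signal = 46, volumeUm3 = 2.3))  # 20
#' @export
spotMeanIntensity <- function(focus) {
  if (any(focus$volumeUm3 <= 0))
    stop("undefined spot intensity: zero focus volume")
  focus$signal / focus$volumeUm3
}

#' Largest-overlap partner of a reference focus
#'
#' For a reference focus mask and a label map of candidate foci on the
#' same voxel grid, computes the overlap of each contacting candidate as a
#' percentage of the reference volume and keeps only the candidate with
#' the largest overlap (the selection rule used when several
#' core-centromere foci touch one segmented focus). Ties in percent are
#' ties in absolute intersection here (fixed reference); they are broken
#' toward the lowest candidate label.
#'
#' @param referenceMask logical array, or integer vector of voxel indices.
#' @param candidateLabels integer label array on the same grid.
#' @return A one-row data frame: \code{partner} (label, \code{NA} if no
#'   candidate touches the reference) and \code{overlapPercent} (percent
#'   of the reference volume covered, 0 if none).
#' @examples
#' ref <- c(1:8)
#' cand <- integer(27); cand[1:2] <- 1L; cand[9] <- 2L
#' dim(cand) <- c(3, 3, 3)
#' overlapFraction(ref, cand)  # partner 1, 25%
#' @export
overlapFraction <- function(referenceMask, candidateLabels) {
  refIdx <- if (is.logical(referenceMask)) which(referenceMask)
    else as.integer(referenceMask)
  if (length(refIdx) == 0L) stop("empty reference mask")
  hits <- candidateLabels[refIdx]
  hits <- hits[hits > 0L]
  if (length(hits) == 0L)
    return(data.frame(partner = NA_integer_, overlapPercent = 0))
  counts <- tabulate(hits)
  best <- which.max(counts)  # first maximum = lowest label on ties
  data.frame(partner = as.integer(best),
             overlapPercent = 100 * counts[best] / length(refIdx))
}

#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided rank-sum comparison of two samples, the nonparametric test
#' used for all pairwise group comparisons of densities and areas. The
#' exact null distribution is used when both samples have at most
#' \code{exactMax} observations and there are no ties; otherwise the
#' normal approximation with tie and continuity correction applies.
#'
#' @param a,b numeric samples (both non-empty).
#' @param exactMax exact-branch size limit per sample (default 8).
#' @return A list with \code{U} (the Mann-Whitney statistic of \code{a})
#'   and \code{p} (two-sided p-value).
#' @examples
#' rankSumTest(c(1, 2, 3), c(4, 5, 6))$p  # exact: 0.1
#' @export
rankSumTest <- function(a, b, exactMax = 8L) {
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= exactMax && length(b) <= exactMax && !ties
  ht <- suppressWarnings(stats::wilcox.test(a, b, exact = exact,
                                            correct = TRUE))
  list(U = unname(ht$statistic), p = ht$p.value, exact = exact)
}

#' Boxplot summary of a sample
#'
#' Median, quartiles (linear-interpolation, type-7 quantiles) and whisker
#' bounds: the most extreme data points within 1.5 interquartile ranges of
#' the quartiles — the plotting convention used for all group boxplots.
#'
#' @param values non-empty numeric sample.
#' @return A list: \code{median}, \code{q1}, \code{q3}, \code{iqr},
#'   \code{whiskerLow}, \code{whiskerHigh}, \code{n}.
#' @examples
#' summarizeGroup(c(1, 2, 3, 4, 5))[c("median", "q1", "q3")]
#' @export
summarizeGroup <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) stop("empty sample")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  iqr <- q[3] - q[1]
  lo <- q[1] - 1.5 * iqr
  hi <- q[3] + 1.5 * iqr
  list(median = q[2], q1 = q[1], q3 = q[3], iqr = iqr,
       whiskerLow = min(values[values >= lo]),
       whiskerHigh = max(values[values <= hi]),
       n = length(values))
}
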