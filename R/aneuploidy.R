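#' Apply S/G2 and volume exclusion rules to per-nucleus count records
#'
#' Flags (never deletes) nuclei that must not enter instability scoring:
#' nuclei with 8 copies of the target and/or the control chromosome
#' (cells in S/G2 that have doubled their chromosomes; reason
#' \code{"s_g2"}), and nuclei showing a significant volume increase
#' (reason \code{"volume"}): volume above the within-group
#' median + \code{volumeMadFactor} robust SDs (1.4826 MAD). The volume
#' statistics are computed over non-S/G2 records of each group, so the
#' operation is idempotent.
#'
#' @param records data frame with \code{count_ch7}, \code{count_ch11},
#'   \code{group}, and \code{volume} (required when \code{volumeRule}).
#' @param volumeRule apply the volume-outlier exclusion?
#' @param sg2Count copy number treated as S/G2 (default 8).
#' @param volumeMadFactor robust-SD multiple of the volume rule.
#' @return \code{records} with \code{excluded} and \code{exclusionReason}
#'   columns set.
#' @export
applyExclusions <- function(records, volumeRule = TRUE, sg2Count = 8L,
                            volumeMadFactor = 2) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  if (n == 0L) {
    records$excluded <- logical(0)
    records$exclusionReason <- character(0)
    return(records)
  }
  sg2 <- records$count_ch7 == sg2Count | records$count_ch11 == sg2Count
  reason <- ifelse(sg2, "s_g2", "")
  if (volumeRule) {
    if (!("volume" %in% names(records)))
      stop("volume rule requested but records carry no 'volume' column")
    grp <- if ("group" %in% names(records)) records$group else rep("all", n)
    for (g in unique(grp)) {
      inG <- grp == g & !sg2
      if (!any(inG)) next
      thr <- stats::median(records$volume[inG]) +
        volumeMadFactor * robustSd(records$volume[inG])
      big <- grp == g & !sg2 & records$volume > thr
      reason[big] <- "volume"
    }
  }
  records$excluded <- reason != ""
  records$exclusionReason <- reason
  records
}

#' Chromosome instability rate
#'
#' Percentage of usable (non-excluded) nuclei whose copy count of the
#' chromosome deviates from the euploid value. Excluded nuclei contribute
#' to neither the aberrant nor the usable total.
#'
#' @param records output of [applyExclusions()].
#' @param chromosome \code{"ch7"} or \code{"ch11"}.
#' @param euploid euploid copy number (default 4).
#' @return A list: \code{aberrant}, \code{usable}, \code{ratePercent}.
#' @examples
#' r <- data.frame(count_ch7 = c(4, 4, 3, 5, 4), count_ch11 = 4,
#'                 group = "uninduced")
#' r <- applyExclusions(r, volumeRule = FALSE)
#' instabilityRate(r, "ch7")$ratePercent  # 40
#' @export
instabilityRate <- function(records, chromosome = c("ch7", "ch11"),
                            euploid = 4L) {
  chromosome <- match.arg(chromosome)
  if (!("excluded" %in% names(records)))
    stop("apply exclusions first (applyExclusions)")
  cnt <- records[[paste0("count_", chromosome)]]
  usable <- !records$excluded
  nU <- sum(usable)
  if (nU == 0L) stop("undefined rate: no usable records")
  nA <- sum(usable & cnt != euploid)
  list(aberrant = nA, usable = nU, ratePercent = 100 * nA / nU)
}

#' Build the 2x2 aberrant-by-group contingency table
#'
#' @param records output of [applyExclusions()] holding exactly two
#'   groups.
#' @param chromosome,euploid as in [instabilityRate()].
#' @param groups optional character length-2 giving the column order
#'   (baseline first); defaults to factor levels or sorted unique values
#'   with \code{"uninduced"} first when present.
#' @return A 2x2 integer matrix, rows \code{aberrant}/\code{normal},
#'   columns the two groups.
#' @export
contingencyTable <- function(records, chromosome = c("ch7", "ch11"),
                             euploid = 4L, groups = NULL) {
  chromosome <- match.arg(chromosome)
  if (!("excluded" %in% names(records)))
    stop("apply exclusions first (applyExclusions)")
  u <- records[!records$excluded, , drop = FALSE]
  if (is.null(groups)) {
    groups <- if (is.factor(u$group)) levels(u$group)
      else sort(unique(as.character(u$group)))
    if ("uninduced" %in% groups)
      groups <- c("uninduced", setdiff(groups, "uninduced"))
  }
  if (length(groups) != 2L)
    stop("need exactly two groups, got: ", paste(groups, collapse = ", "))
  cnt <- u[[paste0("count_", chromosome)]]
  ab <- cnt != euploid
  m <- vapply(groups, function(g)
    c(aberrant = sum(ab & u$group == g),
      normal = sum(!ab & u$group == g)), integer(2))
  m
}

#' Pearson chi-squared test of a 2x2 contingency table
#'
#' One degree of freedom, by default without Yates continuity correction
#' (the corrected variant is available behind \code{correct = TRUE}).
#'
#' @param table 2x2 numeric matrix of non-negative counts with positive
#'   margins.
#' @param correct apply the continuity correction?
#' @return A list: \code{statistic} (chi-squared), \code{p} (upper-tail
#'   p from the 1-df chi-squared distribution).
#' @examples
#' chi2Test2x2(matrix(c(45, 1109, 76, 1130), 2))  # X^2 ~ 6.98, p ~ 0.008
#' @export
chi2Test2x2 <- function(table, correct = FALSE) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2L, 2L))) stop("table must be 2x2")
  if (any(m < 0)) stop("counts must be >= 0")
  if (any(rowSums(m) == 0) || any(colSums(m) == 0))
    stop("degenerate table: zero margin")
  ht <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(statistic = unname(ht$statistic), p = ht$p.value)
}

#' Percent change between two rates
#'
#' @param rateBefore baseline rate (percent; must be > 0).
#' @param rateAfter comparison rate (percent).
#' @return \code{100 * (rateAfter - rateBefore) / rateBefore}.
#' @examples
#' percentChange(3.9, 6.3)  # 61.5, reported as a ~62% increase
#' @export
percentChange <- function(rateBefore, rateAfter) {
  if (rateBefore <= 0) stop("undefined percent change: zero baseline rate")
  100 * (rateAfter - rateBefore) / rateBefore
}

#' Full chromosome-instability report for a two-group experiment
#'
#' Convenience pipeline: exclusions, per-group instability rates, the
#' 2x2 contingency table, the chi-squared test and the percent change of
#' the rate from the baseline group to the other.
#'
#' @param records per-nucleus count records (both groups in one table).
#' @param chromosome,euploid as in [instabilityRate()].
#' @param volumeRule,volumeMadFactor passed to [applyExclusions()].
#' @param correct continuity correction for [chi2Test2x2()].
#' @return A list: \code{rates} (data frame per group: aberrant, usable,
#'   ratePercent, excluded tallies by reason), \code{table},
#'   \code{chi2}, \code{p}, \code{percentChange}.
#' @export
instabilityReport <- function(records, chromosome = c("ch7", "ch11"),
                              euploid = 4L, volumeRule = TRUE,
                              volumeMadFactor = 2, correct = FALSE) {
  chromosome <- match.arg(chromosome)
  flagged <- applyExclusions(records, volumeRule = volumeRule,
                             volumeMadFactor = volumeMadFactor)
  tab <- contingencyTable(flagged, chromosome, euploid)
  groups <- colnames(tab)
  rates <- do.call(rbind, lapply(groups, function(g) {
    sub <- flagged[flagged$group == g, , drop = FALSE]
    r <- instabilityRate(sub, chromosome, euploid)
    data.frame(group = g, aberrant = r$aberrant, usable = r$usable,
               ratePercent = r$ratePercent,
               excludedSG2 = sum(sub$exclusionReason == "s_g2"),
               excludedVolume = sum(sub$exclusionReason == "volume"))
  }))
  test <- chi2Test2x2(tab, correct = correct)
  list(rates = rates, table = tab, chi2 = test$statistic, p = test$p,
       percentChange = percentChange(rates$ratePercent[1],
                                     rates$ratePercent[2]))
}
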