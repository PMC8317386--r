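#' Fiducial-based drift correction
#'
#' Estimates the per-frame stage drift from fiducial bead records and
#' subtracts it from every localization. The raw drift at frame \eqn{f}
#' is the mean over fiducials of (position at \eqn{f} minus position at
#' frame 0); the trajectory is then smoothed — by a cubic smoothing
#' spline (default; exact for linear drift, and the frame-0 anchor then
#' carries averaged rather than single-frame bead noise) or by a centred
#' moving average whose window shrinks symmetrically at the acquisition
#' ends — and re-zeroed so the displacement at frame 0 is exactly (0,0).
#' Frames with no fiducial detection are linearly interpolated with a
#' warning; fiducial records are corrected too and stay flagged.
#'
#' @param locs localization table with logical \code{fiducial} column;
#'   bead identity is taken from \code{fiducialId} when present, else
#'   beads are identified by proximity to the earliest-frame bead
#'   positions (within \code{maxMatchNm}).
#' @param smoothing \code{"spline"} (default) or \code{"movingAverage"}.
#' @param smoothWindow moving-average half-width in frames (window
#'   \code{2*smoothWindow + 1}); used by the moving-average smoother.
#' @param maxMatchNm matching radius for bead identification, nm.
#' @return A list with \code{locs} (drift-corrected table, same row count)
#'   and \code{drift}, a data frame \code{frame, dx, dy} (nm, relative to
#'   frame 0; first row is 0, 0).
#' @export
correctDrift <- function(locs, smoothing = c("spline", "movingAverage"),
                         smoothWindow = 10L, maxMatchNm = 1000) {
  smoothing <- match.arg(smoothing)
  stopifnot(is.data.frame(locs), "fiducial" %in% names(locs))
  fid <- locs[which(locs$fiducial), , drop = FALSE]
  if (nrow(fid) == 0L)
    stop("no fiducial records: cannot estimate drift")
  nF <- max(locs$frame) + 1L

  if (!("fiducialId" %in% names(fid)) || all(is.na(fid$fiducialId))) {
    f0 <- min(fid$frame)
    ref <- fid[fid$frame == f0, , drop = FALSE]
    d2 <- outer(fid$x, ref$x, `-`)^2 + outer(fid$y, ref$y, `-`)^2
    id <- max.col(-d2, ties.method = "first")
    ok <- d2[cbind(seq_len(nrow(fid)), id)] <= maxMatchNm^2
    if (!all(ok)) {
      warning(sum(!ok), " fiducial record(s) match no bead within ",
              maxMatchNm, " nm; dropped from the drift estimate")
      fid <- fid[ok, , drop = FALSE]
      id <- id[ok]
    }
    fid$fiducialId <- id
  }

  ids <- sort(unique(fid$fiducialId))
  # per-bead per-frame mean positions
  trackX <- matrix(NA_real_, nF, length(ids))
  trackY <- matrix(NA_real_, nF, length(ids))
  for (j in seq_along(ids)) {
    sel <- fid$fiducialId == ids[j]
    mx <- tapply(fid$x[sel], fid$frame[sel], mean)
    my <- tapply(fid$y[sel], fid$frame[sel], mean)
    at <- as.integer(names(mx)) + 1L
    trackX[at, j] <- mx
    trackY[at, j] <- my
  }
  if (all(is.na(trackX[1L, ])))
    stop("no fiducial detected in frame 0; drift reference undefined")

  dx <- rowMeans(sweep(trackX, 2L, trackX[1L, ], `-`), na.rm = TRUE)
  dy <- rowMeans(sweep(trackY, 2L, trackY[1L, ], `-`), na.rm = TRUE)
  gap <- !is.finite(dx) | !is.finite(dy)
  if (any(gap)) {
    warning(sum(gap), " frame(s) without fiducial; drift interpolated")
    at <- which(!gap)
    dx <- stats::approx(at, dx[at], xout = seq_len(nF), rule = 2)$y
    dy <- stats::approx(at, dy[at], xout = seq_len(nF), rule = 2)$y
  }
  if (smoothing == "spline" && nF >= 10L) {
    f0 <- seq_len(nF)
    dx <- stats::predict(stats::smooth.spline(f0, dx), f0)$y
    dy <- stats::predict(stats::smooth.spline(f0, dy), f0)$y
  } else {
    dx <- shrinkingMovingAverage(dx, smoothWindow)
    dy <- shrinkingMovingAverage(dy, smoothWindow)
  }
  # re-zero on the smoothed trajectory: the frame-0 anchor then carries
  # averaged (not single-frame) bead noise, and drift(0) = 0 holds exactly
  dx <- dx - dx[1L]
  dy <- dy - dy[1L]

  out <- locs
  out$x <- locs$x - dx[locs$frame + 1L]
  out$y <- locs$y - dy[locs$frame + 1L]
  list(locs = out,
       drift = data.frame(frame = 0:(nF - 1L), dx = dx, dy = dy))
}

# centred moving average; the window shrinks symmetrically at both ends,
# which leaves a linear sequence unchanged everywhere
shrinkingMovingAverage <- function(v, half) {
  n <- length(v)
  if (half <= 0L || n < 3L) return(v)
  cs <- cumsum(c(0, v))
  i <- seq_len(n)
  h <- pmin(half, i - 1L, n - i)
  (cs[i + h + 1L] - cs[i - h]) / (2 * h + 1)
}

#' Merge consecutive detections of the same molecule
#'
#' Detections in consecutive frames (allowing up to \code{maxGapFrames}
#' dark frames) that lie within \code{radiusNm} of each other are linked
#' greedily by nearest neighbour, and each chain collapses to a single
#' record: inverse-variance weighted mean position, summed photons, and
#' combined uncertainty \eqn{1/\sqrt{\sum 1/\sigma_i^2}}. The record count
#' never increases.
#'
#' @param locs drift-corrected localization table.
#' @param radiusNm linking radius, nm (>= 0).
#' @param maxGapFrames tolerated dark frames inside a chain.
#' @return A localization table with one row per chain; extra column
#'   \code{mergedN} gives the chain length. The \code{frame} of a merged
#'   record is its first frame.
#' @export
mergeConsecutive <- function(locs, radiusNm = 50, maxGapFrames = 1L) {
  if (radiusNm < 0) stop("radiusNm must be >= 0")
  if (nrow(locs) == 0L) return(locs)
  ord <- order(locs$frame)
  locs <- locs[ord, , drop = FALSE]
  n <- nrow(locs)
  chain <- integer(n)           # chain id per record
  lastIdx <- integer(0)         # most recent record of each open chain
  nChain <- 0L
  frames <- sort(unique(locs$frame))
  byFrame <- split(seq_len(n), locs$frame)
  for (f in frames) {
    cur <- byFrame[[as.character(f)]]
    if (length(lastIdx)) {
      open <- which(f - locs$frame[lastIdx] <= maxGapFrames + 1L &
                      f - locs$frame[lastIdx] >= 1L)
    } else open <- integer(0)
    if (length(open) && length(cur)) {
      dmat <- sqrt(outer(locs$x[cur], locs$x[lastIdx[open]], `-`)^2 +
                     outer(locs$y[cur], locs$y[lastIdx[open]], `-`)^2)
      pairs <- which(dmat <= radiusNm, arr.ind = TRUE)
      if (nrow(pairs)) {
        pairs <- pairs[order(dmat[pairs]), , drop = FALSE]
        usedC <- logical(length(cur)); usedO <- logical(length(open))
        for (pi in seq_len(nrow(pairs))) {
          ci <- pairs[pi, 1L]; oi <- pairs[pi, 2L]
          if (usedC[ci] || usedO[oi]) next
          usedC[ci] <- TRUE; usedO[oi] <- TRUE
          id <- chain[lastIdx[open[oi]]]
          chain[cur[ci]] <- id
          lastIdx[open[oi]] <- cur[ci]
        }
      }
    }
    fresh <- cur[chain[cur] == 0L]
    if (length(fresh)) {
      chain[fresh] <- nChain + seq_along(fresh)
      nChain <- nChain + length(fresh)
      lastIdx <- c(lastIdx, fresh)
    }
    # prune chains that can no longer be extended
    lastIdx <- lastIdx[f - locs$frame[lastIdx] <= maxGapFrames]
  }

  collapse <- function(ix) {
    if (length(ix) == 1L) {
      row <- locs[ix, , drop = FALSE]
      row$mergedN <- 1L
      return(row)
    }
    s <- locs[ix, , drop = FALSE]
    wt <- 1 / s$uncertainty^2
    if (any(!is.finite(wt))) wt <- rep(1, length(ix))
    row <- s[1L, , drop = FALSE]
    row$x <- sum(s$x * wt) / sum(wt)
    row$y <- sum(s$y * wt) / sum(wt)
    row$uncertainty <- 1 / sqrt(sum(1 / s$uncertainty^2))
    if ("photons" %in% names(s)) row$photons <- sum(s$photons)
    if ("sigma" %in% names(s)) row$sigma <- mean(s$sigma)
    if ("fiducial" %in% names(s)) row$fiducial <- any(s$fiducial)
    row$frame <- min(s$frame)
    row$mergedN <- length(ix)
    row
  }
  out <- do.call(rbind, lapply(split(seq_len(n), chain), collapse))
  out <- out[order(out$frame), , drop = FALSE]
  rownames(out) <- NULL
  out
}
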