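#' Render a super-resolved image from localizations
#'
#' Builds the super-resolution canvas: pixel size is the raw pixel size
#' divided by the upsampling factor (tenfold by default, e.g. 144 nm ->
#' 14.4 nm), and every localization contributes a 2D Gaussian of unit peak
#' amplitude whose sigma is the record's localization uncertainty,
#' evaluated out to \code{truncSigmas} sigmas (4 by default: < 1e-4
#' amplitude error at bounded cost). Amplitudes add, so the canvas sum is
#' approximately \eqn{2\pi(\sigma_{loc}/pixel)^2} per localization.
#' Fiducial records should be removed by the caller before rendering.
#'
#' @param locs localization table; \code{uncertainty} must be set on
#'   every record (an uncertainty of 0 deposits its weight on the nearest
#'   pixel).
#' @param frameDimPx raw frame size \code{(ny, nx)}, px.
#' @param rawPixelNm raw pixel size, nm.
#' @param upsample canvas upsampling factor.
#' @param truncSigmas Gaussian truncation radius, in sigmas.
#' @return A [SuperResImage-class]; an all-zero canvas for an empty table.
#' @export
renderSuperRes <- function(locs, frameDimPx, rawPixelNm = 144,
                           upsample = 10L, truncSigmas = 4) {
  stopifnot(length(frameDimPx) == 2L, upsample >= 1)
  px <- rawPixelNm / upsample
  ny <- as.integer(frameDimPx[1] * upsample)
  nx <- as.integer(frameDimPx[2] * upsample)
  canvas <- matrix(0, ny, nx)
  if (nrow(locs) > 0L) {
    if (!("uncertainty" %in% names(locs)) || anyNA(locs$uncertainty))
      stop("every localization needs an uncertainty (sigma_loc) for rendering")
    for (i in seq_len(nrow(locs))) {
      cx <- locs$x[i] / px           # canvas px, origin at frame corner
      cy <- locs$y[i] / px
      s <- locs$uncertainty[i] / px
      if (s <= 0) {
        r <- min(max(ceiling(cy), 1L), ny)
        c <- min(max(ceiling(cx), 1L), nx)
        canvas[r, c] <- canvas[r, c] + 1
        next
      }
      w <- truncSigmas * s
      c0 <- max(1L, floor(cx - w)); c1 <- min(nx, ceiling(cx + w))
      r0 <- max(1L, floor(cy - w)); r1 <- min(ny, ceiling(cy + w))
      if (c0 > c1 || r0 > r1) next
      gx <- exp(-(((c0:c1) - 0.5) - cx)^2 / (2 * s^2))
      gy <- exp(-(((r0:r1) - 0.5) - cy)^2 / (2 * s^2))
      canvas[r0:r1, c0:c1] <- canvas[r0:r1, c0:c1] + outer(gy, gx)
    }
  }
  SuperResImage(canvas, pixelSizeNm = px)
}

#' Max-normalized cluster area above a threshold
#'
#' Measures the size of one rendered cluster: the region of interest is
#' cropped, divided by its maximum intensity pixel (so the measure
#' reflects cluster size, not event density), and the area is the number
#' of pixels at or above the intensity threshold times the pixel area,
#' reported in um^2. The area is scale-invariant and monotone
#' non-increasing in the threshold.
#'
#' @param img a [SuperResImage-class].
#' @param roiNm numeric length-4 \code{(xmin, xmax, ymin, ymax)} in nm,
#'   half-open; pixels whose centres fall inside are cropped.
#' @param threshold relative intensity threshold \code{t}, \code{0 < t <=
#'   1} (default 0.5; recorded in the result for reproducibility).
#' @return A one-row data frame: \code{areaUm2}, \code{pixelCount},
#'   \code{threshold}, \code{roiXminNm}, \code{roiXmaxNm},
#'   \code{roiYminNm}, \code{roiYmaxNm}. An all-zero region is an error
#'   (undefined area).
#' @examples
#' m <- matrix(0, 3, 3); m[1, 1] <- 1; m[1, 2] <- 0.6; m[2, 1] <- 0.4
#' img <- SuperResImage(m, pixelSizeNm = 14.4)
#' clusterArea(img, c(0, 3 * 14.4, 0, 3 * 14.4), 0.5)$areaUm2
#' # 2 * 0.0144^2 = 4.147e-4
#' @export
clusterArea <- function(img, roiNm, threshold = 0.5) {
  stopifnot(is(img, "SuperResImage"), length(roiNm) == 4L)
  if (threshold <= 0 || threshold > 1)
    stop("threshold must be in (0, 1]")
  px <- img@pixelSizeNm
  d <- dim(img@data)
  xs <- (seq_len(d[2]) - 0.5) * px
  ys <- (seq_len(d[1]) - 0.5) * px
  cols <- which(xs >= roiNm[1] & xs < roiNm[2])
  rows <- which(ys >= roiNm[3] & ys < roiNm[4])
  if (length(cols) == 0L || length(rows) == 0L)
    stop("ROI contains no pixel centres")
  sub <- img@data[rows, cols, drop = FALSE]
  m <- max(sub)
  if (m <= 0) stop("undefined area: ROI has no signal")
  count <- sum(sub / m >= threshold)
  data.frame(areaUm2 = count * (px / 1000)^2, pixelCount = count,
             threshold = threshold, roiXminNm = roiNm[1],
             roiXmaxNm = roiNm[2], roiYminNm = roiNm[3],
             roiYmaxNm = roiNm[4])
}
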