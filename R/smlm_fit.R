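#' Fit single-molecule events in raw SMLM frames
#'
#' Per frame: a difference-of-Gaussians band-pass at the PSF scale, local
#' maxima above \code{detectK} robust SDs of the filtered background, then
#' a least-squares symmetric 2D Gaussian fit (amplitude, centre, sigma,
#' offset; Levenberg-Marquardt) in a window around each candidate. The
#' localization uncertainty is the Thompson-style photon-statistics
#' estimate \eqn{\sigma_{loc}^2 = (\sigma^2 + a^2/12)/N + 8\pi\sigma^4
#' b^2/(a^2 N^2)} with \eqn{N = 2\pi A \sigma^2} photons, pixel size
#' \eqn{a} and background variance \eqn{b^2} (Poisson, from the fitted
#' offset). Failed or implausible fits (no convergence, centre outside
#' the window, sigma far from the PSF scale) are discarded.
#'
#' @param frames a \code{(ny, nx, nFrames)} array, a single matrix, or a
#'   list of matrices (photon counts).
#' @param rawPixelNm raw pixel size, nm.
#' @param psfSigmaPx expected PSF sigma, raw pixels.
#' @param detectK detection threshold in robust SDs of the band-passed
#'   frame.
#' @param winHalfPx half-width of the fitting window (default
#'   \code{ceiling(3 * psfSigmaPx)}).
#' @param minPhotons events fitted with fewer photons are discarded
#'   (quality filter against noise-triggered fits).
#' @return A localization table (\code{frame} 0-based; \code{x, y,
#'   uncertainty, sigma} in nm; \code{photons}; \code{fiducial = FALSE});
#'   zero rows for blank frames.
#' @seealso [simulateSmlm()] with \code{renderFrames = TRUE} for matched
#'   ground truth.
#' @export
fitEvents <- function(frames, rawPixelNm = 144, psfSigmaPx = 1.3,
                      detectK = 5, winHalfPx = NULL, minPhotons = 50) {
  if (is.matrix(frames)) frames <- list(frames)
  if (is.array(frames) && length(dim(frames)) == 3L) {
    arr <- frames
    frames <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  }
  if (!is.list(frames) || !all(vapply(frames, is.matrix, TRUE)))
    stop("schema error: frames must be 2D (a matrix, list of matrices, ",
         "or ny x nx x nFrames array)")
  if (is.null(winHalfPx)) winHalfPx <- ceiling(3 * psfSigmaPx)
  w <- as.integer(winHalfPx)

  rows <- list()
  for (fi in seq_along(frames)) {
    fr <- frames[[fi]]
    ny <- nrow(fr); nx <- ncol(fr)
    dog <- gblurSafe(fr, 0.8 * psfSigmaPx) - gblurSafe(fr, 2 * psfSigmaPx)
    noise <- robustSd(as.numeric(dog))
    if (noise <= 0) next
    cand <- localMaxima2d(dog) & dog > detectK * noise
    # keep a full fitting window inside the frame
    cand[c(seq_len(w), ny - seq_len(w) + 1L), ] <- FALSE
    cand[, c(seq_len(w), nx - seq_len(w) + 1L)] <- FALSE
    for (ci in which(cand)) {
      r0 <- (ci - 1L) %% ny + 1L
      c0 <- (ci - 1L) %/% ny + 1L
      win <- fr[(r0 - w):(r0 + w), (c0 - w):(c0 + w)]
      fit <- fitGauss2d(win, psfSigmaPx)
      if (is.null(fit)) next
      # window-local px -> frame px -> nm (pixel centres at i - 0.5)
      xPx <- (c0 - w - 1L) + fit$x0
      yPx <- (r0 - w - 1L) + fit$y0
      N <- 2 * pi * fit$A * fit$sigma^2
      if (N < minPhotons) next
      bvar <- max(fit$b, 0)   # Poisson background variance per pixel
      slocPx2 <- (fit$sigma^2 + 1 / 12) / N +
        8 * pi * fit$sigma^4 * bvar / N^2
      rows[[length(rows) + 1L]] <- data.frame(
        frame = fi - 1L, x = xPx * rawPixelNm, y = yPx * rawPixelNm,
        uncertainty = sqrt(slocPx2) * rawPixelNm,
        sigma = fit$sigma * rawPixelNm, photons = N,
        fiducial = FALSE, fiducialId = NA_integer_)
    }
  }
  if (length(rows) == 0L) return(emptyLocalizations()[, 1:8])
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# Gaussian blur whose kernel never exceeds the frame size
gblurSafe <- function(m, sigma) {
  r <- 2L * as.integer(ceiling(3 * sigma)) + 1L
  lim <- min(dim(m))
  if (r > lim) r <- lim - (1L - lim %% 2L)  # largest odd radius that fits
  EBImage::gblur(m, sigma = sigma, radius = r)
}

# strict 8-neighbor local maxima of a matrix (border excluded)
localMaxima2d <- function(m) {
  ny <- nrow(m); nx <- ncol(m)
  out <- matrix(FALSE, ny, nx)
  if (ny < 3L || nx < 3L) return(out)
  ic <- 2:(ny - 1L); jc <- 2:(nx - 1L)
  c0 <- m[ic, jc]
  ok <- c0 > m[ic - 1L, jc] & c0 > m[ic + 1L, jc] &
    c0 > m[ic, jc - 1L] & c0 > m[ic, jc + 1L] &
    c0 > m[ic - 1L, jc - 1L] & c0 > m[ic - 1L, jc + 1L] &
    c0 > m[ic + 1L, jc - 1L] & c0 > m[ic + 1L, jc + 1L]
  out[ic, jc] <- ok
  out
}

# least-squares symmetric 2D Gaussian + offset on one window;
# coordinates in pixel units with pixel centres at (i - 0.5)
fitGauss2d <- function(win, psfSigmaPx) {
  ny <- nrow(win); nx <- ncol(win)
  xs <- (seq_len(nx)) - 0.5
  ys <- (seq_len(ny)) - 0.5
  X <- matrix(xs, ny, nx, byrow = TRUE)
  Y <- matrix(ys, ny, nx)
  b0 <- min(win)
  A0 <- max(win) - b0
  if (A0 <= 0) return(NULL)
  wgt <- pmax(win - b0, 0)
  sw <- sum(wgt)
  x0 <- if (sw > 0) sum(X * wgt) / sw else mean(xs)
  y0 <- if (sw > 0) sum(Y * wgt) / sw else mean(ys)
  par0 <- c(A = A0, x0 = x0, y0 = y0, sigma = psfSigmaPx, b = b0)
  resid <- function(p) {
    as.numeric(p[1] * exp(-((X - p[2])^2 + (Y - p[3])^2) /
                            (2 * p[4]^2)) + p[5] - win)
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par = par0, fn = resid,
                       lower = c(0, 0, 0, 0.3, -Inf),
                       upper = c(Inf, nx, ny, 4 * psfSigmaPx, Inf),
                       control = minpack.lm::nls.lm.control(maxiter = 100)),
    error = function(e) NULL)
  if (is.null(fit) || fit$info %in% c(0L, 9L)) return(NULL)
  p <- fit$par
  if (p[1] <= 0 || p[4] <= 0.3 || p[4] >= 4 * psfSigmaPx) return(NULL)
  if (p[2] < 1 || p[2] > nx - 1 || p[3] < 1 || p[3] > ny - 1) return(NULL)
  list(A = p[[1]], x0 = p[[2]], y0 = p[[3]], sigma = p[[4]], b = p[[5]])
}
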