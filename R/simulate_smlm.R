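#' Configuration for the blinking-emitter SMLM simulator
#'
#' Parameters of [simulateSmlm()]. The default 2,000 frames are a
#' desk-scale stand-in for a typical 20,000-frame acquisition; frame count,
#' frame size and drift are all free parameters. The default raw pixel
#' size, 144 nm, is the object-plane pixel of a 16 um camera pixel behind
#' 111x total magnification (see [objectPixelSizeNm()]).
#'
#' @param nFrames number of camera frames (>= 1).
#' @param frameDimPx integer length-2 \code{(ny, nx)} raw frame size, px.
#' @param rawPixelNm raw pixel size on the object plane, nm.
#' @param nClusters number of disc-shaped emitter clusters.
#' @param clusterRadiusNm disc radius of one cluster, nm.
#' @param emittersPerCluster emitters per cluster.
#' @param meanStreakLen mean length (frames) of one emitter's consecutive
#'   on-streak; lengths are \code{1 + Poisson(meanStreakLen - 1)}.
#' @param sigmaLocNm isotropic localization noise sd, nm; also written to
#'   each record's \code{uncertainty} field.
#' @param driftNmPerFrame numeric length-2 \code{(x, y)} linear stage drift
#'   per frame, nm; cumulative drift at frame \code{f} is \code{f * rate}.
#' @param nFiducials number of fiducial beads, visible in every frame.
#' @param fiducialSigmaNm position jitter sd of fiducial detections, nm
#'   (small: beads are bright).
#' @param photonBudget mean photons per detection (Poisson).
#' @param psfSigmaPx PSF sigma in raw pixels (used when rendering raw
#'   frames and stored in the \code{sigma} field).
#' @param bgPhotons mean background photons per raw pixel (frame
#'   rendering only).
#' @param seed integer seed.
#' @return A validated list of class \code{SmlmSimConfig}.
#' @export
smlmSimConfig <- function(nFrames = 2000L,
                          frameDimPx = c(64L, 64L),
                          rawPixelNm = 144,
                          nClusters = 4L,
                          clusterRadiusNm = 60,
                          emittersPerCluster = 40L,
                          meanStreakLen = 3,
                          sigmaLocNm = 20,
                          driftNmPerFrame = c(0.5, 0),
                          nFiducials = 3L,
                          fiducialSigmaNm = 2,
                          photonBudget = 1000,
                          psfSigmaPx = 1.3,
                          bgPhotons = 2,
                          seed = 1L) {
  cfg <- list(nFrames = as.integer(nFrames),
              frameDimPx = as.integer(frameDimPx),
              rawPixelNm = rawPixelNm, nClusters = as.integer(nClusters),
              clusterRadiusNm = clusterRadiusNm,
              emittersPerCluster = as.integer(emittersPerCluster),
              meanStreakLen = meanStreakLen, sigmaLocNm = sigmaLocNm,
              driftNmPerFrame = as.numeric(driftNmPerFrame),
              nFiducials = as.integer(nFiducials),
              fiducialSigmaNm = fiducialSigmaNm,
              photonBudget = photonBudget, psfSigmaPx = psfSigmaPx,
              bgPhotons = bgPhotons, seed = as.integer(seed))
  class(cfg) <- "SmlmSimConfig"
  validateSmlmSimConfig(cfg)
  cfg
}

validateSmlmSimConfig <- function(cfg) {
  with(cfg, {
    if (nFrames < 1L) stop("nFrames must be >= 1")
    if (length(frameDimPx) != 2L || any(frameDimPx < 4L))
      stop("frameDimPx must be two integers >= 4")
    if (rawPixelNm <= 0) stop("rawPixelNm must be > 0")
    if (nClusters < 0L || emittersPerCluster < 0L || nFiducials < 0L)
      stop("counts must be >= 0")
    if (clusterRadiusNm < 0) stop("clusterRadiusNm must be >= 0")
    if (meanStreakLen < 1) stop("meanStreakLen must be >= 1")
    if (sigmaLocNm < 0 || fiducialSigmaNm < 0)
      stop("localization noise must be >= 0")
    if (photonBudget <= 0) stop("photonBudget must be > 0")
    if (psfSigmaPx <= 0) stop("psfSigmaPx must be > 0")
  })
  invisible(cfg)
}

emptyLocalizations <- function() {
  data.frame(frame = integer(0), x = numeric(0), y = numeric(0),
             uncertainty = numeric(0), sigma = numeric(0),
             photons = numeric(0), fiducial = logical(0),
             fiducialId = integer(0), emitterId = integer(0),
             clusterId = integer(0))
}

#' Simulate a single-molecule localization acquisition
#'
#' Emitters sit in disc-shaped clusters; each emitter switches on once and
#' emits on a streak of consecutive frames. An observed localization is the
#' true position plus the cumulative linear stage drift at its frame plus
#' isotropic Gaussian noise of sd \code{sigmaLocNm}; the record's
#' \code{uncertainty} field is set to \code{sigmaLocNm}. Fiducial beads are
#' localized in every frame with their own (smaller) jitter and are
#' flagged. Optionally the raw camera frames are rendered (Gaussian PSF,
#' Poisson counts) for the event-fitting path.
#'
#' @param cfg a [smlmSimConfig()] object.
#' @param renderFrames if \code{TRUE}, also return the raw frame stack as
#'   a \code{(ny, nx, nFrames)} photon-count array (emitters only; fiducial
#'   beads are not painted into rendered frames).
#' @return A list with \code{locs} (localization table: \code{frame}
#'   0-based, \code{x}, \code{y}, \code{uncertainty}, \code{sigma} in nm,
#'   \code{photons}, \code{fiducial}, \code{fiducialId}, \code{emitterId},
#'   \code{clusterId}), \code{truth} (emitter table with streak start and
#'   length, fiducial positions, per-frame drift trajectory with
#'   displacement 0 at frame 0), and optionally \code{frames}.
#' @examples
#' cfg <- smlmSimConfig(nFrames = 50L, nClusters = 1L,
#'                      emittersPerCluster = 5L, sigmaLocNm = 0,
#'                      driftNmPerFrame = c(0, 0))
#' sim <- simulateSmlm(cfg)
#' nrow(sim$locs)  # sum of streak lengths + fiducial records
#' @export
simulateSmlm <- function(cfg, renderFrames = FALSE) {
  stopifnot(inherits(cfg, "SmlmSimConfig"))
  validateSmlmSimConfig(cfg)
  set.seed(cfg$seed)

  extent <- cfg$frameDimPx * cfg$rawPixelNm  # (y, x) nm
  frames0 <- 0:(cfg$nFrames - 1L)
  drift <- cbind(dx = frames0 * cfg$driftNmPerFrame[1],
                 dy = frames0 * cfg$driftNmPerFrame[2])

  # cluster centres and emitters (uniform in a disc), margin keeps
  # clusters + drift inside the frame
  margin <- 0.15 * min(extent) + cfg$clusterRadiusNm +
    max(abs(drift)) + 4 * cfg$sigmaLocNm
  nEm <- cfg$nClusters * cfg$emittersPerCluster
  emitters <- data.frame(emitterId = integer(0), clusterId = integer(0),
                         x = numeric(0), y = numeric(0),
                         startFrame = integer(0), streakLen = integer(0))
  if (nEm > 0L) {
    cx <- margin + stats::runif(cfg$nClusters) * (extent[2] - 2 * margin)
    cy <- margin + stats::runif(cfg$nClusters) * (extent[1] - 2 * margin)
    th <- stats::runif(nEm, 0, 2 * pi)
    rr <- cfg$clusterRadiusNm * sqrt(stats::runif(nEm))
    cl <- rep(seq_len(cfg$nClusters), each = cfg$emittersPerCluster)
    start <- sample.int(cfg$nFrames, nEm, replace = TRUE) - 1L
    len <- 1L + stats::rpois(nEm, cfg$meanStreakLen - 1)
    len <- pmin(len, cfg$nFrames - start)
    emitters <- data.frame(emitterId = seq_len(nEm), clusterId = cl,
                           x = cx[cl] + rr * cos(th),
                           y = cy[cl] + rr * sin(th),
                           startFrame = start, streakLen = len)
  }

  fiducials <- data.frame(fiducialId = integer(0), x = numeric(0),
                          y = numeric(0))
  if (cfg$nFiducials > 0L)
    fiducials <- data.frame(
      fiducialId = seq_len(cfg$nFiducials),
      x = margin + stats::runif(cfg$nFiducials) * (extent[2] - 2 * margin),
      y = margin + stats::runif(cfg$nFiducials) * (extent[1] - 2 * margin))

  # observed emitter records
  emRec <- emptyLocalizations()
  if (nEm > 0L) {
    reps <- emitters$streakLen
    fr <- unlist(mapply(function(s, l) s + 0:(l - 1L), emitters$startFrame,
                        reps, SIMPLIFY = FALSE), use.names = FALSE)
    id <- rep(emitters$emitterId, reps)
    n <- length(fr)
    emRec <- data.frame(
      frame = as.integer(fr),
      x = emitters$x[id] + drift[fr + 1L, "dx"] +
        stats::rnorm(n, 0, cfg$sigmaLocNm),
      y = emitters$y[id] + drift[fr + 1L, "dy"] +
        stats::rnorm(n, 0, cfg$sigmaLocNm),
      uncertainty = cfg$sigmaLocNm,
      sigma = cfg$psfSigmaPx * cfg$rawPixelNm,
      photons = stats::rpois(n, cfg$photonBudget),
      fiducial = FALSE, fiducialId = NA_integer_,
      emitterId = id, clusterId = emitters$clusterId[id])
  }

  # fiducial records: one per bead per frame
  fidRec <- emptyLocalizations()
  if (cfg$nFiducials > 0L) {
    fr <- rep(frames0, times = cfg$nFiducials)
    id <- rep(fiducials$fiducialId, each = cfg$nFrames)
    n <- length(fr)
    fidRec <- data.frame(
      frame = as.integer(fr),
      x = fiducials$x[id] + drift[fr + 1L, "dx"] +
        stats::rnorm(n, 0, cfg$fiducialSigmaNm),
      y = fiducials$y[id] + drift[fr + 1L, "dy"] +
        stats::rnorm(n, 0, cfg$fiducialSigmaNm),
      uncertainty = cfg$fiducialSigmaNm,
      sigma = cfg$psfSigmaPx * cfg$rawPixelNm,
      photons = stats::rpois(n, 10 * cfg$photonBudget),
      fiducial = TRUE, fiducialId = id,
      emitterId = NA_integer_, clusterId = NA_integer_)
  }

  locs <- rbind(emRec, fidRec)
  locs <- locs[order(locs$frame, locs$fiducial, locs$emitterId,
                     locs$fiducialId), , drop = FALSE]
  rownames(locs) <- NULL

  out <- list(locs = locs,
              truth = list(emitters = emitters, fiducials = fiducials,
                           drift = data.frame(frame = frames0, drift)))

  if (renderFrames) {
    ny <- cfg$frameDimPx[1]; nx <- cfg$frameDimPx[2]
    frames <- array(0, dim = c(ny, nx, cfg$nFrames))
    px <- cfg$rawPixelNm
    s <- cfg$psfSigmaPx
    w <- ceiling(4 * s)
    em <- emRec  # true emitter signal uses true (drifted) positions
    if (nrow(em) > 0L) {
      for (i in seq_len(nrow(em))) {
        cxp <- em$x[i] / px; cyp <- em$y[i] / px  # px units, origin corner
        c0 <- max(1L, floor(cxp - w)); c1 <- min(nx, ceiling(cxp + w))
        r0 <- max(1L, floor(cyp - w)); r1 <- min(ny, ceiling(cyp + w))
        if (c0 > c1 || r0 > r1) next
        gx <- exp(-(((c0:c1) - 0.5) - cxp)^2 / (2 * s^2))
        gy <- exp(-(((r0:r1) - 0.5) - cyp)^2 / (2 * s^2))
        psf <- outer(gy, gx) / (2 * pi * s^2)
        fidx <- em$frame[i] + 1L
        frames[r0:r1, c0:c1, fidx] <- frames[r0:r1, c0:c1, fidx] +
          em$photons[i] * psf
      }
    }
    frames <- frames + cfg$bgPhotons
    frames[] <- stats::rpois(length(frames), frames)
    out$frames <- frames
  }
  out
}

#' Object-plane pixel size of a camera behind a magnifying system
#'
#' @param cameraPixelUm physical camera pixel size, um (e.g. 16 for a
#'   typical EM-CCD).
#' @param magnification total optical magnification (e.g. 111).
#' @return Pixel size on the object plane, nm: \code{cameraPixelUm * 1000 /
#'   magnification}; 16 um behind 111x gives ~144 nm.
#' @export
objectPixelSizeNm <- function(cameraPixelUm, magnification) {
  stopifnot(cameraPixelUm > 0, magnification > 0)
  cameraPixelUm * 1000 / magnification
}
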