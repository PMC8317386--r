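#' Configuration for the immunofluorescence Z-stack simulator
#'
#' Bundles and validates the parameters of [simulateIfStack()]. Defaults are
#' desk-scale: a 30 x 256 x 256 voxel stack at the package's widefield
#' calibration (0.23 um focal step, 0.1 um pixels); acquisition-scale stacks
#' (60 x 1024 x 1344) are reachable by changing \code{dim} only.
#'
#' @param dim integer length-3, stack shape \code{(Z, Y, X)} in voxels.
#' @param voxelSize numeric length-3, \code{(dz, dy, dx)} in um.
#' @param nNuclei number of nuclei to place (0 gives a blank stack).
#' @param semiAxesUm 3 x 2 matrix of per-axis semi-axis ranges (rows z, y,
#'   x; columns min, max) in um. Nuclei are axis-aligned ellipsoids, so the
#'   true volume of each nucleus is the closed form \code{4/3 pi a b c}.
#' @param fociPerNucleus foci per nucleus per marker channel (default 4,
#'   the near-tetraploid chromosome-7 copy number of U2OS cells).
#' @param focusSigmaUm isotropic Gaussian sigma of one focus, um. Blobs are
#'   truncated at 3 sigma, matching diffraction-limited spot appearance
#'   while keeping the integrated signal analytic.
#' @param fociMinSepUm minimum distance between focus centres within a
#'   nucleus, um (keeps simulated spots resolvable).
#' @param enrichment focus enrichment \code{e}: the peak focus amplitude
#'   added on top of the intra-nuclear marker background, as a fold of that
#'   background (so the peak intensity is \code{(1 + e) * background}). One
#'   value recycled over marker channels. Default 5, the regime of bright
#'   tethered-protein foci whose measured normalized densities reach ~5.
#' @param delta fractional reduction of marker enrichment in the treated
#'   group (\code{0 <= delta < 1}); treated foci have enrichment
#'   \code{e * (1 - delta)}.
#' @param group \code{"control"} or \code{"treated"}; selects whether
#'   \code{delta} is applied.
#' @param nMarkerChannels number of marker channels after the DNA channel.
#' @param nucleusIntensity mean DNA-channel intensity inside nuclei (a.u.).
#' @param markerBackground intra-nuclear marker-channel background (a.u.).
#' @param background extra-nuclear intensity on all channels (a.u.).
#' @param textureAmplitude relative sd of the low-frequency multiplicative
#'   intensity field applied to the DNA channel inside nuclei.
#' @param textureSigmaUm correlation length of that field, um.
#' @param psfSigmaUm numeric length-3 \code{(z, y, x)} Gaussian PSF sigmas
#'   in um; \code{c(0, 0, 0)} disables blurring.
#' @param poissonGain camera gain of the Poisson shot-noise stage
#'   (photons per intensity unit are \code{1/gain}); 0 disables shot noise.
#' @param readNoiseSd additive Gaussian read noise sd (a.u.); 0 disables.
#' @param seed integer seed; identical config + seed gives bit-identical
#'   stacks.
#' @return A validated list of class \code{StackSimConfig}.
#' @seealso [simulateIfStack()]
#' @export
stackSimConfig <- function(dim = c(30L, 256L, 256L),
                           voxelSize = c(0.23, 0.1, 0.1),
                           nNuclei = 4L,
                           semiAxesUm = rbind(z = c(1.4, 1.8),
                                              y = c(2.0, 2.6),
                                              x = c(2.0, 2.6)),
                           fociPerNucleus = 4L,
                           focusSigmaUm = 0.2,
                           fociMinSepUm = 0.8,
                           enrichment = 5,
                           delta = 0,
                           group = c("control", "treated"),
                           nMarkerChannels = 1L,
                           nucleusIntensity = 100,
                           markerBackground = 50,
                           background = 5,
                           textureAmplitude = 0.1,
                           textureSigmaUm = 1.5,
                           psfSigmaUm = c(0.3, 0.09, 0.09),
                           poissonGain = 1,
                           readNoiseSd = 2,
                           seed = 1L) {
  group <- match.arg(group)
  cfg <- list(dim = as.integer(dim), voxelSize = as.numeric(voxelSize),
              nNuclei = as.integer(nNuclei),
              semiAxesUm = matrix(as.numeric(semiAxesUm), nrow = 3L,
                                  dimnames = list(c("z", "y", "x"),
                                                  c("min", "max"))),
              fociPerNucleus = as.integer(fociPerNucleus),
              focusSigmaUm = focusSigmaUm, fociMinSepUm = fociMinSepUm,
              enrichment = rep_len(enrichment, nMarkerChannels),
              delta = delta, group = group,
              nMarkerChannels = as.integer(nMarkerChannels),
              nucleusIntensity = nucleusIntensity,
              markerBackground = markerBackground, background = background,
              textureAmplitude = textureAmplitude,
              textureSigmaUm = textureSigmaUm,
              psfSigmaUm = as.numeric(psfSigmaUm),
              poissonGain = poissonGain, readNoiseSd = readNoiseSd,
              seed = as.integer(seed))
  class(cfg) <- "StackSimConfig"
  validateStackSimConfig(cfg)
  cfg
}

validateStackSimConfig <- function(cfg) {
  with(cfg, {
    if (length(dim) != 3L || any(dim < 1L)) stop("dim must be 3 positive integers")
    if (any(voxelSize <= 0)) stop("voxelSize must be positive")
    if (nNuclei < 0L) stop("nNuclei must be >= 0")
    if (any(semiAxesUm <= 0) || any(semiAxesUm[, 2] < semiAxesUm[, 1]))
      stop("semiAxesUm must hold positive (min, max) ranges")
    if (fociPerNucleus < 0L) stop("fociPerNucleus must be >= 0")
    if (focusSigmaUm <= 0) stop("focusSigmaUm must be > 0")
    if (any(enrichment <= 0)) stop("enrichment must be > 0")
    if (delta < 0 || delta >= 1) stop("delta must satisfy 0 <= delta < 1")
    if (fociPerNucleus > 0L &&
        min(semiAxesUm[, 1]) <= 3 * focusSigmaUm)
      stop("foci (3 sigma radius) do not fit inside the smallest nucleus")
    if (nucleusIntensity <= 0 || markerBackground <= 0 || background < 0)
      stop("intensities must be non-negative (nucleus and marker > 0)")
    if (poissonGain < 0 || readNoiseSd < 0) stop("noise parameters must be >= 0")
  })
  invisible(cfg)
}

#' Simulate a multichannel immunofluorescence Z-stack with ground truth
#'
#' Generates a calibrated [VoxelGrid-class] with a DNA channel and
#' \code{nMarkerChannels} marker channels. Nuclei are axis-aligned
#' ellipsoids with a smooth multiplicative interior texture; each marker
#' channel carries, per nucleus, \code{fociPerNucleus} isotropic Gaussian
#' foci whose amplitude over the intra-nuclear marker background is
#' \code{enrichment} (treated group: \code{enrichment * (1 - delta)})
#' times that background, so the mean ground-truth enrichment of treated
#' over control foci is exactly \code{1 - delta}. The stack is blurred by
#' a Gaussian PSF, then degraded by Poisson shot noise and Gaussian read
#' noise.
#'
#' @param cfg a [stackSimConfig()] object.
#' @param maxPlacementTries placement retries per nucleus before giving up
#'   with a placement error.
#' @return A list with elements \code{grid} (the [VoxelGrid-class]; channel
#'   names \code{"dna"}, \code{"marker1"}, ...) and \code{truth}, a list of
#'   data frames: \code{nuclei} (centres and semi-axes in um, analytic
#'   volume, group) and \code{foci} (per-focus centre, sigma, amplitude and
#'   enrichment). Truth rows are index-aligned with generation order.
#' @examples
#' cfg <- stackSimConfig(dim = c(16L, 64L, 64L), nNuclei = 1L,
#'                       semiAxesUm = rbind(c(1.2, 1.2), c(1.6, 1.6),
#'                                          c(1.6, 1.6)),
#'                       poissonGain = 0, readNoiseSd = 0)
#' sim <- simulateIfStack(cfg)
#' sim$truth$nuclei$volumeUm3  # 4/3 * pi * 1.2 * 1.6^2
#' @export
simulateIfStack <- function(cfg, maxPlacementTries = 200L) {
  stopifnot(inherits(cfg, "StackSimConfig"))
  validateStackSimConfig(cfg)
  set.seed(cfg$seed)

  d <- cfg$dim
  vs <- cfg$voxelSize
  extentUm <- d * vs
  nCh <- 1L + cfg$nMarkerChannels
  chNames <- c("dna", if (cfg$nMarkerChannels > 0L)
    paste0("marker", seq_len(cfg$nMarkerChannels)))

  # voxel-centre coordinates (um)
  zc <- (seq_len(d[1]) - 0.5) * vs[1]
  yc <- (seq_len(d[2]) - 0.5) * vs[2]
  xc <- (seq_len(d[3]) - 0.5) * vs[3]

  data <- array(cfg$background, dim = c(d, nCh))

  # --- place nuclei without overlap -----------------------------------
  nuclei <- data.frame(nucleus = integer(0), zUm = numeric(0),
                       yUm = numeric(0), xUm = numeric(0),
                       azUm = numeric(0), ayUm = numeric(0),
                       axUm = numeric(0), volumeUm3 = numeric(0),
                       group = character(0))
  if (cfg$nNuclei > 0L) {
    centres <- matrix(NA_real_, cfg$nNuclei, 3L)
    axes <- matrix(NA_real_, cfg$nNuclei, 3L)
    for (i in seq_len(cfg$nNuclei)) {
      ax <- cfg$semiAxesUm[, 1] +
        stats::runif(3) * (cfg$semiAxesUm[, 2] - cfg$semiAxesUm[, 1])
      placed <- FALSE
      for (try in seq_len(maxPlacementTries)) {
        # keep the ellipsoid and its PSF tail off the stack border
        margin <- ax + 3 * cfg$psfSigmaUm + vs
        if (any(extentUm - 2 * margin <= 0))
          stop("nuclei do not fit inside the stack")
        ctr <- margin + stats::runif(3) * (extentUm - 2 * margin)
        ok <- TRUE
        if (i > 1L) {
          for (j in seq_len(i - 1L)) {
            # conservative axis-aligned separation test on summed semi-axes
            s <- (ctr - centres[j, ]) / (ax + axes[j, ])
            if (sum(s^2) <= 1) { ok <- FALSE; break }
          }
        }
        if (ok) { centres[i, ] <- ctr; axes[i, ] <- ax; placed <- TRUE; break }
      }
      if (!placed)
        stop("could not place ", cfg$nNuclei, " non-overlapping nuclei in ",
             maxPlacementTries, " tries; enlarge the stack or shrink nuclei")
    }
    nuclei <- data.frame(nucleus = seq_len(cfg$nNuclei),
                         zUm = centres[, 1], yUm = centres[, 2],
                         xUm = centres[, 3],
                         azUm = axes[, 1], ayUm = axes[, 2], axUm = axes[, 3],
                         volumeUm3 = 4 / 3 * pi * axes[, 1] * axes[, 2] *
                           axes[, 3],
                         group = cfg$group)
  }

  # low-frequency multiplicative texture for the DNA channel
  texture <- NULL
  if (cfg$nNuclei > 0L && cfg$textureAmplitude > 0) {
    noise <- array(stats::rnorm(prod(d)), dim = d)
    sm <- gauss3d(noise, cfg$textureSigmaUm / vs)
    sm <- sm / stats::sd(sm)
    texture <- pmax(1 + cfg$textureAmplitude * sm, 0.2)
  }

  # --- paint nuclei ----------------------------------------------------
  for (i in seq_len(nrow(nuclei))) {
    ctr <- c(nuclei$zUm[i], nuclei$yUm[i], nuclei$xUm[i])
    ax <- c(nuclei$azUm[i], nuclei$ayUm[i], nuclei$axUm[i])
    zi <- which(abs(zc - ctr[1]) <= ax[1])
    yi <- which(abs(yc - ctr[2]) <= ax[2])
    xi <- which(abs(xc - ctr[3]) <= ax[3])
    ez <- ((zc[zi] - ctr[1]) / ax[1])^2
    ey <- ((yc[yi] - ctr[2]) / ax[2])^2
    ex <- ((xc[xi] - ctr[3]) / ax[3])^2
    inside <- outer(outer(ez, ey, `+`), ex, `+`) <= 1
    dna <- data[zi, yi, xi, 1L]
    body <- cfg$nucleusIntensity
    if (!is.null(texture)) body <- body * texture[zi, yi, xi]
    dna[inside] <- (if (is.matrix(body) || is.array(body))
      body[inside] else body)
    data[zi, yi, xi, 1L] <- dna
    for (m in seq_len(cfg$nMarkerChannels)) {
      mk <- data[zi, yi, xi, 1L + m]
      mk[inside] <- cfg$markerBackground
      data[zi, yi, xi, 1L + m] <- mk
    }
  }

  # --- foci ------------------------------------------------------------
  eEff <- cfg$enrichment * (1 - if (cfg$group == "treated") cfg$delta else 0)
  foci <- NULL
  if (nrow(nuclei) > 0L && cfg$fociPerNucleus > 0L &&
      cfg$nMarkerChannels > 0L) {
    rows <- list()
    sg <- cfg$focusSigmaUm
    for (i in seq_len(nrow(nuclei))) {
      ctr <- c(nuclei$zUm[i], nuclei$yUm[i], nuclei$xUm[i])
      ax <- c(nuclei$azUm[i], nuclei$ayUm[i], nuclei$axUm[i])
      inner <- ax - 3 * sg
      for (m in seq_len(cfg$nMarkerChannels)) {
        pts <- matrix(NA_real_, cfg$fociPerNucleus, 3L)
        for (f in seq_len(cfg$fociPerNucleus)) {
          ok <- FALSE
          for (try in 1:500) {
            u <- stats::rnorm(3)
            u <- u / sqrt(sum(u^2)) * stats::runif(1)^(1 / 3)
            p <- ctr + u * inner
            if (f == 1L ||
                all(sqrt(colSums((t(pts[seq_len(f - 1L), , drop = FALSE]) -
                                  p)^2)) >= cfg$fociMinSepUm)) {
              pts[f, ] <- p; ok <- TRUE; break
            }
          }
          if (!ok)
            stop("could not place ", cfg$fociPerNucleus, " foci at least ",
                 cfg$fociMinSepUm, " um apart inside nucleus ", i)
        }
        amp <- eEff[m] * cfg$markerBackground
        for (f in seq_len(cfg$fociPerNucleus)) {
          p <- pts[f, ]
          zi <- which(abs(zc - p[1]) <= 3 * sg)
          yi <- which(abs(yc - p[2]) <= 3 * sg)
          xi <- which(abs(xc - p[3]) <= 3 * sg)
          r2 <- outer(outer((zc[zi] - p[1])^2, (yc[yi] - p[2])^2, `+`),
                      (xc[xi] - p[3])^2, `+`)
          blob <- amp * exp(-r2 / (2 * sg^2))
          blob[r2 > (3 * sg)^2] <- 0
          data[zi, yi, xi, 1L + m] <- data[zi, yi, xi, 1L + m] + blob
          rows[[length(rows) + 1L]] <- data.frame(
            nucleus = i, channel = paste0("marker", m), focus = f,
            zUm = p[1], yUm = p[2], xUm = p[3], sigmaUm = sg,
            amplitude = amp, enrichment = eEff[m], group = cfg$group)
        }
      }
    }
    foci <- do.call(rbind, rows)
  }
  if (is.null(foci))
    foci <- data.frame(nucleus = integer(0), channel = character(0),
                       focus = integer(0), zUm = numeric(0), yUm = numeric(0),
                       xUm = numeric(0), sigmaUm = numeric(0),
                       amplitude = numeric(0), enrichment = numeric(0),
                       group = character(0))

  # --- PSF and noise ---------------------------------------------------
  if (any(cfg$psfSigmaUm > 0)) {
    for (ch in seq_len(nCh))
      data[, , , ch] <- gauss3d(data[, , , ch], cfg$psfSigmaUm / vs)
  }
  if (cfg$poissonGain > 0) {
    lam <- data / cfg$poissonGain
    data <- array(stats::rpois(length(lam), lam) * cfg$poissonGain,
                  dim = dim(data))
  }
  if (cfg$readNoiseSd > 0)
    data <- data + array(stats::rnorm(length(data), 0, cfg$readNoiseSd),
                         dim = dim(data))
  data[data < 0] <- 0

  list(grid = VoxelGrid(data, voxelSize = vs, channelNames = chNames),
       truth = list(nuclei = nuclei, foci = foci))
}
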