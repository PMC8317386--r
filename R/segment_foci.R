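#' Segment intranuclear foci (spot segmentation)
#'
#' Detects diffraction-limited foci inside previously segmented nuclei.
#' Per nucleus: the channel is band-passed with a Laplacian-of-Gaussian at
#' the expected focus scale; seeds are 26-connected local maxima of the
#' smoothed intensity above an adaptive per-nucleus threshold
#' (median + \code{k} robust SDs of the intra-nuclear intensity, robust
#' SD = 1.4826 MAD); touching foci are split by a seeded watershed on the
#' inverted smoothed intensity; each focus then keeps the voxels above
#' half of its peak height over the nuclear background (an FWHM-style
#' extent rule, so focus masks are comparable across staining
#' intensities); finally a minimum-size filter applies. Every focus is
#' assigned to the nucleus containing its intensity-weighted centroid and
#' clipped to it; foci outside any nucleus are discarded.
#'
#' All thresholds are relative to per-nucleus location/scale statistics,
#' so the segmentation is invariant under positive rescaling of the
#' intensities.
#'
#' @param grid a [VoxelGrid-class].
#' @param channel focus channel name or index (missing channel raises a
#'   schema error).
#' @param nuclei result of [segmentNuclei()], or a bare nucleus label
#'   array.
#' @param focusSigmaUm expected focus scale (Gaussian sigma), um.
#' @param k adaptive seed-threshold constant (default 3).
#' @param kLow candidate-region constant: voxels above
#'   median + \code{kLow} robust SDs may join a focus.
#' @param peakFraction focus extent: keep voxels above background +
#'   \code{peakFraction} x (peak - background); 0.5 = FWHM.
#' @param minVoxels minimum focus size kept, voxels.
#' @return A list with \code{labels} (integer focus label array, contiguous
#'   1..K) and \code{records}, one row per focus: \code{label},
#'   \code{nucleus} (parent label), \code{channel}, \code{voxelCount},
#'   \code{volumeUm3}, \code{signal} (integrated raw intensity),
#'   \code{meanIntensity}, and the intensity-weighted centroid
#'   \code{centroid_z/y/x} in um.
#' @seealso [segmentNuclei()], [normalizedDensity()]
#' @export
segmentFoci <- function(grid, channel, nuclei, focusSigmaUm = 0.2, k = 3,
                        kLow = 1.5, peakFraction = 0.5, minVoxels = 5L) {
  stopifnot(is(grid, "VoxelGrid"))
  ch <- channelData(grid, channel)
  chName <- channelNames(grid)[resolveChannel(grid, channel)]
  nucLab <- if (is.list(nuclei)) nuclei$labels else nuclei
  d <- dim(ch)
  stopifnot(all(dim(nucLab) == d))
  vs <- voxelSize(grid)

  out <- list(labels = array(0L, dim = d), records = emptyFocusRecords())
  nucIds <- sort(unique(nucLab[nucLab > 0L]))
  if (length(nucIds) == 0L) return(out)

  sigmaVox <- pmax(focusSigmaUm / vs, 0.5)
  sm <- gauss3d(ch, sigmaVox / 2)            # light denoising
  log3 <- -laplacian3d(gauss3d(ch, sigmaVox), vs)  # band-pass at focus scale
  localMax <- cpp_local_maxima(sm, d)

  marker <- array(0L, dim = d)
  marker[] <- -1L
  seedPeak <- numeric(0)
  seedBg <- numeric(0)
  nextLab <- 0L
  for (nid in nucIds) {
    inNuc <- nucLab == nid
    v <- sm[inNuc]
    med <- stats::median(v)
    rsd <- robustSd(v)
    seedThr <- med + k * rsd
    seedIdx <- which(inNuc & localMax & sm >= seedThr & sm > med & log3 > 0)
    if (length(seedIdx) == 0L) next
    cand <- inNuc & sm >= med + kLow * rsd & sm > med
    marker[cand] <- 0L
    labs <- nextLab + seq_along(seedIdx)
    marker[seedIdx] <- labs
    seedPeak[labs] <- sm[seedIdx]
    seedBg[labs] <- med
    nextLab <- nextLab + length(seedIdx)
  }
  if (nextLab == 0L) return(out)

  lab <- cpp_watershed3d(-sm, marker, d)

  # FWHM-style extent: per focus, keep voxels above bg + frac*(peak - bg)
  pos <- which(lab > 0L)
  li <- lab[pos]
  cut <- seedBg[li] + peakFraction * (seedPeak[li] - seedBg[li])
  dropVox <- sm[pos] < cut
  lab[pos[dropVox]] <- 0L

  # size filter, centroid, nucleus assignment
  pos <- which(lab > 0L)
  if (length(pos) == 0L) return(out)
  li <- lab[pos]
  counts <- tabulate(li, nbins = nextLab)
  keep <- which(counts >= minVoxels)
  if (length(keep) == 0L) return(out)

  rows <- list()
  final <- array(0L, dim = d)
  outLab <- 0L
  arrInd <- arrayInd(pos, d)
  for (fl in keep) {
    sel <- li == fl
    vox <- pos[sel]
    ai <- arrInd[sel, , drop = FALSE]
    w <- pmax(ch[vox] - seedBg[fl], 1e-12)
    centroidVox <- colSums(ai * w) / sum(w)       # 1-based voxel units
    centroidUm <- (centroidVox - 0.5) * vs
    nucAt <- nucLab[matrix(pmin(pmax(round(centroidVox), 1L), d), nrow = 1L)]
    if (is.na(nucAt) || nucAt == 0L) next         # focus outside any nucleus
    inside <- nucLab[vox] == nucAt
    vox <- vox[inside]
    ai <- ai[inside, , drop = FALSE]
    if (length(vox) < minVoxels) next
    outLab <- outLab + 1L
    final[vox] <- outLab
    rows[[outLab]] <- data.frame(
      label = outLab, nucleus = as.integer(nucAt), channel = chName,
      voxelCount = length(vox),
      volumeUm3 = measureVolume(length(vox), vs),
      signal = sum(ch[vox]),
      meanIntensity = mean(ch[vox]),
      centroid_z = centroidUm[1], centroid_y = centroidUm[2],
      centroid_x = centroidUm[3])
  }
  if (outLab == 0L) return(out)
  list(labels = final, records = do.call(rbind, rows))
}

emptyFocusRecords <- function() {
  data.frame(label = integer(0), nucleus = integer(0), channel = character(0),
             voxelCount = integer(0), volumeUm3 = numeric(0),
             signal = numeric(0), meanIntensity = numeric(0),
             centroid_z = numeric(0), centroid_y = numeric(0),
             centroid_x = numeric(0))
}
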