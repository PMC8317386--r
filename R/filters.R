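# Internal 3D filtering helpers built on the compiled primitives.
# All sigmas here are in voxel units, one per axis (z, y, x); callers
# convert from micrometres using the grid calibration so that physical
# smoothing scales are isotropic on anisotropic grids.

gaussKernel1d <- function(sigma) {
  if (sigma <= 0) return(1)
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# separable Gaussian smoothing of a 3D (z, y, x) array
gauss3d <- function(a, sigmaVox) {
  d <- dim(a)
  stopifnot(length(d) == 3L, length(sigmaVox) == 3L)
  out <- a
  for (axis in 0:2) {
    s <- sigmaVox[axis + 1L]
    if (s > 0 && d[axis + 1L] > 1L)
      out <- cpp_convolve_axis(out, d, gaussKernel1d(s), axis)
  }
  array(out, dim = d)
}

# central-difference gradient magnitude in physical units (a.u. per um)
gradientMagnitude3d <- function(a, voxelSizeUm) {
  d <- dim(a)
  g2 <- array(0, dim = d)
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 2L) next
    hi <- a[slabIndex(d, axis, pmin(seq_len(n) + 1L, n))]
    lo <- a[slabIndex(d, axis, pmax(seq_len(n) - 1L, 1L))]
    # one-sided at the faces (denominator 1 step), central inside (2 steps)
    steps <- pmin(seq_len(n) + 1L, n) - pmax(seq_len(n) - 1L, 1L)
    h <- array(0, dim = d)
    h[] <- hi - lo
    den <- stepArray(d, axis, steps) * voxelSizeUm[axis]
    g2 <- g2 + (h / den)^2
  }
  sqrt(g2)
}

# discrete Laplacian with per-axis spacing; negated LoG is -laplacian(smoothed)
laplacian3d <- function(a, voxelSizeUm) {
  d <- dim(a)
  out <- array(0, dim = d)
  for (axis in 1:3) {
    n <- d[axis]
    if (n < 3L) next
    hi <- a[slabIndex(d, axis, pmin(seq_len(n) + 1L, n))]
    lo <- a[slabIndex(d, axis, pmax(seq_len(n) - 1L, 1L))]
    out <- out + (array(hi, d) + array(lo, d) - 2 * a) / voxelSizeUm[axis]^2
  }
  out
}

# index helper: full array indexed with positions `pos` substituted on `axis`
slabIndex <- function(d, axis, pos) {
  idx <- list(seq_len(d[1]), seq_len(d[2]), seq_len(d[3]))
  idx[[axis]] <- pos
  array(seq_len(prod(d)), dim = d)[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
}

stepArray <- function(d, axis, steps) {
  perm <- c(axis, setdiff(1:3, axis))
  a <- array(steps, dim = d[perm])
  aperm(a, order(perm))
}

# Otsu threshold, computed on the min-max normalized data so the rule is
# exactly invariant under positive rescaling of intensities
otsuThreshold <- function(v) {
  v <- as.numeric(v)
  lo <- min(v); hi <- max(v)
  if (!is.finite(lo) || !is.finite(hi) || hi <= lo) return(NA_real_)
  u <- (v - lo) / (hi - lo)
  t <- EBImage::otsu(matrix(u, ncol = 1L), range = c(0, 1), levels = 256L)
  lo + t * (hi - lo)
}

# robust scale: 1.4826 * median absolute deviation
robustSd <- function(v) stats::mad(v, constant = 1.4826)

# 2D per-slice hole filling of a label map (z is the first axis)
fillHolesSlices <- function(lab) {
  d <- dim(lab)
  for (z in seq_len(d[1])) {
    sl <- lab[z, , ]
    if (any(sl > 0))
      lab[z, , ] <- EBImage::fillHull(sl)
  }
  lab
}
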