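#' @useDynLib FociQuant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
NULL

#' VoxelGrid: a calibrated multichannel 3D intensity stack
#'
#' The central image container of the package. Intensities are stored as a
#' 4-dimensional array in \code{(z, y, x, channel)} order; the physical size
#' of one voxel is carried alongside so that all downstream volumes are
#' reported in cubic micrometres. Voxel indices are interpreted with the
#' origin at the top-left corner of voxel \code{[1, 1, 1]}; the centre of
#' voxel \code{i} along an axis with spacing \code{s} lies at
#' \code{(i - 0.5) * s} micrometres.
#'
#' @slot data numeric 4D array, \code{Z x Y x X x C}, non-negative
#'   intensities (arbitrary units).
#' @slot voxelSize numeric length-3, \code{(dz, dy, dx)} in micrometres.
#'   The package default, \code{c(0.23, 0.1, 0.1)}, matches a widefield
#'   Z-stack acquired at 0.23 um focal steps with 0.1 um pixels.
#' @slot channelNames character, one name per channel.
#'
#' @seealso [VoxelGrid()] for the constructor, [readStack()] /
#'   [writeStack()] for TIFF I/O, [segmentNuclei()] and [segmentFoci()].
#' @exportClass VoxelGrid
setClass("VoxelGrid",
  representation(
    data = "array",
    voxelSize = "numeric",
    channelNames = "character"
  )
)

setValidity("VoxelGrid", function(object) {
  d <- object@data
  if (length(dim(d)) != 4L)
    return("data must be a 4D array (z, y, x, channel)")
  if (anyNA(d)) return("data must not contain NA")
  if (any(d < 0)) return("all intensities must be >= 0")
  vs <- object@voxelSize
  if (length(vs) != 3L || anyNA(vs) || any(vs <= 0))
    return("voxelSize must be 3 positive numbers (dz, dy, dx) in um")
  if (length(object@channelNames) != dim(d)[4L])
    return("channelNames length must equal the number of channels")
  if (anyDuplicated(object@channelNames))
    return("channelNames must be unique")
  TRUE
})

#' Construct a VoxelGrid
#'
#' @param data numeric array. Either 4D \code{(z, y, x, channel)} or 3D
#'   \code{(z, y, x)} for a single channel.
#' @param voxelSize numeric length-3, voxel spacing \code{(dz, dy, dx)} in
#'   micrometres.
#' @param channelNames character vector of channel names; defaults to
#'   \code{"ch1"}, \code{"ch2"}, ...
#' @return A [VoxelGrid-class] object.
#' @examples
#' g <- VoxelGrid(array(1, dim = c(4, 8, 8)), voxelSize = c(0.23, 0.1, 0.1))
#' dim(g)
#' @export
VoxelGrid <- function(data, voxelSize = c(0.23, 0.1, 0.1),
                      channelNames = NULL) {
  if (length(dim(data)) == 3L)
    dim(data) <- c(dim(data), 1L)
  if (is.null(channelNames))
    channelNames <- paste0("ch", seq_len(dim(data)[4L]))
  new("VoxelGrid", data = data, voxelSize = as.numeric(voxelSize),
      channelNames = as.character(channelNames))
}

#' SuperResImage: a rendered super-resolution canvas
#'
#' A 2D intensity grid produced by [renderSuperRes()]. The canvas covers
#' the raw camera frame at a finer pixel pitch (raw pixel size divided by
#' the upsampling factor); physical coordinates in nanometres share the
#' raw-frame origin (top-left corner of pixel (0,0)).
#'
#' @slot data numeric matrix (rows = y, columns = x), non-negative.
#' @slot pixelSizeNm positive scalar, canvas pixel pitch in nanometres.
#' @exportClass SuperResImage
setClass("SuperResImage",
  representation(data = "matrix", pixelSizeNm = "numeric")
)

setValidity("SuperResImage", function(object) {
  if (anyNA(object@data)) return("data must not contain NA")
  if (any(object@data < 0)) return("intensities must be >= 0")
  p <- object@pixelSizeNm
  if (length(p) != 1L || is.na(p) || p <= 0)
    return("pixelSizeNm must be a single positive number")
  TRUE
})

#' Construct a SuperResImage
#'
#' @param data numeric matrix of non-negative intensities.
#' @param pixelSizeNm canvas pixel size in nanometres.
#' @return A [SuperResImage-class] object.
#' @export
SuperResImage <- function(data, pixelSizeNm) {
  new("SuperResImage", data = data, pixelSizeNm = as.numeric(pixelSizeNm))
}
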