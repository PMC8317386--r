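#' Accessors for VoxelGrid and SuperResImage
#'
#' \code{voxelData} returns the raw 4D intensity array of a [VoxelGrid-class];
#' \code{voxelSize} its \code{(dz, dy, dx)} spacing in micrometres;
#' \code{channelNames} its channel labels; \code{nChannels} the channel
#' count. \code{canvasData} and \code{pixelSizeNm} are the analogous
#' accessors for [SuperResImage-class].
#'
#' @param x a \code{VoxelGrid} or \code{SuperResImage}.
#' @param channel for \code{channelData}, a channel name or 1-based index.
#' @return The slot value; \code{channelData} returns one channel as a 3D
#'   \code{(z, y, x)} array.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("voxelData", function(x) standardGeneric("voxelData"))
#' @rdname accessors
#' @export
setMethod("voxelData", "VoxelGrid", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setMethod("voxelSize", "VoxelGrid", function(x) x@voxelSize)

#' @rdname accessors
#' @export
setGeneric("channelNames", function(x) standardGeneric("channelNames"))
#' @rdname accessors
#' @export
setMethod("channelNames", "VoxelGrid", function(x) x@channelNames)

#' @rdname accessors
#' @export
setGeneric("nChannels", function(x) standardGeneric("nChannels"))
#' @rdname accessors
#' @export
setMethod("nChannels", "VoxelGrid", function(x) dim(x@data)[4L])

#' @rdname accessors
#' @export
setGeneric("channelData", function(x, channel) standardGeneric("channelData"))
#' @rdname accessors
#' @export
setMethod("channelData", "VoxelGrid", function(x, channel) {
  ci <- resolveChannel(x, channel)
  x@data[, , , ci, drop = TRUE]
})

#' @rdname accessors
#' @export
setGeneric("canvasData", function(x) standardGeneric("canvasData"))
#' @rdname accessors
#' @export
setMethod("canvasData", "SuperResImage", function(x) x@data)

#' @rdname accessors
#' @export
setGeneric("pixelSizeNm", function(x) standardGeneric("pixelSizeNm"))
#' @rdname accessors
#' @export
setMethod("pixelSizeNm", "SuperResImage", function(x) x@pixelSizeNm)

#' @describeIn accessors spatial dimensions \code{(Z, Y, X, C)}.
#' @export
setMethod("dim", "VoxelGrid", function(x) dim(x@data))

#' @export
setMethod("show", "VoxelGrid", function(object) {
  d <- dim(object@data)
  cat("VoxelGrid:", d[1], "x", d[2], "x", d[3], "voxels,",
      d[4], if (d[4] == 1L) "channel\n" else "channels\n")
  cat("  voxel size (dz, dy, dx):",
      paste(format(object@voxelSize), collapse = " x "), "um\n")
  cat("  channels:", paste(object@channelNames, collapse = ", "), "\n")
  cat("  intensity range: [", format(min(object@data)), ", ",
      format(max(object@data)), "]\n", sep = "")
})

#' @export
setMethod("show", "SuperResImage", function(object) {
  d <- dim(object@data)
  cat("SuperResImage:", d[1], "x", d[2], "pixels at",
      format(object@pixelSizeNm), "nm/pixel\n")
  cat("  intensity range: [", format(min(object@data)), ", ",
      format(max(object@data)), "]\n", sep = "")
})

# channel name or index -> index, with a schema-style error
resolveChannel <- function(grid, channel) {
  if (is.character(channel)) {
    ci <- match(channel, grid@channelNames)
    if (is.na(ci))
      stop("channel '", channel, "' not found; available: ",
           paste(grid@channelNames, collapse = ", "), call. = FALSE)
    return(ci)
  }
  ci <- as.integer(channel)
  if (is.na(ci) || ci < 1L || ci > dim(grid@data)[4L])
    stop("channel index ", channel, " out of range 1..",
         dim(grid@data)[4L], call. = FALSE)
  ci
}
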