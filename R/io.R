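#' Read a calibrated TIFF Z-stack
#'
#' Reads a single- or multi-channel Z-stack written by [writeStack()] (or
#' any plain TIFF). Calibration, channel names and the intensity scale are
#' taken from the JSON sidecar \code{<path>.json} when present; otherwise
#' from the \code{voxelSize}/\code{channelNames} arguments; otherwise the
#' package defaults apply with a warning. Slices are ordered
#' channel-major (all Z of channel 1, then channel 2, ...).
#'
#' @param path TIFF file path.
#' @param expectedChannels if given, the channel count is checked and a
#'   format error is raised on mismatch.
#' @param voxelSize,channelNames fallbacks when no sidecar exists.
#' @return A [VoxelGrid-class].
#' @seealso [writeStack()]
#' @export
readStack <- function(path, expectedChannels = NULL, voxelSize = NULL,
                      channelNames = NULL) {
  slices <- tryCatch(tiff::readTIFF(path, all = TRUE),
                     error = function(e)
                       stop("format error reading TIFF '", path, "': ",
                            conditionMessage(e), call. = FALSE))
  if (is.matrix(slices)) slices <- list(slices)
  if (length(slices) == 0L)
    stop("format error: '", path, "' contains no image planes")
  if (!all(vapply(slices, is.matrix, TRUE)))
    slices <- lapply(slices, function(s) if (is.matrix(s)) s else s[, , 1L])
  nS <- length(slices)

  meta <- NULL
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)

  if (!is.null(meta)) {
    nZ <- as.integer(meta$dim[1]); nC <- as.integer(meta$dim[4])
    scale <- as.numeric(meta$scale)
    vs <- as.numeric(meta$voxelSize)
    cn <- as.character(meta$channelNames)
    if (nZ * nC != nS)
      stop("format error on axis 'z/channel': sidecar declares ", nZ,
           " slices x ", nC, " channels but the TIFF holds ", nS, " planes")
  } else {
    nZ <- nS; nC <- 1L; scale <- 1
    vs <- voxelSize
    cn <- channelNames
    if (is.null(vs)) {
      warning("no calibration sidecar for '", path,
              "'; using default voxel size (0.23, 0.1, 0.1) um")
      vs <- c(0.23, 0.1, 0.1)
    }
    if (is.null(cn)) cn <- paste0("ch", seq_len(nC))
  }
  if (!is.null(expectedChannels) && nC != expectedChannels)
    stop("format error on axis 'channel': expected ", expectedChannels,
         " channels, found ", nC)

  d2 <- dim(slices[[1L]])
  data <- array(0, dim = c(nZ, d2[1], d2[2], nC))
  for (ci in seq_len(nC))
    for (zi in seq_len(nZ))
      data[zi, , , ci] <- slices[[(ci - 1L) * nZ + zi]] * scale
  VoxelGrid(data, voxelSize = vs, channelNames = cn)
}

#' Write a VoxelGrid as a calibrated TIFF Z-stack
#'
#' Intensities are stored as 32-bit planes normalized by a scale factor
#' (the stack maximum); the scale, voxel size, channel names and shape go
#' to a JSON sidecar \code{<path>.json} so that [readStack()] restores the
#' grid exactly up to the 32-bit quantization (~2^-32 relative error).
#'
#' @param grid a [VoxelGrid-class].
#' @param path output TIFF path; the sidecar is written next to it.
#' @return \code{path}, invisibly.
#' @export
writeStack <- function(grid, path) {
  stopifnot(is(grid, "VoxelGrid"))
  d <- dim(grid@data)
  m <- max(grid@data)
  scale <- if (m > 0) m else 1
  slices <- vector("list", d[1] * d[4])
  for (ci in seq_len(d[4]))
    for (zi in seq_len(d[1]))
      slices[[(ci - 1L) * d[1] + zi]] <- grid@data[zi, , , ci] / scale
  tiff::writeTIFF(slices, path, bits.per.sample = 32L, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(dim = d, voxelSize = grid@voxelSize,
         channelNames = grid@channelNames, scale = scale,
         sliceOrder = "channel-major", units = "um"),
    paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read a localization table
#'
#' Two CSV dialects are supported. \code{"thunderstorm"} maps the columns
#' \code{frame, x [nm], y [nm], sigma [nm], intensity [photon],
#' uncertainty [nm]} (frames are stored 1-based in that dialect and
#' converted to 0-based on read). \code{"simple"} maps \code{frame, x, y,
#' uncertainty} (already 0-based, lengths in nm) with optional
#' \code{sigma, photons, fiducial, fiducialId}.
#'
#' @param path CSV file with a header row.
#' @param dialect \code{"simple"} or \code{"thunderstorm"}.
#' @return A localization data frame with columns \code{frame} (0-based),
#'   \code{x}, \code{y}, \code{uncertainty}, \code{sigma} (nm),
#'   \code{photons}, \code{fiducial}, \code{fiducialId}. A header-only
#'   file yields an empty table.
#' @export
readLocalizations <- function(path, dialect = c("simple", "thunderstorm")) {
  dialect <- match.arg(dialect)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- if (dialect == "thunderstorm")
    c("frame", "x [nm]", "y [nm]", "uncertainty [nm]")
  else c("frame", "x", "y", "uncertainty")
  missing <- setdiff(need, names(df))
  if (length(missing))
    stop("schema error: missing column(s) ",
         paste0("'", missing, "'", collapse = ", "), " for dialect '",
         dialect, "'", call. = FALSE)

  getcol <- function(nm, default = NA_real_) {
    if (nm %in% names(df)) df[[nm]] else rep(default, nrow(df))
  }
  if (dialect == "thunderstorm") {
    out <- data.frame(
      frame = as.integer(df[["frame"]]) - 1L,
      x = as.numeric(df[["x [nm]"]]), y = as.numeric(df[["y [nm]"]]),
      uncertainty = as.numeric(df[["uncertainty [nm]"]]),
      sigma = as.numeric(getcol("sigma [nm]")),
      photons = as.numeric(getcol("intensity [photon]")),
      fiducial = FALSE, fiducialId = NA_integer_)
  } else {
    out <- data.frame(
      frame = as.integer(df[["frame"]]),
      x = as.numeric(df[["x"]]), y = as.numeric(df[["y"]]),
      uncertainty = as.numeric(df[["uncertainty"]]),
      sigma = as.numeric(getcol("sigma")),
      photons = as.numeric(getcol("photons")),
      fiducial = as.logical(getcol("fiducial", FALSE)),
      fiducialId = as.integer(getcol("fiducialId", NA_integer_)))
  }
  if (nrow(out) > 0L && any(out$frame < 0L, na.rm = TRUE))
    stop("schema error: negative frame index after 0-based conversion")
  out
}

#' Write a localization table
#'
#' Inverse of [readLocalizations()]; the \code{"thunderstorm"} dialect
#' writes 1-based frames and bracketed nm headers.
#'
#' @param locs localization data frame (see [readLocalizations()]).
#' @param path output CSV path.
#' @param dialect \code{"simple"} or \code{"thunderstorm"}.
#' @return \code{path}, invisibly.
#' @export
writeLocalizations <- function(locs, path,
                               dialect = c("simple", "thunderstorm")) {
  dialect <- match.arg(dialect)
  if (dialect == "thunderstorm") {
    out <- data.frame(check.names = FALSE,
      frame = locs$frame + 1L,
      `x [nm]` = locs$x, `y [nm]` = locs$y,
      `sigma [nm]` = if ("sigma" %in% names(locs)) locs$sigma else NA_real_,
      `intensity [photon]` = if ("photons" %in% names(locs)) locs$photons
        else NA_real_,
      `uncertainty [nm]` = locs$uncertainty)
  } else {
    keep <- intersect(c("frame", "x", "y", "uncertainty", "sigma",
                        "photons", "fiducial", "fiducialId"), names(locs))
    out <- locs[, keep, drop = FALSE]
  }
  writeMeasurements(out, path)
}

#' Write a measurement table as a reproducible CSV
#'
#' Flat CSV, one row per object, stable column order, byte-identical for
#' identical inputs. Numeric columns are written at 6 significant digits;
#' persisted lengths are nm for localization tables and um/um^3 for stack
#' measurements (as produced upstream).
#'
#' @param records a data frame (may have zero rows: a header-only CSV is
#'   written).
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
writeMeasurements <- function(records, path) {
  stopifnot(is.data.frame(records))
  fmt <- function(col) {
    if (is.double(col)) {
      out <- as.character(signif(col, 6L))
    } else if (is.logical(col) || is.integer(col)) {
      out <- as.character(col)
    } else {
      out <- as.character(col)
      if (any(grepl("[,\n\"]", out[!is.na(out)])))
        stop("character values must not contain commas, quotes or newlines")
    }
    out[is.na(col)] <- "NA"
    out
  }
  header <- paste(names(records), collapse = ",")
  if (nrow(records) > 0L) {
    cols <- lapply(records, fmt)
    body <- do.call(paste, c(cols, sep = ","))
    lines <- c(header, body)
  } else lines <- header
  con <- file(path, open = "wb")  # binary: fixed \n line endings
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}
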