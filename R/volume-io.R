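#' @include AllClasses.R
NULL

# JSON sidecar field names, fixed schema
.geomFields <- c("lateral_pitch_x", "lateral_pitch_y", "axial_pitch_air",
                 "refractive_index", "n_x", "n_y", "n_z")

.geomToList <- function(g) {
  list(lateral_pitch_x = g@lateralPitchX, lateral_pitch_y = g@lateralPitchY,
       axial_pitch_air = g@axialPitch, refractive_index = g@refractiveIndex,
       n_x = g@nX, n_y = g@nY, n_z = g@nZ)
}

.geomFromList <- function(meta) {
  missing <- setdiff(.geomFields, names(meta))
  if (length(missing))
    stop("metadata is missing required field(s): ",
         paste(missing, collapse = ", "))
  AcquisitionGeometry(lateralPitchX = meta$lateral_pitch_x,
                      lateralPitchY = meta$lateral_pitch_y,
                      axialPitch = meta$axial_pitch_air,
                      refractiveIndex = meta$refractive_index,
                      nX = meta$n_x, nY = meta$n_y, nZ = meta$n_z)
}

#' Read an OCT volume from disk
#'
#' Supported formats, selected by the file extension of \code{path}:
#' \itemize{
#'   \item \code{.tif}/\code{.tiff}: multi-page 16-bit TIFF, one page per
#'     B-scan. Page \code{iy} holds the (z, x) image of slow-axis position
#'     \code{iy} (rows = depth, top row shallowest; columns = fast axis).
#'   \item \code{.raw}/\code{.bin}: unsigned 16-bit little-endian, z-fastest
#'     (then x, then y) -- the order framegrabbers commonly emit.
#' }
#' The JSON metadata sidecar must carry the fields \code{lateral_pitch_x},
#' \code{lateral_pitch_y}, \code{axial_pitch_air}, \code{refractive_index},
#' \code{n_x}, \code{n_y}, \code{n_z}. A shape mismatch between file and
#' metadata is an error.
#'
#' @param path volume file (.tif/.tiff or .raw/.bin).
#' @param metadataPath JSON sidecar path; defaults to \code{path} with a
#'   \code{.json} extension.
#' @return an \linkS4class{OCTVolume}.
#' @seealso \code{\link{writeVolume}}
#' @export
readVolume <- function(path,
                       metadataPath = paste0(tools::file_path_sans_ext(path), ".json")) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  if (!file.exists(metadataPath)) stop("metadata file not found: ", metadataPath)
  meta <- jsonlite::read_json(metadataPath, simplifyVector = TRUE)
  g <- .geomFromList(meta)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
    if (!is.list(pages)) pages <- list(pages)
    if (length(pages) != g@nY)
      stop(sprintf("format error: %d TIFF pages but metadata says n_y = %d",
                   length(pages), g@nY))
    if (!identical(dim(pages[[1L]]), c(g@nZ, g@nX)))
      stop(sprintf("format error: page shape %s does not match n_z x n_x = %d x %d",
                   paste(dim(pages[[1L]]), collapse = "x"), g@nZ, g@nX))
    arr <- array(0, dim = c(g@nX, g@nY, g@nZ))
    for (iy in seq_len(g@nY))
      arr[, iy, ] <- t(pages[[iy]])
  } else if (ext %in% c("raw", "bin")) {
    nVox <- as.double(g@nX) * g@nY * g@nZ
    v <- readBin(path, what = "integer", n = nVox + 1, size = 2L,
                 signed = FALSE, endian = "little")
    if (length(v) != nVox)
      stop(sprintf("format error: file holds %d voxels but metadata implies %.0f",
                   length(v), nVox))
    arr <- aperm(array(as.numeric(v), dim = c(g@nZ, g@nX, g@nY)), c(2L, 3L, 1L))
  } else {
    stop("unsupported volume format: .", ext)
  }
  OCTVolume(arr, g)
}

#' Write an OCT volume to disk
#'
#' Inverse of \code{\link{readVolume}}; the same formats and layouts apply.
#' Intensities must be integer-valued in [0, 65535] (16-bit storage); the
#' round trip is then bit-exact. The geometry is written to the JSON
#' sidecar.
#'
#' @param volume an \linkS4class{OCTVolume}.
#' @param path output file (.tif/.tiff or .raw/.bin).
#' @param metadataPath JSON sidecar path; defaults to \code{path} with a
#'   \code{.json} extension.
#' @return invisibly, \code{c(path, metadataPath)}.
#' @export
writeVolume <- function(volume, path,
                        metadataPath = paste0(tools::file_path_sans_ext(path), ".json")) {
  stopifnot(is(volume, "OCTVolume"))
  arr <- intensity(volume)
  if (any(arr != round(arr)) || any(arr > 65535))
    stop("volume intensities must be integer-valued in [0, 65535] for 16-bit storage")
  g <- geometry(volume)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- lapply(seq_len(g@nY), function(iy) t(arr[, iy, ]) / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else if (ext %in% c("raw", "bin")) {
    v <- as.integer(aperm(arr, c(3L, 1L, 2L)))   # z-fastest
    v <- ifelse(v > 32767L, v - 65536L, v)       # two's-complement for size-2 writeBin
    writeBin(v, path, size = 2L, endian = "little")
  } else {
    stop("unsupported volume format: .", ext)
  }
  jsonlite::write_json(.geomToList(g), metadataPath,
                       auto_unbox = TRUE, digits = NA)
  invisible(c(path, metadataPath))
}

#' Export interface and thickness maps
#'
#' Writes the upper/lower interface index grids and the thickness grid as
#' single-page 32-bit float TIFFs plus one CSV, and a JSON manifest. Float
#' TIFF samples are stored normalised to [0, 1]; the affine calibration
#' (\code{value = offset + scale * sample}) of each TIFF is recorded in the
#' manifest. The CSV carries exact values and the validity mask (one row
#' per lateral cell: \code{x, y, pu, pb, valid, thickness_um}) and is the
#' file \code{\link{readMaps}} reads back; invalid cells have empty
#' \code{pu/pb/thickness} fields.
#'
#' @param interfaceMap an \linkS4class{InterfaceMap}.
#' @param thicknessMap a \linkS4class{ThicknessMap} of the same lateral
#'   shape.
#' @param outDir output directory (created if needed).
#' @return character vector of the files written (the manifest lists the
#'   same four data files).
#' @export
writeMaps <- function(interfaceMap, thicknessMap, outDir) {
  if (!identical(dim(interfaceMap), dim(thicknessGrid(thicknessMap))))
    stop("interface and thickness maps must share a lateral shape")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  writeFloatTiff <- function(m, file) {
    finite <- m[is.finite(m)]
    off <- if (length(finite)) min(finite) else 0
    rng <- if (length(finite)) max(finite) - off else 0
    scl <- if (rng > 0) rng else 1
    norm <- (m - off) / scl
    norm[!is.finite(norm)] <- 0
    tiff::writeTIFF(norm, file, bits.per.sample = 32L, compression = "none")
    list(file = basename(file), offset = off, scale = scl)
  }

  pu <- upperIndex(interfaceMap); pb <- lowerIndex(interfaceMap)
  th <- thicknessGrid(thicknessMap)
  files <- file.path(outDir, c("pu.tif", "pb.tif", "thickness.tif", "maps.csv"))
  cal <- list(pu = writeFloatTiff(pu, files[1]),
              pb = writeFloatTiff(pb, files[2]),
              thickness = writeFloatTiff(th, files[3]))

  d <- dim(pu)
  df <- data.frame(x = rep(seq_len(d[1]), times = d[2]),
                   y = rep(seq_len(d[2]), each = d[1]),
                   pu = as.vector(pu), pb = as.vector(pb),
                   valid = as.vector(validMask(interfaceMap)),
                   thickness_um = as.vector(th))
  write.csv(df, files[4], row.names = FALSE)

  manifest <- file.path(outDir, "manifest.json")
  jsonlite::write_json(
    list(files = basename(files), shape = d, calibration = cal),
    manifest, auto_unbox = TRUE, digits = NA)
  c(files, manifest)
}

#' Read maps back from an export directory
#'
#' Reconstructs the \linkS4class{InterfaceMap} and the thickness grid from
#' the CSV written by \code{\link{writeMaps}} (exact values, exact validity
#' mask).
#'
#' @param outDir directory holding \code{manifest.json} and \code{maps.csv}.
#' @return list with \code{interfaces} (an \linkS4class{InterfaceMap}) and
#'   \code{thicknessGrid} (numeric matrix, um).
#' @export
readMaps <- function(outDir) {
  manifest <- jsonlite::read_json(file.path(outDir, "manifest.json"),
                                  simplifyVector = TRUE)
  d <- as.integer(manifest$shape)
  df <- read.csv(file.path(outDir, "maps.csv"))
  toGrid <- function(v) matrix(v, d[1], d[2])
  list(interfaces = InterfaceMap(puGrid = toGrid(df$pu),
                                 pbGrid = toGrid(df$pb),
                                 validMask = toGrid(df$valid)),
       thicknessGrid = toGrid(df$thickness_um))
}
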