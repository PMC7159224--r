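#' Read a fluorescence image from TIFF or PNG
#'
#' Multi-channel images are collapsed to their first channel; intensities
#' are returned as read (0..1 for standard readers).
#'
#' @param path file path, extension .tif/.tiff/.png.
#' @param pixelSize um per pixel calibration.
#' @return a \linkS4class{FluorescenceImage}.
#' @export
readFluorescenceImage <- function(path, pixelSize) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    tif = , tiff = tiff::readTIFF(path),
    png = png::readPNG(path),
    nmStop("nm_invalid_input", sprintf("unsupported image format '%s'", ext)))
  if (length(dim(img)) == 3L) img <- img[, , 1]
  FluorescenceImage(img, pixelSize)
}

#' Write a fluorescence image as 16-bit grayscale TIFF
#'
#' Intensities are scaled by the image maximum into [0, 1] before writing.
#'
#' @param image a \linkS4class{FluorescenceImage}.
#' @param path output path.
#' @export
writeFluorescenceImage <- function(image, path) {
  m <- intensityMatrix(image)
  mx <- max(m)
  if (mx > 0) m <- m / mx
  tiff::writeTIFF(m, path, bits.per.sample = 16L)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask a \linkS4class{BinaryMask} or \linkS4class{CellROI}.
#' @param path output path.
#' @export
writeMaskPng <- function(mask, path) {
  png::writePNG(maskMatrix(mask) * 1, path)
  invisible(path)
}

#' Read a posture CSV (columns time_s, angle_deg)
#' @param path CSV path.
#' @return a \linkS4class{PostureSeries}.
#' @export
readPostureCsv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "angle_deg") %in% names(d)))
    nmStop("nm_invalid_input", "posture CSV needs columns time_s, angle_deg")
  PostureSeries(d$time_s, d$angle_deg)
}

#' Read a centroid track CSV (columns time_s, x_um, y_um)
#' @param path CSV path.
#' @return a \linkS4class{CentroidTrack}.
#' @export
readTrackCsv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "x_um", "y_um") %in% names(d)))
    nmStop("nm_invalid_input", "track CSV needs columns time_s, x_um, y_um")
  CentroidTrack(d$time_s, d$x_um, d$y_um)
}

#' Read a current-trace CSV (columns time_s, current_pA)
#'
#' The sampling rate is inferred from the median time step unless given.
#'
#' @param path CSV path.
#' @param sampleRate Hz; inferred when NULL.
#' @param holdingPotential mV metadata (default -60).
#' @return a \linkS4class{CurrentTrace}.
#' @export
readTraceCsv <- function(path, sampleRate = NULL, holdingPotential = -60) {
  d <- utils::read.csv(path)
  if (!all(c("time_s", "current_pA") %in% names(d)))
    nmStop("nm_invalid_input", "trace CSV needs columns time_s, current_pA")
  sr <- sampleRate %||% (1 / stats::median(diff(d$time_s)))
  CurrentTrace(d$current_pA, sr, holdingPotential)
}

#' Read a polygon ROI CSV (columns x, y; 0-based pixel coordinates)
#'
#' @param path CSV path.
#' @param dim image dimensions c(rows, cols) to rasterize into.
#' @param pixelSize um per pixel.
#' @return a \linkS4class{CellROI}.
#' @export
readRoiCsv <- function(path, dim, pixelSize) {
  d <- utils::read.csv(path)
  if (!all(c("x", "y") %in% names(d)))
    nmStop("nm_invalid_input", "ROI CSV needs columns x, y")
  polygonToRoi(d[, c("x", "y")], dim, pixelSize)
}
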