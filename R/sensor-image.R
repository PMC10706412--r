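#' Sensor-array image container
#'
#' A `sensor_image` wraps an RGB raster of a colorimetric sensor array
#' together with its capture phase (before or after exposure to the
#' volatile organic compounds) and an optional capture time. Pixel values
#' are stored as doubles on the 8-bit scale `[0, 255]`; all geometry is
#' 1-based `(row, col)` with the origin at the top-left pixel.
#'
#' @param pixels numeric array `height x width x 3` with values in
#'   `[0, 255]` (channel order R, G, B).
#' @param phase `"pre"` or `"post"` — capture phase relative to exposure.
#' @param time_min optional non-negative capture time in minutes since
#'   exposure start (used by time-lapse analyses).
#' @return An object of class `sensor_image`.
#' @examples
#' px <- array(128, dim = c(4, 4, 3))
#' img <- sensor_image(px, "pre")
#' dim(img$pixels)
#' @export
sensor_image <- function(pixels, phase = c("pre", "post"), time_min = NULL) {
  phase <- match.arg(phase)
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3)
    stopf("`pixels` must be a height x width x 3 array")
  if (dim(pixels)[1] < 1 || dim(pixels)[2] < 1)
    stopf("image must be at least 1 x 1")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255)
    stopf("channel values must lie in [0, 255]")
  if (!is.null(time_min)) {
    if (!is.numeric(time_min) || length(time_min) != 1 || time_min < 0)
      stopf("`time_min` must be a single non-negative number")
  }
  structure(
    list(pixels = pixels, phase = phase, time_min = time_min),
    class = "sensor_image"
  )
}

#' @export
print.sensor_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<sensor_image> %d x %d px, phase = %s%s\n", d[1], d[2],
              x$phase,
              if (is.null(x$time_min)) "" else
                sprintf(", t = %g min", x$time_min)))
  invisible(x)
}

#' @export
dim.sensor_image <- function(x) dim(x$pixels)

#' Read a sensor-array photograph
#'
#' Reads an 8-bit RGB PNG or TIFF image into a [sensor_image]. An alpha
#' channel, if present, is stripped with a warning; grayscale images are
#' replicated to three channels.
#'
#' @param path path to a `.png`, `.tif` or `.tiff` file.
#' @inheritParams sensor_image
#' @return A [sensor_image] with pixel values on `[0, 255]`.
#' @export
read_sensor_image <- function(path, phase = c("pre", "post"),
                              time_min = NULL) {
  phase <- match.arg(phase)
  if (!file.exists(path)) stopf("file not found: %s", path)
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stopf("unsupported image format '.%s' (expected PNG or TIFF)", ext)
  )
  if (length(dim(raw)) == 2) raw <- array(raw, dim = c(dim(raw), 1))
  nch <- dim(raw)[3]
  if (nch == 2 || nch == 4) {
    warning("image has an alpha channel; stripping it", call. = FALSE)
    raw <- raw[, , seq_len(nch - 1), drop = FALSE]
    nch <- dim(raw)[3]
  }
  if (nch == 1) raw <- array(rep(raw, 3), dim = c(dim(raw)[1:2], 3))
  sensor_image(raw[, , 1:3, drop = FALSE] * 255, phase, time_min)
}

#' Write an RGB image as 8-bit PNG
#'
#' @param image a [sensor_image] or a `height x width x 3` array on the
#'   `[0, 255]` scale.
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_sensor_image <- function(image, path) {
  px <- if (inherits(image, "sensor_image")) image$pixels else image
  png::writePNG(pmin(pmax(px / 255, 0), 1), path)
  invisible(path)
}

# Shared shape check for image pairs.
check_same_shape <- function(a, b) {
  da <- if (inherits(a, "sensor_image")) dim(a$pixels) else dim(a)
  db <- if (inherits(b, "sensor_image")) dim(b$pixels) else dim(b)
  if (!identical(da[1:2], db[1:2]))
    stopf("image shapes differ: %dx%d vs %dx%d", da[1], da[2], db[1], db[2])
  invisible(TRUE)
}
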