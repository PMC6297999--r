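#' RGB plate image
#'
#' Construct an 8-bit RGB image from an `H x W x 3` array. The origin is the
#' top-left corner; the first array dimension is the image row (increasing
#' downwards), the second the column, the third the colour channel (R, G, B).
#' Channel intensities are integers in `[0, 255]`.
#'
#' @param pixels numeric array of dimension `H x W x 3`, values in `[0, 255]`.
#' @return An object of class `rgb_image` (the validated array).
#' @examples
#' px <- array(200, dim = c(4, 4, 3))
#' img <- rgb_image(px)
#' dim(img)
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    sh_abort("`pixels` must be an H x W x 3 array", "seedhalo_format_error")
  }
  d <- dim(pixels)
  if (d[1] < 2 || d[2] < 2) {
    sh_abort("image must be at least 2 x 2 pixels", "seedhalo_format_error")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    sh_abort("channel values must lie in [0, 255]", "seedhalo_format_error")
  }
  pixels <- round(pixels)
  storage.mode(pixels) <- "integer"
  structure(pixels, class = c("rgb_image", class(array())))
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image> %d x %d px, 3 channels (8-bit)\n", d[1], d[2]))
  invisible(x)
}

#' Read a plate image from disk
#'
#' Reads an 8-bit RGB PNG, TIFF or JPEG. Grayscale images are expanded to
#' three identical channels; an alpha channel, if present, is dropped with a
#' warning.
#'
#' @param path path to a `.png`, `.tif(f)`, `.jpg` or `.jpeg` file.
#' @return An [rgb_image].
#' @export
read_plate_image <- function(path) {
  if (!file.exists(path)) {
    sh_abort(paste0("cannot read image: ", path), "seedhalo_io_error")
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    sh_abort(paste0("unsupported image format: .", ext), "seedhalo_format_error")
  )
  if (length(dim(raw)) == 2) {
    raw <- array(raw, dim = c(dim(raw), 3))
  }
  if (dim(raw)[3] == 4) {
    warn("image has an alpha channel; dropping it")
    raw <- raw[, , 1:3, drop = FALSE]
  }
  if (dim(raw)[3] == 2) { # gray + alpha
    warn("image has an alpha channel; dropping it")
    raw <- array(raw[, , 1], dim = c(dim(raw)[1:2], 3))
  }
  rgb_image(round(raw * 255))
}

#' Write an RGB image as PNG
#'
#' @param image an [rgb_image].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_plate_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  arr <- unclass(image) / 255
  png::writePNG(arr, target = path)
  invisible(path)
}

#' Crop window
#'
#' Half-open pixel-index window `[top, bottom) x [left, right)` with the
#' top-left pixel at `(0, 0)`, matching the image coordinate convention.
#'
#' @param top,left,bottom,right integer pixel indices, `0 <= top < bottom`,
#'   `0 <= left < right`.
#' @return A `crop_window` object.
#' @export
crop_window <- function(top, left, bottom, right) {
  v <- c(top = top, left = left, bottom = bottom, right = right)
  if (anyNA(v) || any(v != round(v)) || top < 0 || left < 0 ||
      top >= bottom || left >= right) {
    sh_abort("invalid crop window: need 0 <= top < bottom and 0 <= left < right",
             "seedhalo_bounds_error")
  }
  structure(as.list(v), class = "crop_window")
}

#' Crop an image
#'
#' Cropping changes only which pixels are kept; the millimetre calibration of
#' the plate is unaffected.
#'
#' @param image an [rgb_image].
#' @param window a [crop_window] lying within the image bounds.
#' @return The cropped [rgb_image].
#' @export
crop_image <- function(image, window) {
  stopifnot(inherits(image, "rgb_image"), inherits(window, "crop_window"))
  d <- dim(image)
  if (window$bottom > d[1] || window$right > d[2]) {
    sh_abort(sprintf("crop window [%d,%d)x[%d,%d) exceeds image %d x %d",
                     window$top, window$bottom, window$left, window$right,
                     d[1], d[2]),
             "seedhalo_bounds_error")
  }
  rows <- (window$top + 1):window$bottom
  cols <- (window$left + 1):window$right
  rgb_image(unclass(image)[rows, cols, , drop = FALSE])
}
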