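#' Spatial calibration
#'
#' A single isotropic scale factor converting pixels to millimetres. Square
#' pixels are assumed, which holds for flatbed scanners and camera copy
#' stands used for plate imaging.
#'
#' @param pixels_per_mm positive, finite scale in px/mm.
#' @return A `calibration` object.
#' @examples
#' calibration(10)
#' @export
calibration <- function(pixels_per_mm) {
  if (!is.numeric(pixels_per_mm) || length(pixels_per_mm) != 1 ||
      !is.finite(pixels_per_mm) || pixels_per_mm <= 0) {
    sh_abort("`pixels_per_mm` must be a single positive finite number",
             "seedhalo_calibration_error")
  }
  structure(list(pixels_per_mm = as.numeric(pixels_per_mm)),
            class = "calibration")
}

#' @export
print.calibration <- function(x, ...) {
  cat(sprintf("<calibration> %.6g px/mm\n", x$pixels_per_mm))
  invisible(x)
}

#' Compute the plate scale from two reference points
#'
#' The user marks the two extremities of the plate (or of a ruler laid next
#' to it) and states the physical distance between them; the scale is the
#' Euclidean pixel distance divided by that length. Swapping the two points
#' does not change the result.
#'
#' @param point_a,point_b numeric length-2 pixel coordinates `(x, y)` (any
#'   consistent convention; only the distance matters). Must differ.
#' @param known_distance_mm positive physical distance in mm.
#' @return A [calibration].
#' @examples
#' compute_scale(c(0, 0), c(100, 0), 50)   # 2 px/mm
#' @export
compute_scale <- function(point_a, point_b, known_distance_mm) {
  if (length(point_a) != 2 || length(point_b) != 2 ||
      anyNA(point_a) || anyNA(point_b)) {
    sh_abort("calibration points must be numeric length-2 vectors",
             "seedhalo_calibration_error")
  }
  if (!is.numeric(known_distance_mm) || length(known_distance_mm) != 1 ||
      !is.finite(known_distance_mm) || known_distance_mm <= 0) {
    sh_abort("`known_distance_mm` must be a single positive number",
             "seedhalo_calibration_error")
  }
  d <- sqrt(sum((as.numeric(point_a) - as.numeric(point_b))^2))
  if (d == 0) {
    sh_abort("calibration points coincide", "seedhalo_calibration_error")
  }
  calibration(d / known_distance_mm)
}

#' Convert a pixel count to an area in mm^2
#'
#' @param pixel_count non-negative pixel count (vectorised).
#' @param cal a [calibration].
#' @return Area(s) in mm^2.
#' @export
px_area_to_mm2 <- function(pixel_count, cal) {
  stopifnot(inherits(cal, "calibration"))
  if (any(pixel_count < 0)) {
    sh_abort("pixel counts must be non-negative", "seedhalo_format_error")
  }
  pixel_count / cal$pixels_per_mm^2
}

# length conversion used throughout morphometry
px_to_mm <- function(px, cal) px / cal$pixels_per_mm
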