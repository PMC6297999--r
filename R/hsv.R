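#' Split an RGB image into 8-bit HSV planes
#'
#' Converts to the HSV colour space with all three planes rescaled to the
#' integer range 0-255, the convention used by ImageJ-style colour
#' thresholding: hue is the colour angle mapped as `floor(h_deg / 360 * 255)`
#' (so the wheel occupies 0-254 and wraps), saturation is
#' `floor((max - min) / max * 255)` and value is `max(R, G, B)`. Achromatic
#' pixels (`max == min`) get hue 0 and saturation 0; black additionally has
#' saturation 0 by the `max == 0` convention.
#'
#' @param image an [rgb_image].
#' @return An object of class `hsv_planes`: a list with integer matrices
#'   `h`, `s`, `v` of the same height/width as `image`.
#' @examples
#' red <- rgb_image(array(rep(c(255, 0, 0), each = 4), dim = c(2, 2, 3)))
#' p <- rgb_to_hsv_planes(red)
#' p$h[1, 1]; p$s[1, 1]; p$v[1, 1]   # 0, 255, 255
#' @export
rgb_to_hsv_planes <- function(image) {
  if (!inherits(image, "rgb_image")) {
    sh_abort("`image` must be an rgb_image (H x W x 3)", "seedhalo_format_error")
  }
  r <- unclass(image)[, , 1]
  g <- unclass(image)[, , 2]
  b <- unclass(image)[, , 3]
  mx <- pmax(r, g, b)
  mn <- pmin(r, g, b)
  delta <- mx - mn

  # hue angle in degrees, sector by dominant channel
  h_deg <- matrix(0, nrow(r), ncol(r))
  nz <- delta > 0
  rmax <- nz & (mx == r)
  gmax <- nz & !rmax & (mx == g)
  bmax <- nz & !rmax & !gmax
  h_deg[rmax] <- 60 * (((g[rmax] - b[rmax]) / delta[rmax]) %% 6)
  h_deg[gmax] <- 60 * ((b[gmax] - r[gmax]) / delta[gmax] + 2)
  h_deg[bmax] <- 60 * ((r[bmax] - g[bmax]) / delta[bmax] + 4)

  h <- floor(h_deg / 360 * 255 + 1e-9)
  s <- matrix(0, nrow(r), ncol(r))
  pos <- mx > 0
  s[pos] <- floor(delta[pos] / mx[pos] * 255 + 1e-9)
  v <- mx

  planes <- list(h = h, s = s, v = v)
  planes <- lapply(planes, function(m) { storage.mode(m) <- "integer"; m })
  structure(planes, class = "hsv_planes")
}

#' @export
print.hsv_planes <- function(x, ...) {
  cat(sprintf("<hsv_planes> %d x %d px (8-bit H, S, V)\n",
              nrow(x$h), ncol(x$h)))
  invisible(x)
}

#' Reconstruct an RGB image from 8-bit HSV planes
#'
#' Standard inverse of [rgb_to_hsv_planes()]. Because hue is quantised to
#' 255 levels (about 1.41 degrees per level), reconstruction of saturated
#' colours is exact only up to the hue quantisation: the value (max) channel
#' and the min channel round-trip within one intensity level, while the
#' intermediate channel can move by up to roughly `delta * 1.41 / 60 + 1`
#' levels, where `delta` is the pixel's max - min spread.
#'
#' @param planes an `hsv_planes` object.
#' @return An [rgb_image].
#' @export
hsv_planes_to_rgb <- function(planes) {
  if (!inherits(planes, "hsv_planes")) {
    sh_abort("`planes` must be an hsv_planes object", "seedhalo_format_error")
  }
  h_deg <- planes$h / 255 * 360
  s <- planes$s / 255
  v <- planes$v # 0-255 scale
  c_ <- v * s
  hp <- h_deg / 60
  x <- c_ * (1 - abs(hp %% 2 - 1))
  m <- v - c_
  H <- nrow(h_deg); W <- ncol(h_deg)
  r <- g <- b <- matrix(0, H, W)
  sector <- floor(hp) %% 6
  pick <- function(sec) sector == sec
  r[pick(0)] <- c_[pick(0)]; g[pick(0)] <- x[pick(0)]
  r[pick(1)] <- x[pick(1)];  g[pick(1)] <- c_[pick(1)]
  g[pick(2)] <- c_[pick(2)]; b[pick(2)] <- x[pick(2)]
  g[pick(3)] <- x[pick(3)];  b[pick(3)] <- c_[pick(3)]
  r[pick(4)] <- x[pick(4)];  b[pick(4)] <- c_[pick(4)]
  r[pick(5)] <- c_[pick(5)]; b[pick(5)] <- x[pick(5)]
  out <- array(0, dim = c(H, W, 3))
  out[, , 1] <- r + m
  out[, , 2] <- g + m
  out[, , 3] <- b + m
  rgb_image(pmin(pmax(round(out), 0), 255))
}
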