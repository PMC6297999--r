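#' Channel band
#'
#' An inclusive intensity interval `[low, high]` on one 8-bit HSV plane.
#'
#' @param low,high integers with `0 <= low <= high <= 255`.
#' @return A `channel_band` object.
#' @export
channel_band <- function(low, high) {
  if (anyNA(c(low, high)) || low != round(low) || high != round(high) ||
      low < 0 || high > 255 || low > high) {
    sh_abort("channel band must satisfy 0 <= low <= high <= 255",
             "seedhalo_parameter_error")
  }
  structure(list(low = as.integer(low), high = as.integer(high)),
            class = "channel_band")
}

#' Segmentation parameters
#'
#' HSV band thresholds for one segmentation target (`"mucilage"` halos or
#' `"seed"` bodies).
#'
#' @param h_band,s_band,v_band [channel_band] objects.
#' @param target `"mucilage"` or `"seed"`.
#' @return A `seg_params` object.
#' @seealso [default_seg_params()] for the shipped species defaults.
#' @export
seg_params <- function(h_band, s_band, v_band, target = c("mucilage", "seed")) {
  target <- tryCatch(match.arg(target),
                     error = function(e) sh_abort(
                       "target must be \"mucilage\" or \"seed\"",
                       "seedhalo_parameter_error"))
  for (b in list(h_band, s_band, v_band)) {
    if (!inherits(b, "channel_band")) {
      sh_abort("bands must be channel_band objects", "seedhalo_parameter_error")
    }
  }
  structure(list(h_band = h_band, s_band = s_band, v_band = v_band,
                 target = target),
            class = "seg_params")
}

#' @export
print.seg_params <- function(x, ...) {
  cat(sprintf("<seg_params:%s> H [%d,%d]  S [%d,%d]  V [%d,%d]\n",
              x$target, x$h_band$low, x$h_band$high,
              x$s_band$low, x$s_band$high, x$v_band$low, x$v_band$high))
  invisible(x)
}

#' Default segmentation parameters
#'
#' The shipped flax defaults. The printed anchor values (H 172, S 24, V 85
#' for mucilage; V 70 for seeds) are the non-trivial bound of each band; the
#' other end of the band is the extreme of the scale. Stained mucilage is
#' selected by hue in `[172, 255]` (purple-pink), saturation in `[24, 255]`
#' (rejecting near-achromatic background noise) and value in `[85, 255]`.
#' Seeds are dark against both gel and halo, so only the value plane binds:
#' `V` in `[0, 70]` with hue and saturation passing everything.
#'
#' @param target `"mucilage"` or `"seed"`.
#' @return A [seg_params] object.
#' @examples
#' default_seg_params("mucilage")
#' default_seg_params("seed")
#' @export
default_seg_params <- function(target = c("mucilage", "seed")) {
  target <- tryCatch(match.arg(target),
                     error = function(e) sh_abort(
                       "unknown segmentation target",
                       "seedhalo_parameter_error"))
  if (target == "mucilage") {
    seg_params(channel_band(172, 255), channel_band(24, 255),
               channel_band(85, 255), "mucilage")
  } else {
    seg_params(channel_band(0, 255), channel_band(0, 255),
               channel_band(0, 70), "seed")
  }
}

#' Binary mask from HSV band thresholds
#'
#' A pixel is selected iff its hue, saturation and value all fall inside
#' their respective (inclusive) bands.
#'
#' @param planes an `hsv_planes` object.
#' @param params a [seg_params] object.
#' @return A logical matrix of the same height/width.
#' @export
band_mask <- function(planes, params) {
  if (!inherits(planes, "hsv_planes")) {
    sh_abort("`planes` must be an hsv_planes object", "seedhalo_format_error")
  }
  stopifnot(inherits(params, "seg_params"))
  within_band <- function(m, b) m >= b$low & m <= b$high
  within_band(planes$h, params$h_band) &
    within_band(planes$s, params$s_band) &
    within_band(planes$v, params$v_band)
}

#' Iterative-intermeans (IsoData) threshold of a 256-bin histogram
#'
#' Starting from the intensity that bisects the histogram mass, iterates
#' `T <- round((mean of intensities <= T) + (mean of intensities > T)) / 2)`
#' (ties rounded half up) to its fixed point. Intensities at or below the
#' returned threshold form the lower class.
#'
#' @param histogram numeric vector of 256 non-negative counts for
#'   intensities 0-255. At least two bins must be non-zero.
#' @return Integer threshold in `[0, 254]`.
#' @examples
#' h <- numeric(256); h[51] <- 10; h[201] <- 10  # deltas at 50 and 200
#' isodata_threshold(h)   # 125
#' @export
isodata_threshold <- function(histogram) {
  if (length(histogram) != 256 || anyNA(histogram) || any(histogram < 0)) {
    sh_abort("`histogram` must be 256 non-negative counts",
             "seedhalo_parameter_error")
  }
  nz <- which(histogram > 0)
  if (length(nz) < 2) {
    sh_abort("degenerate histogram: fewer than two non-zero bins",
             "seedhalo_degenerate_histogram")
  }
  intens <- 0:255
  lo <- nz[1] - 1L
  hi <- nz[length(nz)] - 1L
  # initial T: smallest intensity whose cumulative mass reaches half
  total <- sum(histogram)
  t_cur <- intens[which(cumsum(histogram) >= total / 2)[1]]
  t_cur <- min(max(t_cur, lo), hi - 1L)
  csum  <- cumsum(histogram)
  cmom  <- cumsum(histogram * intens)
  for (iter in 1:256) {
    n1 <- csum[t_cur + 1]; m1 <- cmom[t_cur + 1] / n1
    n2 <- total - n1;      m2 <- (cmom[256] - cmom[t_cur + 1]) / n2
    t_new <- floor((m1 + m2) / 2 + 0.5)
    t_new <- min(max(t_new, lo), hi - 1L)
    if (t_new == t_cur) break
    t_cur <- t_new
  }
  as.integer(t_cur)
}

#' Suggest segmentation parameters from the image itself
#'
#' Applies [isodata_threshold()] to each HSV plane's histogram and maps the
#' result onto the band geometry of the target: for mucilage the threshold
#' becomes the lower bound of each band (halo pixels sit on the high side of
#' each plane); for seeds it becomes the upper bound of the value band, with
#' hue and saturation passing everything.
#'
#' The value plane of a stained plate typically has three populations —
#' dark seeds, stained halos, bright gel — and a single intermeans split
#' lands between halo and gel, not at the seed/halo gap that both value
#' thresholds must straddle. The value threshold therefore re-splits the
#' dark class while that class is still spread over a wide intensity range
#' (weighted SD > 24 levels), which isolates the darkest population; on a
#' plainly bimodal histogram the first split is already final and is
#' returned unchanged. The suggestion is advisory — the supervised workflow
#' applies the species defaults unless automatic thresholding is requested
#' explicitly.
#'
#' @param planes an `hsv_planes` object.
#' @param target `"mucilage"` or `"seed"`.
#' @return A [seg_params] object. If any required plane histogram is
#'   degenerate (effectively single-valued), the species defaults are
#'   returned with a warning.
#' @export
suggest_seg_params <- function(planes, target = c("mucilage", "seed")) {
  target <- match.arg(target)
  if (!inherits(planes, "hsv_planes")) {
    sh_abort("`planes` must be an hsv_planes object", "seedhalo_format_error")
  }
  hist256 <- function(m) tabulate(as.vector(m) + 1L, nbins = 256)
  thr <- function(m) isodata_threshold(hist256(m))
  res <- tryCatch({
    if (target == "mucilage") {
      seg_params(channel_band(thr(planes$h) + 1L, 255),
                 channel_band(thr(planes$s) + 1L, 255),
                 channel_band(darkest_split(hist256(planes$v)) + 1L, 255),
                 "mucilage")
    } else {
      seg_params(channel_band(0, 255), channel_band(0, 255),
                 channel_band(0, darkest_split(hist256(planes$v))), "seed")
    }
  }, seedhalo_degenerate_histogram = function(e) NULL)
  if (is.null(res)) {
    warn(paste0("degenerate channel histogram; falling back to default ",
                target, " parameters"))
    res <- default_seg_params(target)
  }
  res
}

# Threshold isolating the darkest intensity population: intermeans split,
# re-applied to the lower class while that class is itself spread widely
# enough (weighted SD > 24 levels) to still mix two populations.
darkest_split <- function(histogram) {
  t_cur <- isodata_threshold(histogram)
  for (i in 1:8) {
    w <- histogram[seq_len(t_cur + 1L)]
    ints <- seq_len(t_cur + 1L) - 1L
    if (sum(w > 0) < 2) break
    mu <- sum(w * ints) / sum(w)
    sdv <- sqrt(sum(w * (ints - mu)^2) / sum(w))
    if (sdv <= 24) break
    lower <- numeric(256)
    lower[seq_len(t_cur + 1L)] <- w
    t_new <- tryCatch(isodata_threshold(lower),
                      seedhalo_degenerate_histogram = function(e) t_cur)
    if (t_new >= t_cur) break
    t_cur <- t_new
  }
  t_cur
}

#' Fill holes in a binary mask
#'
#' Background pixels (4-connected) not reachable from the image border are
#' interior holes and are turned on. The 4-connected background paired with
#' 8-connected foreground is the standard dual-connectivity convention.
#'
#' @param mask logical matrix.
#' @return Logical matrix with all holes filled.
#' @export
fill_holes <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!any(mask) || all(mask)) return(mask)
  bg <- matrix(as.numeric(!mask), nrow(mask), ncol(mask))
  lab <- EBImage::bwlabel(bg) # 4-connected components
  border_labels <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
  border_labels <- border_labels[border_labels > 0]
  holes <- !mask & !(lab %in% border_labels)
  mask | matrix(holes, nrow(mask), ncol(mask))
}

#' Segment mucilage halos
#'
#' Band-thresholds the image with the mucilage parameters, then fills every
#' interior hole so that each halo region is simply connected. The filled
#' area therefore includes the pixels occupied by the seed inside the halo —
#' the halo area is the whole disk bounded by the outer stained contour,
#' which is what the adjusted mucilage content is defined on.
#'
#' @param image an [rgb_image].
#' @param params mucilage [seg_params]; defaults to the flax defaults.
#' @return A logical mask.
#' @export
segment_mucilage <- function(image, params = default_seg_params("mucilage")) {
  stopifnot(inherits(params, "seg_params"))
  if (params$target != "mucilage") {
    sh_abort("`params` must target mucilage", "seedhalo_parameter_error")
  }
  fill_holes(band_mask(rgb_to_hsv_planes(image), params))
}

#' Segment seeds
#'
#' Same process as [segment_mucilage()] on the seed parameters: the dark
#' seed body is selected on the value plane and specular-highlight holes are
#' filled.
#'
#' @inheritParams segment_mucilage
#' @export
segment_seeds <- function(image, params = default_seg_params("seed")) {
  stopifnot(inherits(params, "seg_params"))
  if (params$target != "seed") {
    sh_abort("`params` must target seed", "seedhalo_parameter_error")
  }
  fill_holes(band_mask(rgb_to_hsv_planes(image), params))
}
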