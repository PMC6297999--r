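# Static validation overlay: a side-by-side triptych replacing interactive
# inspection. Left: the input image. Middle: mucilage objects tinted by
# label. Right: seed objects tinted by label. Object numbers are drawn at
# the centroids with a small built-in bitmap font so the rendering has no
# graphics-device dependency and is byte-reproducible.

# 3x5 bitmap digits, rows top to bottom
.digit_font <- list(
  "0" = c("111", "101", "101", "101", "111"),
  "1" = c("010", "110", "010", "010", "111"),
  "2" = c("111", "001", "111", "100", "111"),
  "3" = c("111", "001", "111", "001", "111"),
  "4" = c("101", "101", "111", "001", "001"),
  "5" = c("111", "100", "111", "001", "111"),
  "6" = c("111", "100", "111", "101", "111"),
  "7" = c("111", "001", "010", "010", "010"),
  "8" = c("111", "101", "111", "101", "111"),
  "9" = c("111", "101", "111", "001", "111")
)

# deterministic, well-separated label colours (golden-angle hue walk)
label_color <- function(k) {
  hue <- (k * 0.6180339887) %% 1
  col2rgb(hsv(hue, 0.85, 1))[, 1]
}

draw_number <- function(ch, number, row, col, scale = 3, fg = c(0, 0, 0)) {
  digits <- strsplit(as.character(number), "")[[1]]
  W <- ncol(ch[[1]]); H <- nrow(ch[[1]])
  x0 <- col - (length(digits) * 4 * scale) %/% 2
  for (d in digits) {
    pat <- .digit_font[[d]]
    for (r in 1:5) {
      bits <- strsplit(pat[r], "")[[1]] == "1"
      for (cc in 1:3) {
        if (!bits[cc]) next
        rr <- row + (r - 3) * scale + seq_len(scale) - 1L
        ccs <- x0 + (cc - 1) * scale + seq_len(scale) - 1L
        rr <- rr[rr >= 1 & rr <= H]; ccs <- ccs[ccs >= 1 & ccs <= W]
        if (!length(rr) || !length(ccs)) next
        for (j in 1:3) ch[[j]][rr, ccs] <- fg[j]
      }
    }
    x0 <- x0 + 4 * scale
  }
  ch
}

tint_panel <- function(image, regions, alpha = 0.55) {
  ch <- lapply(1:3, function(j) unclass(image)[, , j])
  if (regions$count > 0) {
    for (k in seq_len(regions$count)) {
      colk <- label_color(k)
      sel <- regions$labels == k
      for (j in 1:3) {
        ch[[j]][sel] <- round((1 - alpha) * ch[[j]][sel] + alpha * colk[j])
      }
    }
    # number at each centroid
    idx <- which(regions$labels > 0)
    H <- nrow(regions$labels)
    rows <- ((idx - 1L) %% H) + 1L
    cols <- ((idx - 1L) %/% H) + 1L
    labs <- regions$labels[idx]
    cen_r <- round(tapply(rows, labs, mean))
    cen_c <- round(tapply(cols, labs, mean))
    for (k in seq_len(regions$count)) {
      ch <- draw_number(ch, k, cen_r[[as.character(k)]], cen_c[[as.character(k)]])
    }
  }
  ch
}

#' Render the validation overlay triptych
#'
#' Side-by-side panels: input image, mucilage labels, seed labels. Each
#' object is tinted with a deterministic per-label colour and its number is
#' drawn at its centroid. With empty labelings the panels show the untinted
#' image.
#'
#' @param image the analysed [rgb_image].
#' @param seed_regions,mucilage_regions `labeled_regions` objects on the
#'   same frame as `image`.
#' @return An [rgb_image] of width `3 * W`.
#' @export
render_overlay <- function(image, seed_regions, mucilage_regions) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image)
  if (!identical(dim(seed_regions$labels), d[1:2]) ||
      !identical(dim(mucilage_regions$labels), d[1:2])) {
    sh_abort("regions do not match the image frame", "seedhalo_format_error")
  }
  muc <- tint_panel(image, mucilage_regions)
  sed <- tint_panel(image, seed_regions)
  out <- array(0, dim = c(d[1], 3 * d[2], 3))
  for (j in 1:3) {
    out[, 1:d[2], j] <- unclass(image)[, , j]
    out[, (d[2] + 1):(2 * d[2]), j] <- muc[[j]]
    out[, (2 * d[2] + 1):(3 * d[2]), j] <- sed[[j]]
  }
  rgb_image(out)
}
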