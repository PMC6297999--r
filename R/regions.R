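#' Labeled regions
#'
#' Integer-labelled connected components of a binary mask, numbered line by
#' line from the top of the image: label `k` is the component whose anchor
#' (topmost pixel, ties broken by smallest column) comes `k`-th in raster
#' order. Foreground connectivity is 8-connected, so compact blobs with
#' anti-aliased boundaries stay in one piece.
#'
#' Implementation: the 4-connected pass is delegated to
#' [EBImage::bwlabel()]; diagonal-only contacts are then merged with a small
#' union-find over the provisional labels, and the merged components are
#' renumbered by their anchors.
#'
#' @param mask logical matrix.
#' @return A `labeled_regions` object: list with `labels` (integer matrix,
#'   0 = background), `count`, and `anchors` (tibble of `label`, `row`,
#'   `col` anchor coordinates, 1-based).
#' @examples
#' m <- matrix(FALSE, 5, 5); m[2, 2] <- TRUE; m[3, 3] <- TRUE
#' label_components(m)$count  # 1 (diagonal touch joins)
#' @export
label_components <- function(mask) {
  stopifnot(is.logical(mask), is.matrix(mask))
  H <- nrow(mask); W <- ncol(mask)
  if (!any(mask)) {
    return(new_labeled_regions(matrix(0L, H, W), 0L,
                               tibble(label = integer(), row = integer(),
                                      col = integer())))
  }
  lab4 <- EBImage::bwlabel(matrix(as.numeric(mask), H, W))
  lab4 <- matrix(as.integer(lab4), H, W)
  n4 <- max(lab4)

  # merge labels that touch only diagonally (8-connectivity)
  parent <- seq_len(n4)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[max(ra, rb)] <<- min(ra, rb)
    invisible(NULL)
  }
  if (H > 1 && W > 1) {
    a1 <- lab4[-H, -W]; b1 <- lab4[-1, -1]   # down-right diagonal
    a2 <- lab4[-H, -1]; b2 <- lab4[-1, -W]   # down-left diagonal
    pairs <- rbind(cbind(as.vector(a1), as.vector(b1)),
                   cbind(as.vector(a2), as.vector(b2)))
    pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 &
                     pairs[, 1] != pairs[, 2], , drop = FALSE]
    if (nrow(pairs)) {
      pairs <- unique(pairs)
      for (i in seq_len(nrow(pairs))) union_(pairs[i, 1], pairs[i, 2])
    }
  }
  root <- vapply(seq_len(n4), find, integer(1))

  # anchor of each merged component = minimal raster index (row-major)
  fg <- which(mask)                      # column-major linear indices
  rows <- ((fg - 1L) %% H) + 1L
  cols <- ((fg - 1L) %/% H) + 1L
  comp <- root[lab4[fg]]
  raster <- (rows - 1L) * W + (cols - 1L)
  anchor_by_comp <- tapply(raster, comp, min)
  ord <- order(anchor_by_comp)
  new_of_comp <- integer(max(comp))
  new_of_comp[as.integer(names(anchor_by_comp))[ord]] <- seq_along(ord)

  labels <- matrix(0L, H, W)
  labels[fg] <- new_of_comp[comp]
  anchors_raster <- sort(as.integer(anchor_by_comp))
  anchors <- tibble(label = seq_along(ord),
                    row = anchors_raster %/% W + 1L,
                    col = anchors_raster %% W + 1L)
  new_labeled_regions(labels, length(ord), anchors)
}

new_labeled_regions <- function(labels, count, anchors) {
  structure(list(labels = labels, count = as.integer(count),
                 anchors = anchors),
            class = "labeled_regions")
}

#' @export
print.labeled_regions <- function(x, ...) {
  cat(sprintf("<labeled_regions> %d object(s) on %d x %d px\n",
              x$count, nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Area-range filter
#'
#' @param min_mm2 lower bound (mm^2), `>= 0`.
#' @param max_mm2 upper bound (mm^2), `> min_mm2`; may be `Inf`.
#' @return An `area_range_filter` object.
#' @export
area_range_filter <- function(min_mm2, max_mm2) {
  if (!is.numeric(min_mm2) || !is.numeric(max_mm2) || min_mm2 < 0 ||
      is.na(min_mm2) || is.na(max_mm2) || min_mm2 >= max_mm2) {
    sh_abort("need 0 <= min_mm2 < max_mm2", "seedhalo_parameter_error")
  }
  structure(list(min_mm2 = as.numeric(min_mm2), max_mm2 = as.numeric(max_mm2)),
            class = "area_range_filter")
}

#' Default area-range filters
#'
#' For mucilage halos the flax default is 18-315 mm^2, which both rejects
#' specks and automatically deletes two or more halos that have merged on
#' the gel. The seed filter (0.5-50 mm^2) drops dust specks and oversized
#' debris; it is a package default, configurable per species.
#'
#' @param target `"mucilage"` or `"seed"`.
#' @return An [area_range_filter].
#' @export
default_area_filter <- function(target = c("mucilage", "seed")) {
  target <- match.arg(target)
  if (target == "mucilage") area_range_filter(18, 315)
  else area_range_filter(0.5, 50)
}

#' Remove components whose area falls outside a range
#'
#' Components with calibrated area outside `[min_mm2, max_mm2]` (inclusive)
#' are deleted; survivors are renumbered `1..m` preserving the original
#' top-to-bottom order. The removed objects are recorded in the `removed`
#' attribute (tibble of original `label`, `area_mm2`, `reason`).
#'
#' @param regions a `labeled_regions` object.
#' @param filt an [area_range_filter].
#' @param cal a [calibration].
#' @return A filtered `labeled_regions`, with attribute `removed`.
#' @export
filter_by_area <- function(regions, filt, cal) {
  stopifnot(inherits(regions, "labeled_regions"),
            inherits(filt, "area_range_filter"),
            inherits(cal, "calibration"))
  if (regions$count == 0) {
    attr(regions, "removed") <- tibble(label = integer(), area_mm2 = numeric(),
                                       reason = character())
    return(regions)
  }
  px <- tabulate(regions$labels[regions$labels > 0], nbins = regions$count)
  mm2 <- px_area_to_mm2(px, cal)
  keep <- mm2 >= filt$min_mm2 & mm2 <= filt$max_mm2
  removed <- tibble(label = which(!keep), area_mm2 = mm2[!keep],
                    reason = ifelse(mm2[!keep] < filt$min_mm2,
                                    "below_min_area", "above_max_area"))
  relabel <- integer(regions$count)
  relabel[keep] <- seq_len(sum(keep))
  labels <- regions$labels
  labels[labels > 0] <- relabel[labels[labels > 0]]
  out <- new_labeled_regions(labels, sum(keep),
                             regions$anchors[keep, ] |>
                               mutate(label = seq_len(sum(keep))))
  attr(out, "removed") <- removed
  out
}

#' Labels of regions touching the image border
#'
#' @param regions a `labeled_regions` object.
#' @return Sorted integer vector of labels with at least one pixel on the
#'   first/last row or column.
#' @export
flag_border_regions <- function(regions) {
  stopifnot(inherits(regions, "labeled_regions"))
  l <- regions$labels
  edge <- c(l[1, ], l[nrow(l), ], l[, 1], l[, ncol(l)])
  sort(unique(edge[edge > 0]))
}
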