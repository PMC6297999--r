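#' Tidy a plate analysis
#'
#' Broom-style accessor returning one of the result tables as a tibble.
#'
#' @param x a `plate_analysis`.
#' @param table `"matched"` (default), `"seeds"` or `"mucilage"`.
#' @param ... unused.
#' @return A tibble.
#' @method tidy plate_analysis
#' @export
tidy.plate_analysis <- function(x, table = c("matched", "seeds", "mucilage"),
                                ...) {
  table <- match.arg(table)
  as_tibble(x[[table]])
}

#' One-row summary of a plate analysis
#'
#' @param x a `plate_analysis`.
#' @param ... unused.
#' @return A one-row tibble: object counts, median and mean adjusted
#'   mucilage content, calibration and warning count.
#' @method glance plate_analysis
#' @export
glance.plate_analysis <- function(x, ...) {
  amc <- x$matched$adjusted_mucilage_content
  tibble(
    n_seeds = nrow(x$seeds),
    n_mucilage = nrow(x$mucilage),
    n_matched = nrow(x$matched),
    mean_adjusted_content = if (length(amc)) mean(amc) else NA_real_,
    median_adjusted_content = if (length(amc)) stats::median(amc) else NA_real_,
    pixels_per_mm = x$calibration$pixels_per_mm,
    match_mode = x$match_mode,
    n_warnings = length(x$warnings))
}

#' Plot a plate analysis
#'
#' Plate map in millimetre coordinates (y increasing downwards, as in the
#' image): each matched halo is drawn as a circle of equivalent radius
#' `sqrt(AreaM / pi)` around its seed centroid, seeds as filled points
#' scaled by seed area, coloured by the adjusted mucilage content.
#'
#' @param object a `plate_analysis`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot plate_analysis
#' @export
autoplot.plate_analysis <- function(object, ...) {
  m <- object$matched
  p <- ggplot2::ggplot()
  if (nrow(m)) {
    ang <- rep(seq(0, 2 * pi, length.out = 90), times = nrow(m))
    rad <- rep(sqrt(m$mucilage_area_mm2 / pi), each = 90)
    circ <- tibble(
      pair_id = rep(m$pair_id, each = 90),
      x = rep(m$mucilage_centroid_x_mm, each = 90) + rad * cos(ang),
      y = rep(m$mucilage_centroid_y_mm, each = 90) + rad * sin(ang))
    p <- p +
      ggplot2::geom_path(data = circ,
                         ggplot2::aes(.data$x, .data$y, group = .data$pair_id),
                         colour = "orchid4", linewidth = 0.4) +
      ggplot2::geom_point(data = m,
                          ggplot2::aes(.data$seed_centroid_x_mm,
                                       .data$seed_centroid_y_mm,
                                       size = .data$seed_area_mm2,
                                       colour = .data$adjusted_mucilage_content)) +
      ggplot2::geom_text(data = m,
                         ggplot2::aes(.data$seed_centroid_x_mm,
                                      .data$seed_centroid_y_mm,
                                      label = .data$pair_id),
                         nudge_x = 1.2, size = 2.6) +
      ggplot2::scale_colour_viridis_c(name = "AreaM/AreaS") +
      ggplot2::scale_size_area(name = "seed mm²", max_size = 4)
  }
  p +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
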