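#' Adjusted mucilage content
#'
#' The halo area normalised by its seed's area, `AreaM / AreaS`. Because the
#' filled halo mask includes the pixels under the seed, the ratio is >= 1
#' whenever the seed lies inside its halo; a value of 1 means the halo has
#' fully eroded to the seed outline.
#'
#' @param mucilage_area_mm2,seed_area_mm2 areas in mm^2 (vectorised);
#'   `seed_area_mm2` must be positive.
#' @return Unitless ratio(s).
#' @examples
#' adjusted_content(120, 8)   # 15
#' @export
adjusted_content <- function(mucilage_area_mm2, seed_area_mm2) {
  if (any(is.na(seed_area_mm2)) || any(seed_area_mm2 <= 0)) {
    sh_abort("adjusted mucilage content is undefined for zero seed area",
             "seedhalo_undefined_metric")
  }
  mucilage_area_mm2 / seed_area_mm2
}

#' Pair seeds with mucilage halos by sowing rank
#'
#' Seeds sown along a diagonal are numbered top to bottom, and so are their
#' halos, so object `k` of one table corresponds to object `k` of the other.
#' If the two tables have unequal lengths the surplus objects are reported
#' unpaired with a warning: unequal counts are the known hazard of rank
#' matching (a large halo detected one line early shifts every subsequent
#' rank by one).
#'
#' @param seeds,mucilages metric tibbles from [measure_regions()], in label
#'   order.
#' @return A tibble of matched pairs: `pair_id`, `match_mode`, seed metrics
#'   prefixed `seed_`, halo metrics prefixed `mucilage_`, and
#'   `adjusted_mucilage_content`. Attribute `unpaired` holds the surplus
#'   objects (tibble of `role`, `label`, `area_mm2`).
#' @export
match_by_rank <- function(seeds, mucilages) {
  n <- nrow(seeds); m <- nrow(mucilages)
  k <- min(n, m)
  unpaired <- bind_rows(
    if (n > k) tibble(role = "seed", label = seeds$label[(k + 1):n],
                      area_mm2 = seeds$area_mm2[(k + 1):n]),
    if (m > k) tibble(role = "mucilage", label = mucilages$label[(k + 1):m],
                      area_mm2 = mucilages$area_mm2[(k + 1):m])
  )
  if (is.null(unpaired)) {
    unpaired <- tibble(role = character(), label = integer(),
                       area_mm2 = numeric())
  }
  if (n != m) {
    warn(sprintf(paste0(
      "seed/mucilage counts differ (%d vs %d): %d object(s) left unpaired; ",
      "ranks may be shifted (a halo detected one line early mislabels all ",
      "later objects) - consider containment matching"), n, m, abs(n - m)))
  }
  pairs <- pair_table(seeds[seq_len(k), , drop = FALSE],
                      mucilages[seq_len(k), , drop = FALSE], "rank")
  attr(pairs, "unpaired") <- unpaired
  pairs
}

#' Pair seeds with mucilage halos by centroid containment
#'
#' A seed is paired with the halo whose region contains the seed's centroid
#' pixel. This is robust to non-diagonal sowing and to rank shifts. A halo
#' containing two or more seed centroids is a merged halo: it yields no
#' pairs and a warning. Seeds whose centroid falls in no halo are reported
#' unmatched (e.g. mucilage-free mutants).
#'
#' @param seed_regions,mucilage_regions `labeled_regions` objects sharing
#'   the image coordinate frame.
#' @param cal a [calibration].
#' @param seeds,mucilages optional pre-computed metric tibbles (computed
#'   from the regions if omitted).
#' @return As [match_by_rank()]; `match_mode` is `"containment"`.
#' @export
match_by_containment <- function(seed_regions, mucilage_regions, cal,
                                 seeds = NULL, mucilages = NULL) {
  stopifnot(inherits(seed_regions, "labeled_regions"),
            inherits(mucilage_regions, "labeled_regions"))
  if (!identical(dim(seed_regions$labels), dim(mucilage_regions$labels))) {
    sh_abort("seed and mucilage regions must share the image frame",
             "seedhalo_format_error")
  }
  if (is.null(seeds)) seeds <- measure_regions(seed_regions, cal)
  if (is.null(mucilages)) mucilages <- measure_regions(mucilage_regions, cal)

  ppmm <- cal$pixels_per_mm
  host <- integer(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    r <- max(1L, min(nrow(mucilage_regions$labels),
                     round(seeds$centroid_y_mm[i] * ppmm)))
    c <- max(1L, min(ncol(mucilage_regions$labels),
                     round(seeds$centroid_x_mm[i] * ppmm)))
    host[i] <- mucilage_regions$labels[r, c]
  }
  tab <- table(host[host > 0])
  merged <- as.integer(names(tab)[tab >= 2])
  if (length(merged)) {
    warn(sprintf("mucilage region(s) %s contain >= 2 seed centroids (merged halos); no pairs emitted for them",
                 paste(merged, collapse = ", ")))
  }
  ok <- host > 0 & !(host %in% merged)
  unmatched_seeds <- which(!ok)
  if (length(unmatched_seeds)) {
    warn(sprintf("%d seed(s) without a matched halo: labels %s",
                 length(unmatched_seeds),
                 paste(seeds$label[unmatched_seeds], collapse = ", ")))
  }
  unpaired <- bind_rows(
    if (length(unmatched_seeds))
      tibble(role = "seed", label = seeds$label[unmatched_seeds],
             area_mm2 = seeds$area_mm2[unmatched_seeds]),
    {
      um <- setdiff(mucilages$label, host[ok])
      if (length(um)) tibble(role = "mucilage", label = um,
                             area_mm2 = mucilages$area_mm2[match(um, mucilages$label)])
    }
  )
  if (is.null(unpaired)) {
    unpaired <- tibble(role = character(), label = integer(),
                       area_mm2 = numeric())
  }
  s_idx <- which(ok)
  m_idx <- match(host[ok], mucilages$label)
  pairs <- pair_table(seeds[s_idx, , drop = FALSE],
                      mucilages[m_idx, , drop = FALSE], "containment")
  attr(pairs, "unpaired") <- unpaired
  pairs
}

# Combine matched seed and halo rows into the output pair table.
pair_table <- function(seed_rows, muc_rows, mode) {
  k <- nrow(seed_rows)
  if (k == 0) {
    out <- bind_cols(
      tibble(pair_id = integer(), match_mode = character()),
      rename_with(seed_rows[0, ], ~ paste0("seed_", .x)),
      rename_with(muc_rows[0, ], ~ paste0("mucilage_", .x)))
    out$adjusted_mucilage_content <- numeric()
    return(out)
  }
  out <- bind_cols(
    tibble(pair_id = seq_len(k), match_mode = mode),
    rename_with(seed_rows, ~ paste0("seed_", .x)),
    rename_with(muc_rows, ~ paste0("mucilage_", .x)))
  out$adjusted_mucilage_content <-
    adjusted_content(out$mucilage_area_mm2, out$seed_area_mm2)
  out
}
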