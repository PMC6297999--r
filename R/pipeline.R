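#' Analyse one plate image
#'
#' The full measurement chain on a calibrated image: segment mucilage halos
#' and seeds in HSV space, fill holes, label objects line by line from the
#' top, apply the area-range filters, compute the eleven shape descriptors
#' per object, flag border-touching objects, and pair each seed with its
#' halo to obtain the adjusted mucilage content.
#'
#' @param image an [rgb_image] (already cropped to the plate interior).
#' @param cal a [calibration].
#' @param mucilage_params,seed_params [seg_params]; default to the flax
#'   defaults, or to automatic suggestions when `auto_threshold = TRUE`.
#' @param mucilage_filter,seed_filter [area_range_filter]s.
#' @param match_mode `"rank"` (fidelity to diagonal sowing) or
#'   `"containment"` (robust to rank shifts; recommended).
#' @param auto_threshold derive thresholds from the image histograms
#'   instead of the shipped defaults.
#' @param delete_border drop objects touching the image border instead of
#'   merely flagging them.
#' @return A `plate_analysis` object: list with the metric tibbles
#'   (`seeds`, `mucilage`, each with a `border` flag column), the matched
#'   pair table (`matched`), the `labeled_regions`, the calibration, the
#'   parameters used, and any accumulated `warnings`.
#' @seealso [run_pipeline()] for the file-writing wrapper, [tidy.plate_analysis()],
#'   [autoplot.plate_analysis()].
#' @export
analyze_plate <- function(image, cal,
                          mucilage_params = NULL, seed_params = NULL,
                          mucilage_filter = default_area_filter("mucilage"),
                          seed_filter = default_area_filter("seed"),
                          match_mode = c("rank", "containment"),
                          auto_threshold = FALSE,
                          delete_border = FALSE) {
  match_mode <- match.arg(match_mode)
  stopifnot(inherits(image, "rgb_image"), inherits(cal, "calibration"))
  warnings <- character()
  note <- function(w) warnings <<- c(warnings, w)

  planes <- rgb_to_hsv_planes(image)
  if (auto_threshold) {
    if (is.null(mucilage_params)) {
      mucilage_params <- withCallingHandlers(
        suggest_seg_params(planes, "mucilage"),
        warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    }
    if (is.null(seed_params)) {
      seed_params <- withCallingHandlers(
        suggest_seg_params(planes, "seed"),
        warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
    }
  }
  if (is.null(mucilage_params)) mucilage_params <- default_seg_params("mucilage")
  if (is.null(seed_params)) seed_params <- default_seg_params("seed")

  muc_mask <- fill_holes(band_mask(planes, mucilage_params))
  seed_mask <- fill_holes(band_mask(planes, seed_params))
  if (!any(muc_mask) && !any(seed_mask)) {
    sh_abort("empty segmentation: no pixel falls in either threshold band",
             "seedhalo_empty_segmentation")
  }
  if (!any(muc_mask)) note("mucilage segmentation is empty")
  if (!any(seed_mask)) note("seed segmentation is empty")

  muc_regions <- filter_by_area(label_components(muc_mask), mucilage_filter, cal)
  seed_regions <- filter_by_area(label_components(seed_mask), seed_filter, cal)
  for (role in c("mucilage", "seed")) {
    rem <- attr(if (role == "mucilage") muc_regions else seed_regions, "removed")
    if (nrow(rem)) {
      note(sprintf("%s: removed %d object(s) by area filter (labels %s; %s mm2)",
                   role, nrow(rem), paste(rem$label, collapse = ","),
                   paste(round(rem$area_mm2, 2), collapse = ",")))
    }
  }

  muc_border <- flag_border_regions(muc_regions)
  seed_border <- flag_border_regions(seed_regions)
  if (delete_border) {
    drop_labels <- function(regions, labels) {
      if (!length(labels)) return(regions)
      keep_filter <- area_range_filter(0, Inf)
      lab <- regions$labels
      lab[lab %in% labels] <- 0L
      relab <- label_components(lab > 0)
      relab
    }
    if (length(muc_border)) {
      note(sprintf("mucilage: deleted border-touching object(s) %s",
                   paste(muc_border, collapse = ",")))
      muc_regions <- drop_labels(muc_regions, muc_border)
      muc_border <- integer()
    }
    if (length(seed_border)) {
      note(sprintf("seed: deleted border-touching object(s) %s",
                   paste(seed_border, collapse = ",")))
      seed_regions <- drop_labels(seed_regions, seed_border)
      seed_border <- integer()
    }
  }

  seeds <- measure_regions(seed_regions, cal)
  mucilage <- measure_regions(muc_regions, cal)
  seeds$border <- seeds$label %in% seed_border
  mucilage$border <- mucilage$label %in% muc_border

  matched <- withCallingHandlers(
    if (match_mode == "rank") {
      match_by_rank(seeds, mucilage)
    } else {
      match_by_containment(seed_regions, muc_regions, cal,
                           seeds = seeds, mucilages = mucilage)
    },
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })

  structure(list(
    image = image, calibration = cal,
    mucilage_params = mucilage_params, seed_params = seed_params,
    mucilage_filter = mucilage_filter, seed_filter = seed_filter,
    match_mode = match_mode,
    seed_regions = seed_regions, mucilage_regions = muc_regions,
    seeds = seeds, mucilage = mucilage, matched = matched,
    warnings = warnings), class = "plate_analysis")
}

#' @export
print.plate_analysis <- function(x, ...) {
  cat(sprintf(paste0(
    "<plate_analysis> %d seed(s), %d mucilage halo(s), %d matched pair(s) [%s]\n"),
    nrow(x$seeds), nrow(x$mucilage), nrow(x$matched), x$match_mode))
  if (nrow(x$matched)) {
    cat(sprintf("  adjusted mucilage content: median %.2f (range %.2f-%.2f)\n",
                stats::median(x$matched$adjusted_mucilage_content),
                min(x$matched$adjusted_mucilage_content),
                max(x$matched$adjusted_mucilage_content)))
  }
  if (length(x$warnings)) {
    cat(sprintf("  %d warning(s); first: %s\n", length(x$warnings),
                x$warnings[1]))
  }
  invisible(x)
}

#' Run configuration
#'
#' Bundles everything one analysis run needs. Exactly one calibration source
#' must be given: either `plate_mm` (the physical width of the imaged plate;
#' the scale is `image width in px / plate_mm`) or `cal_points`
#' (`c(x1, y1, x2, y2, mm)`, two marked points plus their distance).
#'
#' @param input path to the plate image.
#' @param output_dir directory for the result files.
#' @param plate_mm plate width in mm, or `NULL`.
#' @param cal_points numeric length-5 `c(x1, y1, x2, y2, mm)`, or `NULL`.
#' @param crop optional [crop_window] applied before analysis.
#' @param preset optional species preset name (see [species_preset()]).
#' @param mucilage_params,seed_params,mucilage_filter,seed_filter optional
#'   overrides (win over the preset).
#' @param match_mode,auto_threshold,delete_border see [analyze_plate()].
#' @return A `run_config` object.
#' @export
run_config <- function(input, output_dir,
                       plate_mm = NULL, cal_points = NULL, crop = NULL,
                       preset = NULL,
                       mucilage_params = NULL, seed_params = NULL,
                       mucilage_filter = NULL, seed_filter = NULL,
                       match_mode = "rank",
                       auto_threshold = FALSE, delete_border = FALSE) {
  if (is.null(plate_mm) == is.null(cal_points)) {
    sh_abort("supply exactly one calibration source: `plate_mm` or `cal_points`",
             "seedhalo_config_error")
  }
  if (!is.null(cal_points) && length(cal_points) != 5) {
    sh_abort("`cal_points` must be c(x1, y1, x2, y2, mm)",
             "seedhalo_config_error")
  }
  if (!is.null(preset)) {
    p <- species_preset(preset)
    if (is.null(mucilage_params)) mucilage_params <- p$mucilage_params
    if (is.null(seed_params)) seed_params <- p$seed_params
    if (is.null(mucilage_filter)) mucilage_filter <- p$mucilage_filter
    if (is.null(seed_filter)) seed_filter <- p$seed_filter
  }
  structure(list(
    input = input, output_dir = output_dir, plate_mm = plate_mm,
    cal_points = cal_points, crop = crop, preset = preset,
    mucilage_params = mucilage_params, seed_params = seed_params,
    mucilage_filter = mucilage_filter, seed_filter = seed_filter,
    match_mode = match_mode, auto_threshold = isTRUE(auto_threshold),
    delete_border = isTRUE(delete_border)), class = "run_config")
}

#' Run the full pipeline and write the result files
#'
#' Executes crop, calibration, segmentation, labelling, filtering,
#' measurement and matching, then writes `seeds.csv`, `mucilage.csv`,
#' `matched.csv`, `overlay.png` and `run.log` into the output directory.
#' The run is a pure function of the image bytes and the configuration:
#' repeated runs produce byte-identical outputs.
#'
#' @param config a [run_config].
#' @return A summary list (`n_seeds`, `n_mucilage`, `n_matched`,
#'   `warnings`, `files`), invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  image <- read_plate_image(config$input)
  if (!is.null(config$crop)) image <- crop_image(image, config$crop)
  cal <- if (!is.null(config$plate_mm)) {
    calibration(ncol_image(image) / config$plate_mm)
  } else {
    compute_scale(config$cal_points[1:2], config$cal_points[3:4],
                  config$cal_points[5])
  }
  args <- list(image = image, cal = cal,
               match_mode = config$match_mode,
               auto_threshold = config$auto_threshold,
               delete_border = config$delete_border)
  for (nm in c("mucilage_params", "seed_params", "mucilage_filter",
               "seed_filter")) {
    if (!is.null(config[[nm]])) args[[nm]] <- config[[nm]]
  }
  res <- do.call(analyze_plate, args)

  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(config$output_dir,
                     c("seeds.csv", "mucilage.csv", "matched.csv",
                       "overlay.png", "run.log"))
  names(paths) <- c("seeds", "mucilage", "matched", "overlay", "log")
  readr::write_csv(round_num(res$seeds), paths["seeds"])
  readr::write_csv(round_num(res$mucilage), paths["mucilage"])
  readr::write_csv(round_num(res$matched), paths["matched"])
  overlay <- render_overlay(res$image, res$seed_regions, res$mucilage_regions)
  write_plate_image(overlay, paths["overlay"])
  log_lines <- c(
    sprintf("input: %s", config$input),
    sprintf("calibration: %.6f px/mm", cal$pixels_per_mm),
    sprintf("match_mode: %s", res$match_mode),
    sprintf("objects: %d seed(s), %d mucilage halo(s), %d pair(s)",
            nrow(res$seeds), nrow(res$mucilage), nrow(res$matched)),
    if (length(res$warnings)) paste0("warning: ", res$warnings) else
      "warnings: none")
  writeLines(log_lines, paths["log"])

  invisible(list(n_seeds = nrow(res$seeds), n_mucilage = nrow(res$mucilage),
                 n_matched = nrow(res$matched), warnings = res$warnings,
                 files = paths, analysis = res))
}

ncol_image <- function(image) dim(image)[2]

# areas etc. are written to 4 decimals so reruns are byte-stable across
# platforms
round_num <- function(df) {
  mutate(df, dplyr::across(dplyr::where(is.numeric), ~ round(.x, 4)))
}
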