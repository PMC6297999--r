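#' Species threshold presets
#'
#' Loads the per-species preset shipped with the package: HSV bands for
#' mucilage and seed segmentation plus the area-range filters. All species
#' currently ship with the flax-calibrated threshold bands; the area filters
#' are scaled to typical seed/halo sizes per species and are provisional
#' defaults. The recalibration procedure (run the automatic threshold
#' suggester on a representative plate, inspect the overlay, adjust bands)
#' is described in the package vignette.
#'
#' @param species one of `"linum"`, `"arabidopsis"`, `"camelina"`,
#'   `"plantago"`, `"capsella"`.
#' @return A list with `mucilage_params`, `seed_params` ([seg_params]) and
#'   `mucilage_filter`, `seed_filter` ([area_range_filter]).
#' @export
species_preset <- function(species = c("linum", "arabidopsis", "camelina",
                                       "plantago", "capsella")) {
  species <- tryCatch(match.arg(species),
                      error = function(e) sh_abort(
                        "unknown species preset", "seedhalo_parameter_error"))
  path <- system.file("extdata", "presets.yaml", package = "seedhalo",
                      mustWork = TRUE)
  all <- yaml::read_yaml(path)
  p <- all[[species]]
  band <- function(v) { v <- unlist(v); channel_band(v[1], v[2]) }
  rng <- function(v) unlist(v)
  list(
    species = species,
    mucilage_params = seg_params(band(p$mucilage$h), band(p$mucilage$s),
                                 band(p$mucilage$v), "mucilage"),
    seed_params = seg_params(band(p$seed$h), band(p$seed$s),
                             band(p$seed$v), "seed"),
    mucilage_filter = area_range_filter(rng(p$mucilage_area)[1],
                                        rng(p$mucilage_area)[2]),
    seed_filter = area_range_filter(rng(p$seed_area)[1], rng(p$seed_area)[2])
  )
}
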