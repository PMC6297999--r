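# Synthetic stained-plate generator with analytic ground truth.
#
# Emulates a toluidine-blue-O assay plate: light-blue gel background, dark
# elliptical seeds, concentric purple-pink halos with a radial dye gradient,
# optional Gaussian sensor noise. Geometry is exact (pixel centres tested
# against analytic shapes), so every downstream measurement can be compared
# with closed-form truth. Seeds are "sown" the way a practitioner sows them:
# along diagonal lines, each successive seed strictly lower on the plate, so
# top-to-bottom numbering pairs seed k with halo k by construction.

#' Synthetic plate specification
#'
#' Defaults describe a flax (Linum) assay plate: about 30 seeds per plate,
#' seeds ~4.8 x 2.4 mm, halos ~9.6 mm across (48-106 mm^2, inside the
#' 18-315 mm^2 mucilage filter), imaged at 8 px/mm. Colours are package
#' constants chosen so that the shipped default thresholds segment them:
#' background (190,215,235) has hue below the mucilage band, halo colours
#' (200,120,180)-(215,150,200) sit inside all three mucilage bands, and the
#' seed colour (60,40,30) has value <= 70.
#'
#' @param n_seeds number of seeds (>= 1).
#' @param pixels_per_mm image resolution (px/mm).
#' @param sowing `"diagonal"` (successive seeds strictly lower, ranks exact),
#'   `"jittered"` (positions perturbed; pairing must rely on containment) or
#'   `"overlap_pair"` (two oversized halos drawn to merge, for the
#'   area-filter scenario).
#' @param noise_sigma standard deviation of additive Gaussian noise on each
#'   8-bit channel (0 = clean).
#' @param seed_axes_mm mean semi-axes `c(major, minor)` of the seed ellipses.
#' @param halo_radius_mm mean halo outer radius; individual radii vary
#'   mildly around it (truncated so consecutive tops stay ordered and halos
#'   never merge outside the overlap scenario).
#' @param seed_scale overall size multiplier (species variants).
#' @param no_halo_ids sowing ranks of seeds that release no mucilage.
#' @param border_touch if `TRUE`, the first halo is placed crossing the top
#'   image border.
#' @param gradient use a radial colour gradient across the halo (uniform
#'   colour if `FALSE`, for exact-geometry tests).
#' @param background,seed_color,halo_inner,halo_outer RGB triplets.
#' @param rng_seed integer; the whole plate is a deterministic function of
#'   the spec including this seed.
#' @return A `plate_spec` object.
#' @export
plate_spec <- function(n_seeds = 30,
                       pixels_per_mm = 8,
                       sowing = c("diagonal", "jittered", "overlap_pair"),
                       noise_sigma = 0,
                       seed_axes_mm = c(2.4, 1.2),
                       halo_radius_mm = 4.8,
                       seed_scale = 1,
                       no_halo_ids = integer(),
                       border_touch = FALSE,
                       gradient = TRUE,
                       background = c(190, 215, 235),
                       seed_color = c(60, 40, 30),
                       halo_inner = c(200, 120, 180),
                       halo_outer = c(215, 150, 200),
                       rng_seed = 1L) {
  sowing <- match.arg(sowing)
  if (n_seeds < 1 || n_seeds != round(n_seeds)) {
    sh_abort("`n_seeds` must be a positive integer", "seedhalo_parameter_error")
  }
  if (noise_sigma < 0 || pixels_per_mm <= 0 || seed_scale <= 0) {
    sh_abort("noise_sigma, pixels_per_mm and seed_scale must be non-negative/positive",
             "seedhalo_parameter_error")
  }
  if (halo_radius_mm * seed_scale <= max(seed_axes_mm) * seed_scale) {
    sh_abort("halo radius must exceed the seed semi-major axis",
             "seedhalo_parameter_error")
  }
  structure(list(
    n_seeds = as.integer(n_seeds), pixels_per_mm = pixels_per_mm,
    sowing = sowing, noise_sigma = noise_sigma,
    seed_axes_mm = seed_axes_mm, halo_radius_mm = halo_radius_mm,
    seed_scale = seed_scale, no_halo_ids = as.integer(no_halo_ids),
    border_touch = isTRUE(border_touch), gradient = isTRUE(gradient),
    background = background, seed_color = seed_color,
    halo_inner = halo_inner, halo_outer = halo_outer,
    rng_seed = as.integer(rng_seed)), class = "plate_spec")
}

# run code with a locally-set RNG seed, restoring global state afterwards
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic plate image with ground truth
#'
#' Deterministic for a fixed spec (including its `rng_seed`): the same spec
#' always renders byte-identical pixels. Halos are concentric with their
#' seeds. In diagonal sowing the seed and halo anchor pixels are strictly
#' ordered top to bottom in sowing order, so rank matching recovers the true
#' pairing exactly.
#'
#' @param spec a [plate_spec].
#' @return A list with `image` ([rgb_image]), `ground_truth` (tibble: per
#'   seed the sowing rank, centre, semi-axes, rotation, analytic seed area /
#'   perimeter (Ramanujan) / circularity / Feret, halo radius and area, and
#'   the true adjusted mucilage content) and `calibration`.
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  with_local_seed(spec$rng_seed, render_plate(spec))
}

render_plate <- function(spec) {
  ppmm <- spec$pixels_per_mm
  sc <- spec$seed_scale
  n <- spec$n_seeds

  if (spec$sowing == "overlap_pair") {
    # two oversized halos (~170 mm^2 each) whose union (~330 mm^2) exceeds
    # the 315 mm^2 filter bound
    R <- rep(sqrt(170 / pi), 2)[seq_len(min(n, 2))]
    n <- length(R)
    a <- rep(spec$seed_axes_mm[1] * sc, n)
    b <- rep(spec$seed_axes_mm[2] * sc, n)
    theta <- rep(0, n)
    cx <- 14 + c(0, 13)[seq_len(n)]
    cy <- 12 + c(0, 2)[seq_len(n)]
    width_mm <- 42; height_mm <- 26
    has_halo <- rep(TRUE, n)
  } else {
    a <- rtrunc_norm(n, spec$seed_axes_mm[1] * sc, 0.05 * spec$seed_axes_mm[1] * sc,
                     0.85 * spec$seed_axes_mm[1] * sc, 1.15 * spec$seed_axes_mm[1] * sc)
    b <- rtrunc_norm(n, spec$seed_axes_mm[2] * sc, 0.06 * spec$seed_axes_mm[2] * sc,
                     0.85 * spec$seed_axes_mm[2] * sc, 1.2 * spec$seed_axes_mm[2] * sc)
    theta <- runif(n, 0, pi)
    # halo radii: mild variation, truncated so consecutive halo tops keep
    # their vertical order and neighbouring halos cannot touch
    R0 <- spec$halo_radius_mm * sc
    R <- rtrunc_norm(n, R0, 0.09 * R0, 0.82 * R0, 1.2 * R0)
    # sheared grid: several diagonal lines, y strictly increasing per rank
    k <- ceiling(sqrt(n))
    sxy <- 3.4 * R0                    # centre spacing within/between lines
    margin <- 2.6 * R0
    col_of <- (seq_len(n) - 1L) %% k
    cx <- margin + col_of * sxy
    cy <- margin + (seq_len(n) - 1L) * (sxy / k)
    if (spec$sowing == "jittered") {
      cx <- cx + runif(n, -0.3 * R0, 0.3 * R0)
      cy <- cy + runif(n, -0.22 * R0, 0.22 * R0)
    }
    if (spec$border_touch) cy[1] <- 0.6 * R[1]
    width_mm <- max(cx) + margin
    height_mm <- max(cy) + margin
    has_halo <- !(seq_len(n) %in% spec$no_halo_ids)
  }

  W <- ceiling(width_mm * ppmm)
  H <- ceiling(height_mm * ppmm)
  ch <- lapply(spec$background, function(v) matrix(v, H, W))

  paint <- function(rows, cols, sel, cols3) {
    for (j in 1:3) {
      m <- ch[[j]][rows, cols]
      m[sel] <- cols3[[j]]
      ch[[j]][rows, cols] <<- m
    }
  }

  # halos first, seeds on top
  for (i in seq_len(n)) {
    if (!has_halo[i]) next
    bb <- bbox_px(cx[i], cy[i], R[i], R[i], H, W, ppmm)
    if (is.null(bb)) next
    d <- sqrt((bb$xm - cx[i])^2 + (bb$ym - cy[i])^2)
    sel <- d <= R[i]
    if (!any(sel)) next
    if (spec$gradient) {
      t <- d[sel] / R[i]
      cols3 <- lapply(1:3, function(j)
        round(spec$halo_inner[j] + (spec$halo_outer[j] - spec$halo_inner[j]) * t))
    } else {
      cols3 <- lapply(1:3, function(j) spec$halo_inner[j])
    }
    paint(bb$rows, bb$cols, sel, cols3)
  }
  for (i in seq_len(n)) {
    bb <- bbox_px(cx[i], cy[i], a[i], a[i], H, W, ppmm)
    if (is.null(bb)) next
    u <- (bb$xm - cx[i]) * cos(theta[i]) + (bb$ym - cy[i]) * sin(theta[i])
    v <- -(bb$xm - cx[i]) * sin(theta[i]) + (bb$ym - cy[i]) * cos(theta[i])
    sel <- (u / a[i])^2 + (v / b[i])^2 <= 1
    if (!any(sel)) next
    paint(bb$rows, bb$cols, sel, lapply(1:3, function(j) spec$seed_color[j]))
  }

  px <- array(0, dim = c(H, W, 3))
  for (j in 1:3) px[, , j] <- ch[[j]]
  if (spec$noise_sigma > 0) {
    px <- px + array(rnorm(length(px), 0, spec$noise_sigma), dim = dim(px))
    px <- pmin(pmax(round(px), 0), 255)
  }

  seed_perim <- ellipse_perimeter(a, b)
  seed_area <- pi * a * b
  gt <- tibble(
    seed_id = seq_len(n),
    center_x_mm = cx, center_y_mm = cy,
    semi_major_mm = a, semi_minor_mm = b, rotation_rad = theta,
    seed_area_mm2 = seed_area,
    seed_perimeter_mm = seed_perim,
    seed_circularity = pmin(4 * pi * seed_area / seed_perim^2, 1),
    seed_feret_mm = 2 * a,
    seed_solidity = 1,
    has_halo = has_halo,
    halo_radius_mm = ifelse(has_halo, R, NA_real_),
    halo_area_mm2 = ifelse(has_halo, pi * R^2, NA_real_),
    halo_perimeter_mm = ifelse(has_halo, 2 * pi * R, NA_real_),
    adjusted_mucilage_content = ifelse(has_halo, pi * R^2 / seed_area, NA_real_))
  list(image = rgb_image(px), ground_truth = gt,
       calibration = calibration(ppmm))
}

# bounding box of a disc/ellipse in pixel indices + pixel-centre grids (mm)
bbox_px <- function(cx, cy, rx, ry, H, W, ppmm) {
  c0 <- max(1L, floor((cx - rx) * ppmm) - 1L)
  c1 <- min(W, ceiling((cx + rx) * ppmm) + 1L)
  r0 <- max(1L, floor((cy - ry) * ppmm) - 1L)
  r1 <- min(H, ceiling((cy + ry) * ppmm) + 1L)
  if (c0 > c1 || r0 > r1) return(NULL)
  rows <- r0:r1; cols <- c0:c1
  # pixel (r, c) centre sits at ((c - 0.5)/ppmm, (r - 0.5)/ppmm) in mm
  list(rows = rows, cols = cols,
       xm = matrix((cols - 0.5) / ppmm, length(rows), length(cols), byrow = TRUE),
       ym = matrix((rows - 0.5) / ppmm, length(rows), length(cols)))
}

# Ramanujan's second approximation; relative error < 1e-4 for aspect <= 5
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' Write the regression fixture suite
#'
#' Renders a fixed set of seeded scenario plates (clean, noisy, merged
#' halos, border-touching halo, mucilage-free seeds, and five species size
#' variants), writes each image as PNG with its ground-truth CSV, and a
#' manifest with MD5 checksums. Fully deterministic: repeated runs produce
#' identical checksums.
#'
#' @param dir output directory (created if needed).
#' @return Tibble manifest (`file`, `md5`), invisibly; also written as
#'   `manifest.txt`.
#' @export
generate_regression_suite <- function(dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  scen <- regression_scenarios()
  files <- character()
  for (name in names(scen)) {
    pl <- generate_plate(scen[[name]])
    img_path <- file.path(dir, paste0(name, ".png"))
    gt_path <- file.path(dir, paste0(name, "_truth.csv"))
    write_plate_image(pl$image, img_path)
    readr::write_csv(pl$ground_truth, gt_path)
    files <- c(files, img_path, gt_path)
  }
  md5 <- tools::md5sum(files)
  manifest <- tibble(file = basename(files), md5 = unname(md5))
  readr::write_csv(manifest, file.path(dir, "manifest.txt"))
  invisible(manifest)
}

regression_scenarios <- function() {
  list(
    clean        = plate_spec(n_seeds = 12, rng_seed = 101L),
    noisy        = plate_spec(n_seeds = 12, noise_sigma = 8, rng_seed = 102L),
    merged_halo  = plate_spec(n_seeds = 2, sowing = "overlap_pair",
                              rng_seed = 103L),
    border_touch = plate_spec(n_seeds = 6, border_touch = TRUE,
                              rng_seed = 104L),
    no_mucilage  = plate_spec(n_seeds = 8, no_halo_ids = c(3L, 6L),
                              rng_seed = 105L),
    linum        = plate_spec(n_seeds = 10, rng_seed = 106L),
    arabidopsis  = plate_spec(n_seeds = 10, seed_scale = 0.22,
                              pixels_per_mm = 30, rng_seed = 107L),
    camelina     = plate_spec(n_seeds = 10, seed_scale = 0.55,
                              pixels_per_mm = 12, rng_seed = 108L),
    plantago     = plate_spec(n_seeds = 10, seed_scale = 0.6,
                              pixels_per_mm = 12, rng_seed = 109L),
    capsella     = plate_spec(n_seeds = 10, seed_scale = 0.4,
                              pixels_per_mm = 16, rng_seed = 110L)
  )
}
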