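test_that("shipped default thresholds carry the published anchor values", {
  muc <- default_seg_params("mucilage")
  expect_equal(muc$h_band$low, 172L)
  expect_equal(muc$s_band$low, 24L)
  expect_equal(muc$v_band$low, 85L)
  expect_equal(c(muc$h_band$high, muc$s_band$high, muc$v_band$high),
               c(255L, 255L, 255L))
  seed <- default_seg_params("seed")
  expect_equal(seed$v_band$high, 70L)
  expect_equal(seed$v_band$low, 0L)
  expect_equal(c(seed$h_band$low, seed$h_band$high), c(0L, 255L))
  expect_error(default_seg_params("root"), class = "seedhalo_parameter_error")
  expect_error(channel_band(100, 20), class = "seedhalo_parameter_error")
})

make_planes <- function(h, s, v) {
  structure(list(h = matrix(as.integer(h), 1), s = matrix(as.integer(s), 1),
                 v = matrix(as.integer(v), 1)), class = "hsv_planes")
}

test_that("band mask is the conjunction of the three inclusive bands", {
  muc <- default_seg_params("mucilage")
  expect_true(band_mask(make_planes(200, 100, 150), muc)[1, 1])
  expect_false(band_mask(make_planes(100, 100, 150), muc)[1, 1])
  # bounds are inclusive on both ends
  expect_true(band_mask(make_planes(172, 24, 85), muc)[1, 1])
  expect_false(band_mask(make_planes(171, 24, 85), muc)[1, 1])
  seed <- default_seg_params("seed")
  expect_true(band_mask(make_planes(37, 5, 40), seed)[1, 1])
  expect_false(band_mask(make_planes(37, 5, 71), seed)[1, 1])
})

test_that("widening any band never removes pixels, and pass-all selects everything", {
  set.seed(42)
  planes <- rgb_to_hsv_planes(
    rgb_image(array(sample(0:255, 30 * 30 * 3, TRUE), dim = c(30, 30, 3))))
  pass_all <- seg_params(channel_band(0, 255), channel_band(0, 255),
                         channel_band(0, 255), "mucilage")
  expect_true(all(band_mask(planes, pass_all)))
  for (i in 1:15) {
    lo <- sample(0:150, 3)
    hi <- sample(160:255, 3)
    p1 <- seg_params(channel_band(lo[1], hi[1]), channel_band(lo[2], hi[2]),
                     channel_band(lo[3], hi[3]), "mucilage")
    p2 <- seg_params(channel_band(max(lo[1] - 10, 0), 255),
                     channel_band(max(lo[2] - 25, 0), min(hi[2] + 20, 255)),
                     channel_band(lo[3], hi[3]), "mucilage")
    m1 <- band_mask(planes, p1); m2 <- band_mask(planes, p2)
    expect_true(all(m2[m1]))
  }
})

test_that("intermeans threshold matches its definition and handles degeneracy", {
  h <- numeric(256); h[51] <- 100; h[201] <- 100
  expect_equal(isodata_threshold(h), 125L)
  h1 <- numeric(256); h1[101] <- 500
  expect_error(isodata_threshold(h1), class = "seedhalo_degenerate_histogram")
  expect_error(isodata_threshold(numeric(256)),
               class = "seedhalo_degenerate_histogram")
  h3 <- numeric(256); h3[11] <- 100; h3[21] <- 50; h3[241] <- 150
  expect_true(isodata_threshold(h3) %in% isodata_fixed_points(h3))
})

test_that("intermeans threshold is a fixed point of the exhaustive oracle", {
  set.seed(7)
  for (i in 1:100) {
    h <- random_histogram()
    t_iter <- isodata_threshold(h)
    fp <- isodata_fixed_points(h)
    expect_true(t_iter %in% fp,
                info = sprintf("iteration %d: %d not in {%s}", i, t_iter,
                               paste(fp, collapse = ",")))
  }
})

test_that("suggested thresholds split bimodal value histograms between the modes", {
  set.seed(5)
  v <- matrix(sample(c(120, 230), 400, TRUE), 20)
  h <- matrix(sample(c(180L, 220L), 400, TRUE), 20)
  s <- matrix(sample(c(60L, 120L), 400, TRUE), 20)
  planes <- structure(list(h = h, s = s, v = matrix(as.integer(v), 20, 20)),
                      class = "hsv_planes")
  sp <- suggest_seg_params(planes, "mucilage")
  expect_gt(sp$v_band$low, 120)
  expect_lt(sp$v_band$low, 230)
  expect_equal(sp$v_band$high, 255L)
})

test_that("suggestion falls back to defaults on a uniform image with a warning", {
  planes <- rgb_to_hsv_planes(flat_image(10, 10, c(190, 215, 235)))
  expect_warning(sp <- suggest_seg_params(planes, "mucilage"),
                 "degenerate")
  expect_equal(sp$h_band$low, 172L)
})

test_that("suggested bands reproduce the default classification of halo pixels", {
  pl <- generate_plate(plate_spec(n_seeds = 8, rng_seed = 21))
  planes <- rgb_to_hsv_planes(pl$image)
  m_def <- band_mask(planes, default_seg_params("mucilage"))
  m_sug <- band_mask(planes, suggest_seg_params(planes, "mucilage"))
  gt <- pl$ground_truth
  ppmm <- pl$calibration$pixels_per_mm
  d <- dim(pl$image)
  xm <- matrix((seq_len(d[2]) - 0.5) / ppmm, d[1], d[2], byrow = TRUE)
  ym <- matrix((seq_len(d[1]) - 0.5) / ppmm, d[1], d[2])
  gtmask <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(nrow(gt))) {
    gtmask <- gtmask |
      (sqrt((xm - gt$center_x_mm[i])^2 + (ym - gt$center_y_mm[i])^2) <=
         gt$halo_radius_mm[i])
  }
  expect_gte(mean(m_sug[gtmask] == m_def[gtmask]), 0.99)
})

test_that("mucilage segmentation fills each halo to a simply connected disk", {
  # annulus of halo colour around a dark seed disk
  H <- 80; W <- 80
  px <- array(rep(c(190, 215, 235), each = H * W), dim = c(H, W, 3))
  cc <- 40.5
  d <- sqrt(outer((1:H - cc)^2, (1:W - cc)^2, "+"))
  ring <- d <= 30 & d >= 18
  seedpx <- d <= 10
  for (j in 1:3) {
    ch <- px[, , j]
    ch[ring] <- c(200, 120, 180)[j]
    ch[seedpx] <- c(60, 40, 30)[j]
    px[, , j] <- ch
  }
  img <- rgb_image(px)
  mask <- segment_mucilage(img)
  disk <- d <= 30
  expect_true(all(mask[disk]))
  expect_true(!any(mask[!disk]))
  expect_gte(sum(mask), sum(ring) + sum(seedpx))

  # no pixel in band -> empty mask
  expect_false(any(segment_mucilage(flat_image(10, 10, c(190, 215, 235)))))
})

test_that("mucilage masks have no holes on generated plates", {
  pl <- generate_plate(plate_spec(n_seeds = 6, rng_seed = 9))
  mask <- segment_mucilage(pl$image)
  # every background region must reach the image border
  bg <- label_components(!mask)
  border <- flag_border_regions(bg)
  expect_setequal(seq_len(bg$count), border)
  # per-halo pixel count exceeds ring + enclosed seed pixel count
  regions <- label_components(mask)
  planes <- rgb_to_hsv_planes(pl$image)
  ring_mask <- band_mask(planes, default_seg_params("mucilage"))
  seed_mask <- band_mask(planes, default_seg_params("seed"))
  for (k in seq_len(regions$count)) {
    sel <- regions$labels == k
    expect_gte(sum(sel), sum(ring_mask[sel]) + sum(seed_mask[sel]))
    expect_gt(sum(seed_mask[sel]), 0)  # the enclosed seed is inside the fill
  }
})

test_that("noiseless segmentation recovers halo disks almost exactly (Jaccard)", {
  pl <- generate_plate(plate_spec(n_seeds = 8, rng_seed = 33))
  mask <- segment_mucilage(pl$image)
  gt <- pl$ground_truth
  ppmm <- pl$calibration$pixels_per_mm
  d <- dim(pl$image)
  xm <- matrix((seq_len(d[2]) - 0.5) / ppmm, d[1], d[2], byrow = TRUE)
  ym <- matrix((seq_len(d[1]) - 0.5) / ppmm, d[1], d[2])
  gtmask <- matrix(FALSE, d[1], d[2])
  for (i in seq_len(nrow(gt))) {
    gtmask <- gtmask |
      (sqrt((xm - gt$center_x_mm[i])^2 + (ym - gt$center_y_mm[i])^2) <=
         gt$halo_radius_mm[i])
  }
  jaccard <- sum(mask & gtmask) / sum(mask | gtmask)
  expect_gte(jaccard, 0.98)
})

test_that("seed segmentation hits every seed and fills highlight holes", {
  pl <- generate_plate(plate_spec(n_seeds = 8, rng_seed = 13))
  mask <- segment_seeds(pl$image)
  gt <- pl$ground_truth
  ppmm <- pl$calibration$pixels_per_mm
  for (i in seq_len(nrow(gt))) {
    r <- round(gt$center_y_mm[i] * ppmm); c <- round(gt$center_x_mm[i] * ppmm)
    expect_true(mask[r, c])
  }
  expect_false(any(segment_seeds(flat_image(10, 10, c(190, 215, 235)))))
  # seed with a bright specular hole: hole is filled
  px <- array(rep(c(190, 215, 235), each = 40 * 40), dim = c(40, 40, 3))
  d2 <- sqrt(outer((1:40 - 20.5)^2, (1:40 - 20.5)^2, "+"))
  body <- d2 <= 10
  hole <- d2 <= 2
  for (j in 1:3) {
    ch <- px[, , j]
    ch[body] <- c(60, 40, 30)[j]
    ch[hole] <- c(240, 240, 240)[j]
    px[, , j] <- ch
  }
  m <- segment_seeds(rgb_image(px))
  expect_true(all(m[body]))
})

test_that("target mismatches are rejected", {
  img <- flat_image(5, 5, c(10, 10, 10))
  expect_error(segment_mucilage(img, default_seg_params("seed")),
               class = "seedhalo_parameter_error")
  expect_error(segment_seeds(img, default_seg_params("mucilage")),
               class = "seedhalo_parameter_error")
})
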