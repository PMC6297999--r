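test_that("region area is pixel counting in calibrated units", {
  sq <- cbind(rep(1:20, 20), rep(1:20, each = 20))
  expect_equal(region_area(sq, calibration(2)), 100)
  d <- mask_pixels(disk_mask(50))
  expect_lt(abs(region_area(d, cal1) - pi * 50^2) / (pi * 50^2), 0.01)
  expect_error(region_area(matrix(numeric(), 0, 2), cal1),
               class = "seedhalo_empty_region")
})

test_that("perimeter follows the corner-corrected chain-code estimator", {
  # 10x10 square: closed boundary of 36 axial steps and 4 corners
  sq <- cbind(rep(1:10, 10), rep(1:10, each = 10))
  expect_equal(region_perimeter(sq, cal1), 0.980 * 36 - 0.091 * 4)
  # single pixel: degenerate boundary
  expect_equal(region_perimeter(cbind(5, 5), cal1), 0)
  # disks: within 3% of the true circumference
  for (r in c(20, 50, 100)) {
    p <- region_perimeter(mask_pixels(disk_mask(r)), cal1)
    expect_lt(abs(p - 2 * pi * r) / (2 * pi * r), 0.03)
  }
  # 1-px line: out-and-back trace, 12 axial steps, 2 reversals at the ends
  line <- cbind(rep(3, 7), 2:8)
  expect_equal(region_perimeter(line, cal1), 0.980 * 12 - 0.091 * 2)
})

test_that("circularity is the normalised isoperimetric quotient, clipped at 1", {
  expect_equal(circularity(1, 4), pi / 4)
  expect_lt(circularity(80, 84), 0.3)       # elongated 2x40 rectangle
  expect_equal(circularity(100, 10), 1)     # raw value > 1 clips
  expect_error(circularity(10, 0), class = "seedhalo_undefined_metric")
  # digitised disks measure as round
  for (r in c(50, 100)) {
    px <- mask_pixels(disk_mask(r))
    circ <- circularity(region_area(px, cal1), region_perimeter(px, cal1))
    expect_gte(circ, 0.98)
    expect_lte(abs(circ - 1), 0.02)
  }
})

test_that("Feret diameters match pixel-centre geometry", {
  run <- cbind(rep(4, 11), 10:20)
  f <- feret(run, cal1)
  expect_equal(f$feret_mm, 10)
  expect_equal(f$feret_angle_deg, 0)
  tri <- cbind(c(0, 0, 4) + 1, c(0, 3, 0) + 1)
  expect_equal(feret(tri, cal1)$feret_mm, 5)
  expect_equal(feret(cbind(7, 7), cal1)$feret_mm, 0)
  # min Feret of an axis-aligned 3-wide strip is its width (2 between centres)
  strip <- cbind(rep(1:3, 10), rep(1:10, each = 3))
  expect_equal(feret(strip, cal1)$min_feret_mm, 2)
})

test_that("hull-based Feret equals the exhaustive pairwise oracle", {
  set.seed(99)
  for (i in 1:100) {
    px <- random_blob(500)
    expect_equal(feret(px, cal1)$feret_mm, feret_bruteforce(px),
                 tolerance = 1e-12)
  }
})

test_that("solidity uses the pixel-corner hull and is exact for convex shapes", {
  sq <- cbind(rep(1:10, 10), rep(1:10, each = 10))
  s <- solidity(sq, cal1)
  expect_equal(s$solidity, 1)
  expect_equal(s$convex_area_mm2, 100)
  # plus sign: five unit pixels, octagonal corner hull of area 7
  plus <- rbind(c(1, 2), c(2, 1), c(2, 2), c(2, 3), c(3, 2))
  sp <- solidity(plus, cal1)
  expect_equal(sp$convex_area_mm2, 7)
  expect_equal(sp$solidity, 5 / 7)
  # collinear component: degenerate hull, defined as solid
  expect_equal(solidity(cbind(rep(2, 6), 1:6), cal1)$solidity, 1)
  # any region: solidity <= 1, convex area >= area
  set.seed(4)
  for (i in 1:25) {
    px <- random_blob(400)
    s <- solidity(px, cal1)
    expect_lte(s$solidity, 1)
    expect_gte(s$convex_area_mm2, region_area(px, cal1))
  }
})

test_that("digitised disks satisfy the descriptor accuracy envelope", {
  for (r in c(20, 50, 100)) {
    px <- mask_pixels(disk_mask(r))
    a <- region_area(px, cal1)
    p <- region_perimeter(px, cal1)
    expect_lt(abs(a - pi * r^2) / (pi * r^2), 0.02)
    expect_lt(abs(p - 2 * pi * r) / (2 * pi * r), 0.03)
    expect_gte(circularity(a, p), 0.98)
    f <- feret(px, cal1)
    expect_lte(abs(f$feret_mm - 2 * r), 2)
  }
  # corner-hull solidity of a digital disk approaches 1 from below as the
  # boundary-to-area ratio shrinks; the bound is ~1 - 0.5 * P / A
  expect_gte(solidity(mask_pixels(disk_mask(20)), cal1)$solidity, 0.95)
  for (r in c(50, 100)) {
    expect_gte(solidity(mask_pixels(disk_mask(r)), cal1)$solidity, 0.98)
  }
})

test_that("descriptors are invariant under rotation by 90 degrees and mirroring", {
  set.seed(31)
  px <- random_blob(300)
  m <- matrix(FALSE, 50, 50)
  m[px] <- TRUE
  variants <- list(
    m,
    t(m)[, rev(seq_len(nrow(m)))],       # 90 deg rotation
    m[, rev(seq_len(ncol(m)))]           # mirror
  )
  vals <- lapply(variants, function(mm) {
    px <- mask_pixels(mm)
    c(area = region_area(px, cal1),
      perim = region_perimeter(px, cal1),
      feret = feret(px, cal1)$feret_mm,
      minf = feret(px, cal1)$min_feret_mm,
      sol = solidity(px, cal1)$solidity)
  })
  expect_equal(vals[[2]], vals[[1]])
  expect_equal(vals[[3]], vals[[1]])
})

test_that("metrics scale exactly with calibration", {
  px <- mask_pixels(disk_mask(15))
  m1 <- feret(px, calibration(2))
  m2 <- feret(px, calibration(4))
  expect_equal(m2$feret_mm, m1$feret_mm / 2)
  expect_equal(region_area(px, calibration(4)),
               region_area(px, calibration(2)) / 4)
  expect_equal(region_perimeter(px, calibration(4)),
               region_perimeter(px, calibration(2)) / 2)
})

test_that("measure_regions returns one full record per label in order", {
  m <- matrix(FALSE, 220, 80)
  centers <- c(30, 70, 110, 150, 190)
  for (i in seq_along(centers)) {
    d2 <- outer((1:220 - centers[i])^2, (1:80 - 40)^2, "+")
    m <- m | d2 <= 15^2
  }
  lr <- label_components(m)
  met <- measure_regions(lr, calibration(4))
  expect_equal(nrow(met), 5L)
  expect_equal(met$label, 1:5)
  expect_true(all(abs(met$aspect_ratio - 1) < 0.05))   # disks are round
  expect_true(all(met$circularity > 0.97))
  expect_true(all(met$solidity > 0.9 & met$solidity <= 1))
  expect_true(all(met$feret_mm >= met$min_feret_mm))
  expect_true(all(met$convex_area_mm2 >= met$area_mm2))
  # centroids sit at the construction centres (within half a pixel)
  expect_equal(met$centroid_y_mm, (centers - 0.0) / 4, tolerance = 0.2)
  # empty labeling -> empty table with the full column set
  empty <- measure_regions(label_components(matrix(FALSE, 5, 5)), cal1)
  expect_equal(nrow(empty), 0L)
  expect_equal(ncol(empty), 12L)
})

test_that("metrics agree with an independent region-features implementation", {
  # cross-check areas and centroids against EBImage::computeFeatures
  m <- matrix(FALSE, 120, 120)
  d2a <- outer((1:120 - 40)^2, (1:120 - 40)^2, "+")
  d2b <- outer((1:120 - 85)^2, (1:120 - 80)^2, "+")
  m <- d2a <= 15^2 | d2b <= 20^2
  lr <- label_components(m)
  met <- measure_regions(lr, cal1)
  ref <- EBImage::computeFeatures.shape(lr$labels)
  expect_equal(met$area_mm2, unname(ref[, "s.area"]))
  # perimeter estimators differ; agree within 10%
  expect_true(all(abs(met$perimeter_mm - ref[, "s.perimeter"]) /
                    met$perimeter_mm < 0.10))
})
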