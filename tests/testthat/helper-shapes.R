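# Shared fixtures (built in code) and independent oracles.

# logical mask with a filled disk of radius r px (pixel-centre test)
disk_mask <- function(r, pad = 6) {
  n <- 2 * r + 2 * pad + 1
  cc <- (n + 1) / 2
  outer(1:n, 1:n, function(i, j) (i - cc)^2 + (j - cc)^2 <= r^2)
}

# (row, col) pixel matrix of the single foreground object in a mask
mask_pixels <- function(mask) {
  which(mask, arr.ind = TRUE)
}

# uniform-colour image from a palette matrix lookup
flat_image <- function(H, W, rgb) {
  rgb_image(array(rep(rgb, each = H * W), dim = c(H, W, 3)))
}

# exhaustive O(n^2) Feret oracle over all pixel-centre pairs
feret_bruteforce <- function(pixels) {
  d2 <- outer(pixels[, 1], pixels[, 1], "-")^2 +
    outer(pixels[, 2], pixels[, 2], "-")^2
  sqrt(max(d2))
}

# exhaustive intermeans fixed-point search over all 256 candidate
# thresholds: T is a fixed point iff floor((m_low + m_high)/2 + 0.5) == T
isodata_fixed_points <- function(histogram) {
  ints <- 0:255
  nz <- which(histogram > 0) - 1L
  lo <- min(nz); hi <- max(nz)
  fp <- integer()
  for (t in lo:(hi - 1L)) {
    below <- histogram[1:(t + 1)]
    above <- histogram[(t + 2):256]
    m1 <- sum(below * ints[1:(t + 1)]) / sum(below)
    m2 <- sum(above * ints[(t + 2):256]) / sum(above)
    if (floor((m1 + m2) / 2 + 0.5) == t) fp <- c(fp, t)
  }
  fp
}

# random compact blob of at most max_px pixels: union of a few random
# discs, largest 8-connected component
random_blob <- function(max_px = 500) {
  n <- 40
  m <- matrix(FALSE, n, n)
  for (i in 1:4) {
    cx <- runif(1, 8, n - 8); cy <- runif(1, 8, n - 8); r <- runif(1, 2, 6)
    m <- m | outer(1:n, 1:n, function(a, b) (a - cy)^2 + (b - cx)^2 <= r^2)
  }
  lr <- label_components(m)
  if (lr$count == 0) return(random_blob(max_px))
  sizes <- tabulate(lr$labels[lr$labels > 0], nbins = lr$count)
  big <- which.max(sizes)
  px <- which(lr$labels == big, arr.ind = TRUE)
  if (nrow(px) > max_px) px <- px[seq_len(max_px), , drop = FALSE]
  px
}

# random 256-bin histogram with a guaranteed bimodal-ish structure plus
# background noise, always >= 2 nonzero bins
random_histogram <- function() {
  h <- numeric(256)
  k <- sample(2:6, 1)
  centers <- sample(0:255, k)
  for (c in centers) {
    w <- sample(5:500, 1)
    spread <- sample(0:6, 1)
    bins <- pmax(0, pmin(255, c + (-spread):spread)) + 1
    h[bins] <- h[bins] + w
  }
  h[sample(256, 10)] <- h[sample(256, 10)] + sample(0:3, 10, replace = TRUE)
  if (sum(h > 0) < 2) h[c(10, 200) + 1] <- c(5, 5)
  h
}

cal1 <- calibration(1)
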