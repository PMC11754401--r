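# Shared fixture builders for the test suite.

# constant-colour tile
flat_tile <- function(rgb, n = 8, gsd = 0.01, label = NA_character_) {
  px <- array(0, c(n, n, 3))
  for (ch in 1:3) px[, , ch] <- rgb[ch]
  image_tile(px, gsd = gsd, label = label)
}

# uniform-random integer tile
random_tile <- function(n = 16, gsd = 0.01, seed = 1) {
  withr::with_seed(seed,
                   image_tile(array(sample(0:255, n * n * 3, TRUE), c(n, n, 3)),
                              gsd = gsd))
}

# small balanced labelled synthetic sample from the default class specs
sample_tiles <- function(n_per_class, tile_pixels = 48, seed = 11) {
  generate_dataset(dataset_spec(n_per_class, tile_pixels = tile_pixels,
                                gsd = 0.004, seed = seed))
}

# 1x1 identity convolution backbone: maps each channel to itself, so the
# channel-mean activation map of a gray tile equals the tile itself.
identity_backbone <- function() {
  W <- array(0, c(1, 1, 3, 3))
  for (ch in 1:3) W[1, 1, ch, ch] <- 1
  backbone_spec("identity-fixture",
                list(list(type = "conv", label = "L01", W = W, b = rep(0, 3))))
}

# two-layer fixture: L01 a row-gradient (stripe-sensitive) filter on
# luminance, L02 a data-independent noise map.
stripe_noise_backbone <- function() {
  lum <- c(0.299, 0.587, 0.114)
  k <- t(matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3))  # row gradient
  W <- array(0, c(3, 3, 3, 1))
  for (ch in 1:3) W[, , ch, 1] <- k * lum[ch]
  backbone_spec("stripe-noise-fixture", list(
    list(type = "conv", label = "L01", W = W, b = 0),
    list(type = "noise", label = "L02", sigma = 1, seed = 99)
  ))
}

# Minimal uncompressed RGB GeoTIFF writer (classic little-endian TIFF with
# the ModelPixelScaleTag), used only to exercise GSD metadata reading.
write_minimal_geotiff <- function(path, pixels, pixel_scale) {
  h <- dim(pixels)[1]; w <- dim(pixels)[2]
  data_off <- 8L
  n_bytes <- h * w * 3L
  bps_off <- data_off + n_bytes            # BitsPerSample triple
  scale_off <- bps_off + 6L                # 3 doubles
  ifd_off <- scale_off + 24L
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x49), as.raw(0x49)), con)            # little-endian
  writeBin(42L, con, size = 2, endian = "little")
  writeBin(ifd_off, con, size = 4, endian = "little")
  # interleaved RGB rows
  inter <- aperm(pixels, c(3, 2, 1))                       # channel, col, row
  writeBin(as.raw(as.integer(inter)), con)
  writeBin(rep(8L, 3), con, size = 2, endian = "little")   # BitsPerSample
  writeBin(c(pixel_scale[1], pixel_scale[2], 0), con, size = 8, endian = "little")
  entry <- function(tag, type, count, value) {
    writeBin(as.integer(tag), con, size = 2, endian = "little")
    writeBin(as.integer(type), con, size = 2, endian = "little")
    writeBin(as.integer(count), con, size = 4, endian = "little")
    writeBin(as.integer(value), con, size = 4, endian = "little")
  }
  tags <- list(
    c(256, 3, 1, w), c(257, 3, 1, h), c(258, 3, 3, bps_off),
    c(259, 3, 1, 1), c(262, 3, 1, 2), c(273, 4, 1, data_off),
    c(277, 3, 1, 3), c(278, 3, 1, h), c(279, 4, 1, n_bytes),
    c(33550, 12, 3, scale_off))
  writeBin(length(tags), con, size = 2, endian = "little")
  for (tg in tags) entry(tg[1], tg[2], tg[3], tg[4])
  writeBin(0L, con, size = 4, endian = "little")           # no next IFD
  invisible(path)
}

# quick feature table for classifier tests: `sep` a separable column
toy_table <- function(n_per_class = 10, classes = c("I", "II"), seed = 3) {
  withr::with_seed(seed, {
    lab <- rep(classes, each = n_per_class)
    feature_table(
      data.frame(sep = match(lab, AP_CLASSES) + rnorm(length(lab), sd = 0.01),
                 noise = rnorm(length(lab))),
      label = lab)
  })
}
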