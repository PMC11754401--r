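test_that("fixture forward passes are deterministic", {
  tile <- sample_tiles(1, tile_pixels = 32, seed = 40)[[3]]
  bb <- fixture_backbone()
  a <- extract_activation_maps(tile, bb)
  b <- extract_activation_maps(tile, bb)
  expect_identical(lapply(a, `[[`, "values"), lapply(b, `[[`, "values"))
  expect_identical(pooled_features(tile, bb), pooled_features(tile, bb))
})

test_that("an identity convolution reproduces a gray tile as its map", {
  g <- withr::with_seed(41, matrix(sample(0:255, 20 * 20, TRUE), 20, 20))
  px <- array(0, c(20, 20, 3)); for (ch in 1:3) px[, , ch] <- g
  tile <- image_tile(px, gsd = 0.01)
  maps <- extract_activation_maps(tile, identity_backbone())
  expect_equal(maps$L01$values, g)
})

test_that("an all-zero tile maps to all-zero activations under zero bias", {
  tile <- flat_tile(c(0, 0, 0), n = 12)
  maps <- extract_activation_maps(tile, fixture_backbone())
  for (m in maps) expect_true(all(m$values == 0))
  expect_true(all(pooled_features(tile, fixture_backbone()) == 0))
})

test_that("unknown layer labels and missing pretrained weights error helpfully", {
  tile <- flat_tile(c(1, 2, 3))
  expect_error(extract_activation_maps(tile, fixture_backbone(), "L99"),
               "L01", class = "ap_lookup_error")
  expect_error(extract_activation_maps(tile, resnet50_backbone()),
               "fixture", class = "ap_capability_error")
  expect_error(pooled_features(tile, resnet50_backbone()),
               class = "ap_capability_error")
  expect_identical(resnet50_backbone()$layer_labels, sprintf("L%02d", 1:49))
})

test_that("activation contrast: constant maps are 0, affine rescaling is invisible", {
  expect_equal(activation_contrast(matrix(3.7, 8, 8)), 0)
  withr::with_seed(42, {
    m <- matrix(rnorm(400), 20, 20)
    a <- activation_contrast(m)
    expect_equal(activation_contrast(2.5 * m + 11), a)
    expect_gt(a, 0)
  })
})

test_that("via the identity fixture, LxxCON reduces to the tile's CON", {
  # gray image spanning the full 0..255 range, avoiding quantization-bin
  # edges (multiples of 8) where float luminance could straddle a boundary
  pool <- setdiff(1:254, seq(8, 248, by = 8))
  g <- withr::with_seed(43, matrix(sample(pool, 400, TRUE), 20, 20))
  g[1] <- 0; g[2] <- 255
  px <- array(0, c(20, 20, 3)); for (ch in 1:3) px[, , ch] <- g
  tile <- image_tile(px, gsd = 0.01)
  cfg <- glcm_config()
  map <- extract_activation_maps(tile, identity_backbone())$L01
  expect_equal(activation_contrast(map, cfg),
               unname(texture_features(tile, cfg)))
})

test_that("pooled features have the final stage's channel count and collapse means", {
  tile <- sample_tiles(1, tile_pixels = 32, seed = 44)[[5]]
  v <- pooled_features(tile, fixture_backbone())
  expect_length(v, 16)
  expect_named(v, sprintf("RN%04d", 1:16))
  # constant-weight 1x1 fixture: pooled value depends only on channel means
  W <- array(1, c(1, 1, 3, 2)); bbc <- backbone_spec(
    "const", list(list(type = "conv", label = "L01", W = W, b = c(0, 0))))
  t1 <- flat_tile(c(10, 20, 30), n = 9)
  t2 <- flat_tile(c(30, 20, 10), n = 9)   # same channel-mean sum
  expect_equal(pooled_features(t1, bbc), pooled_features(t2, bbc))
})

test_that("a stripe-sensitive layer outranks a noise layer on striped classes", {
  specs <- default_class_specs()
  striped <- class_spec("III", base_rgb = c(120, 104, 82), rgb_jitter = 5,
                        noise_sigma = 4, stripe_period = 10,
                        stripe_amplitude = 30)
  plain <- class_spec("IV", base_rgb = c(120, 104, 82), rgb_jitter = 5,
                      noise_sigma = 4, correlation_length = 2)
  tiles <- c(lapply(1:30, function(k) generate_tile(striped, 40, 0.004, k)),
             lapply(1:30, function(k) generate_tile(plain, 40, 0.004, 1000 + k)))
  rk <- rank_layers(tiles, stripe_noise_backbone())
  expect_identical(rk$layer[1], "L01")
  expect_gt(rk$score[1], 0.5)
  expect_true(all(diff(rk$score) <= 0))
  expect_true(all(rk$score >= 0 & rk$score <= 1))
})

test_that("layer ranking validates its inputs and handles a single layer", {
  tiles <- sample_tiles(2, tile_pixels = 24, seed = 45)
  expect_error(rank_layers(tiles[c(1, 3)], identity_backbone()), "2 tiles")
  one <- rank_layers(tiles, identity_backbone())
  expect_equal(nrow(one), 1L)
  expect_true(is.finite(one$score))
})

test_that("eta squared is 1 for zero within-class variance and 0 for constants", {
  tiles <- list(flat_tile(c(10, 10, 10), label = "I"),
                flat_tile(c(10, 10, 10), label = "I"))
  s <- c(1, 1, 2, 2)
  lab <- factor(c("I", "I", "II", "II"))
  expect_equal(agroprogress:::eta_squared(s, lab), 1)
  expect_equal(agroprogress:::eta_squared(rep(3, 4), lab), 0)
})
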