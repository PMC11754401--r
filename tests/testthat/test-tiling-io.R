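test_that("exact-threshold tiles are retained and small edge strips dropped", {
  full <- withr::with_seed(1, image_tile(array(sample(0:255, 300 * 300 * 3, TRUE),
                                               c(300, 300, 3)), gsd = 0.01))
  tiles <- tile_orthomosaic(full, tiling_config())
  expect_length(tiles, 25)                       # 3.0 m x 3.0 m, all 0.36 m2
  expect_true(all(vapply(tiles, tile_area_m2, 0) >= 0.36 - 1e-9))
  expect_true(all(vapply(tiles, function(t) all(dim(t$pixels)[1:2] == 60), TRUE)))

  wide <- withr::with_seed(2, image_tile(array(sample(0:255, 310 * 310 * 3, TRUE),
                                               c(310, 310, 3)), gsd = 0.01))
  expect_length(tile_orthomosaic(wide, tiling_config()), 25)  # 60x10 strips out

  tiny <- flat_tile(c(10, 20, 30), n = 50, gsd = 0.01)         # 0.25 m2
  expect_length(tile_orthomosaic(tiny, tiling_config()), 0)
})

test_that("tiling is a partition with origins in source coordinates", {
  r <- withr::with_seed(3, image_tile(array(sample(0:255, 130 * 95 * 3, TRUE),
                                            c(130, 95, 3)), gsd = 0.01))
  cfg <- tiling_config(tile_size_m = 0.40, min_area_m2 = 0.0001)
  tiles <- tile_orthomosaic(r, cfg)   # area rule effectively off: full cover
  covered <- matrix(0L, 130, 95)
  for (t in tiles) {
    h <- dim(t$pixels)[1]; w <- dim(t$pixels)[2]
    rows <- (t$origin[1] + 1):(t$origin[1] + h)
    cols <- (t$origin[2] + 1):(t$origin[2] + w)
    covered[rows, cols] <- covered[rows, cols] + 1L
    expect_identical(t$pixels, r$pixels[rows, cols, , drop = FALSE])
  }
  expect_true(all(covered == 1L))     # every pixel in exactly one tile
})

test_that("tile counts match the brute-force grid enumerator on random rasters", {
  withr::with_seed(42, {
    for (k in 1:20) {
      R <- sample(20:200, 1); C <- sample(20:200, 1)
      gsd <- sample(c(0.004, 0.01, 0.02), 1)
      cfg <- tiling_config()
      s <- floor(0.60 / gsd + 0.5)
      r <- image_tile(array(0, c(R, C, 3)), gsd = gsd)
      expect_length(tile_orthomosaic(r, cfg),
                    oracle_tile_count(R, C, s, gsd, 0.36))
    }
  })
})

test_that("degenerate tiling configurations error", {
  r <- flat_tile(c(1, 2, 3), n = 10, gsd = 10)   # tile side rounds to 0 px
  expect_error(tile_orthomosaic(r, tiling_config()), class = "ap_config_error")
  expect_error(tiling_config(tile_size_m = 0), "tile_size_m")
  expect_error(tiling_config(min_area_m2 = 0.5), "min_area_m2")
})

test_that("tiles round-trip losslessly through a labelled PNG directory", {
  tiles <- sample_tiles(2, tile_pixels = 24, seed = 5)[c(1, 2, 5, 6)]
  dir <- withr::local_tempdir()
  write_tile_dir(tiles, dir)
  expect_true(file.exists(file.path(dir, "manifest.csv")))
  back <- read_labeled_tiles(dir, gsd = 0.004)
  expect_length(back, 4)
  key <- function(ts) lapply(ts[order(vapply(ts, `[[`, "", "id"))], function(t)
    list(t$pixels, t$label))
  expect_identical(key(back), key(tiles))
})

test_that("labelled-directory reading enforces the class set and warns when empty", {
  dir <- withr::local_tempdir()
  dir.create(file.path(dir, "VII"))
  expect_error(read_labeled_tiles(dir), class = "ap_label_error")
  empty <- withr::local_tempdir()
  dir.create(file.path(empty, "I"))
  expect_warning(tiles <- read_labeled_tiles(empty, gsd = 0.01), "no tiles")
  expect_length(tiles, 0)
})

test_that("load_raster reads PNG with an explicit GSD and rejects gray input", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "t.png")
  px <- withr::with_seed(6, array(sample(0:255, 12 * 12 * 3, TRUE), c(12, 12, 3)))
  png::writePNG(px / 255, p)
  tile <- load_raster(p, gsd_override = 0.004)
  expect_equal(tile$gsd, 0.004)
  expect_identical(tile$pixels, px * 1.0)
  expect_error(load_raster(p), class = "ap_config_error")  # no GSD source
  g <- file.path(dir, "gray.png")
  png::writePNG(matrix(runif(16), 4, 4), g)
  expect_error(load_raster(g, gsd_override = 0.01), class = "ap_format_error")
})

test_that("GeoTIFF pixel-scale metadata supplies the GSD, override wins", {
  dir <- withr::local_tempdir()
  p <- file.path(dir, "geo.tif")
  px <- withr::with_seed(7, array(sample(0:255, 10 * 8 * 3, TRUE), c(10, 8, 3)))
  write_minimal_geotiff(p, px, pixel_scale = c(0.01, 0.01))
  tile <- load_raster(p)
  expect_equal(tile$gsd, 0.01)
  expect_identical(tile$pixels, px * 1.0)
  expect_equal(load_raster(p, gsd_override = 0.004)$gsd, 0.004)
})

test_that("feature tables round-trip exactly through CSV", {
  tab <- feature_table(
    data.frame(ExG = c(1.25, -3.1415926535897931, 1e-17),
               CON = c(0.1, NA, 2.5)),
    label = c("I", "III", NA), id = c("a", "b", "c"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_feature_table(tab, p)
  back <- read_feature_table(p)
  expect_identical(names(back), names(tab))
  expect_identical(back$ExG, tab$ExG)
  expect_identical(back$CON, tab$CON)
  expect_identical(as.character(back$label), as.character(tab$label))
  expect_identical(back$id, tab$id)

  bad <- withr::local_tempfile(fileext = ".csv")
  writeLines("a,b\n1,2", bad)
  expect_error(read_feature_table(bad), class = "ap_format_error")
})
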