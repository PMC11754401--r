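# Raster reading and orthomosaic tiling.
#
# Orthomosaics are cut on a regular non-overlapping grid anchored at the
# raster's top-left corner into tiles of tile_size_m a side (0.60 m by
# default); partial edge tiles whose ground area falls below min_area_m2
# (0.36 m2 by default, i.e. "smaller than" excludes strictly) are dropped.

#' Tiling parameters
#'
#' @param tile_size_m Tile side length in metres (default 0.60).
#' @param min_area_m2 Minimum ground area of an emitted tile in square
#'   metres (default 0.36); tiles of exactly this area are retained.
#' @return An object of class `ap_tiling_config`.
#' @export
tiling_config <- function(tile_size_m = 0.60, min_area_m2 = 0.36) {
  ap_assert(is_number(tile_size_m) && tile_size_m > 0, "tile_size_m must be positive")
  ap_assert(is_number(min_area_m2) && min_area_m2 > 0 &&
              min_area_m2 <= tile_size_m^2 + 1e-12,
            "min_area_m2 must lie in (0, tile_size_m^2]")
  structure(list(tile_size_m = tile_size_m, min_area_m2 = min_area_m2),
            class = "ap_tiling_config")
}

# Minimal reader for the GeoTIFF ModelPixelScaleTag (33550): scans the
# classic-TIFF IFD chain for the tag and returns the (x, y) pixel scale in
# map units, or NULL when absent. Pixel payloads are read by tiff::readTIFF;
# only this one geo tag needs raw access since no metadata-level TIFF API is
# available to the package.
geotiff_pixel_scale <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", 4L)
  if (length(hdr) < 4L) return(NULL)
  endian <- if (hdr[1] == as.raw(0x49)) "little" else if (hdr[1] == as.raw(0x4d)) "big" else return(NULL)
  magic <- readBin(hdr[3:4], "integer", 1L, size = 2L, signed = FALSE, endian = endian)
  if (magic != 42L) return(NULL)  # BigTIFF (43) not supported
  seek(con, 4L)
  ifd_off <- readBin(con, "integer", 1L, size = 4L, endian = endian)
  read_u16 <- function() readBin(con, "integer", 1L, size = 2L, signed = FALSE, endian = endian)
  read_u32 <- function() readBin(con, "integer", 1L, size = 4L, endian = endian)
  while (!is.na(ifd_off) && ifd_off > 0L) {
    seek(con, ifd_off)
    n_entries <- read_u16()
    if (length(n_entries) == 0L || is.na(n_entries)) return(NULL)
    for (k in seq_len(n_entries)) {
      seek(con, ifd_off + 2L + (k - 1L) * 12L)
      tag <- read_u16(); type <- read_u16(); count <- read_u32()
      if (tag == 33550L && type == 12L && count >= 2L) {
        off <- read_u32()
        seek(con, off)
        vals <- readBin(con, "double", count, size = 8L, endian = endian)
        return(vals[1:2])
      }
    }
    seek(con, ifd_off + 2L + n_entries * 12L)
    ifd_off <- read_u32()
  }
  NULL
}

# 0-1 float array from a decoded image; drops alpha, promotes gray to RGB.
as_rgb255 <- function(img, path) {
  if (is.matrix(img))
    ap_stop("raster ", path, " has 1 band; 3-band RGB input is required",
            class = "ap_format_error")
  nb <- dim(img)[3]
  if (nb == 4L) img <- img[, , 1:3, drop = FALSE]
  if (dim(img)[3] != 3L)
    ap_stop("raster ", path, " has ", nb, " bands; 3-band RGB input is required",
            class = "ap_format_error")
  round(img * 255)
}

#' Load a raster as a single unlabelled tile
#'
#' Reads GeoTIFF/TIFF (via the tiff package), PNG (via the png package) or
#' JPEG (via EBImage, when installed). The ground-sampling distance is taken
#' from the GeoTIFF pixel-scale metadata when present; `gsd_override` wins
#' when given, and is required for formats without geo-metadata.
#'
#' @param path Path to the raster.
#' @param gsd_override Optional metres-per-pixel value.
#' @return An [image_tile()] covering the whole raster.
#' @export
load_raster <- function(path, gsd_override = NULL) {
  ap_assert(file.exists(path), "file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  gsd <- gsd_override
  if (ext %in% c("tif", "tiff")) {
    img <- tryCatch(tiff::readTIFF(path),
                    error = function(e) ap_stop("unreadable TIFF ", path, ": ",
                                                conditionMessage(e), class = "ap_format_error"))
    if (is.null(gsd)) {
      scale <- geotiff_pixel_scale(path)
      if (!is.null(scale)) gsd <- scale[1]
    }
  } else if (ext == "png") {
    img <- tryCatch(png::readPNG(path),
                    error = function(e) ap_stop("unreadable PNG ", path, ": ",
                                                conditionMessage(e), class = "ap_format_error"))
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      ap_stop("JPEG input requires the EBImage package", class = "ap_format_error")
    img <- aperm(EBImage::imageData(EBImage::readImage(path)), c(2, 1, 3))
  } else {
    ap_stop("unsupported raster format: .", ext, class = "ap_format_error")
  }
  if (is.null(gsd))
    ap_stop("no ground-sampling distance: ", path,
            " carries no pixel-scale metadata and no gsd_override was given",
            class = "ap_config_error")
  image_tile(as_rgb255(img, path), gsd = gsd,
             id = tools::file_path_sans_ext(basename(path)))
}

#' Cut a raster into fixed-ground-size tiles
#'
#' Tiles lie on a regular non-overlapping grid anchored at pixel (0, 0) and
#' are emitted in row-major order with 0-based, half-open pixel origins.
#' The tile side in pixels is `round(tile_size_m / gsd)` (half up); edge
#' tiles whose ground area is below `min_area_m2` are excluded, tiles at
#' exactly the threshold retained.
#'
#' @param raster An [image_tile()] covering the raster.
#' @param config A [tiling_config()].
#' @return List of [image_tile()]s.
#' @export
tile_orthomosaic <- function(raster, config = tiling_config()) {
  ap_assert(inherits(raster, "ap_tile"), "raster must be an image_tile")
  ap_assert(inherits(config, "ap_tiling_config"), "config must be a tiling_config")
  s <- floor(config$tile_size_m / raster$gsd + 0.5)
  if (s < 1)
    ap_stop("tile side computes to 0 pixels at gsd ", raster$gsd,
            class = "ap_config_error")
  d <- dim(raster$pixels)
  row0 <- seq(0L, d[1] - 1L, by = s)
  col0 <- seq(0L, d[2] - 1L, by = s)
  out <- list()
  for (r0 in row0) {
    for (c0 in col0) {
      h <- min(s, d[1] - r0); w <- min(s, d[2] - c0)
      if (h * w * raster$gsd^2 < config$min_area_m2 - 1e-9) next
      out[[length(out) + 1L]] <- image_tile(
        raster$pixels[(r0 + 1L):(r0 + h), (c0 + 1L):(c0 + w), , drop = FALSE],
        gsd = raster$gsd, origin = c(r0, c0), label = raster$label,
        id = sprintf("%s_r%d_c%d", raster$id, r0, c0))
    }
  }
  out
}

#' Read a directory of labelled tiles
#'
#' Layout: one sub-directory per class (`I` .. `VI`), image files inside;
#' the folder name becomes the tile label.
#'
#' @param dir Directory path.
#' @param gsd Metres per pixel to assign to tiles without geo-metadata.
#' @return List of labelled [image_tile()]s.
#' @export
read_labeled_tiles <- function(dir, gsd = NULL) {
  ap_assert(dir.exists(dir), "directory not found: ", dir)
  classes <- list.dirs(dir, recursive = FALSE, full.names = FALSE)
  bad <- setdiff(classes, AP_CLASSES)
  if (length(bad))
    ap_stop("class folder name(s) not in I..VI: ", paste(bad, collapse = ", "),
            class = "ap_label_error")
  tiles <- list()
  for (cl in classes) {
    files <- sort(list.files(file.path(dir, cl), full.names = TRUE,
                             pattern = "\\.(png|tif|tiff|jpg|jpeg)$", ignore.case = TRUE))
    for (f in files) {
      tile <- load_raster(f, gsd_override = gsd)
      tile$label <- cl
      tiles[[length(tiles) + 1L]] <- tile
    }
  }
  if (!length(tiles)) warning("no tiles found under ", dir)
  tiles
}

#' Write tiles as a labelled PNG directory with a manifest
#'
#' Inverse of [read_labeled_tiles()]: writes `dir/<class>/<id>.png` plus a
#' `manifest.csv` listing path, class, and gsd per tile.
#'
#' @param tiles List of labelled [image_tile()]s.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_tile_dir <- function(tiles, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(tiles, function(tile) {
    ap_assert(!is.na(tile$label), "tiles must be labelled to be written to a class directory")
    sub <- file.path(dir, tile$label)
    dir.create(sub, showWarnings = FALSE)
    path <- file.path(sub, paste0(tile$id, ".png"))
    png::writePNG(tile$pixels / 255, path)
    data.frame(path = file.path(tile$label, paste0(tile$id, ".png")),
               class = tile$label, gsd = tile$gsd)
  })
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
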