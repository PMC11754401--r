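#' Construct an image tile
#'
#' The atomic unit of classification: an H x W x 3 RGB raster on the 0--255
#' integer scale together with its ground-sampling distance (GSD, metres of
#' ground per pixel), an optional field-state label and a provenance id.
#'
#' @param pixels Numeric H x W x 3 array with values in \[0, 255\].
#' @param gsd Ground-sampling distance in metres per pixel.
#' @param origin Integer (row, col) pixel offset of the tile's top-left
#'   corner in its source raster, 0-based. Defaults to c(0, 0).
#' @param label Optional class label, one of [AP_CLASSES], or NA.
#' @param id Character identifier.
#' @return An object of class `ap_tile`.
#' @export
image_tile <- function(pixels, gsd, origin = c(0L, 0L), label = NA_character_,
                       id = "tile") {
  ap_assert(is.array(pixels) && length(dim(pixels)) == 3L && dim(pixels)[3] == 3L,
            "pixels must be an H x W x 3 array")
  ap_assert(dim(pixels)[1] >= 1L && dim(pixels)[2] >= 1L,
            "tile must have at least one row and one column")
  ap_assert(all(is.finite(pixels)), "pixels must be finite (no NA/NaN)")
  ap_assert(min(pixels) >= 0 && max(pixels) <= 255,
            "pixel values must lie in [0, 255]")
  ap_assert(is_number(gsd) && gsd > 0, "gsd must be a positive number")
  if (!is.na(label))
    ap_assert(label %in% AP_CLASSES,
              "label must be one of ", paste(AP_CLASSES, collapse = ", "))
  structure(list(pixels = pixels, gsd = gsd,
                 origin = as.integer(origin), label = label,
                 id = as.character(id)),
            class = "ap_tile")
}

#' @export
print.ap_tile <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<ap_tile %s: %d x %d px, gsd %.4g m/px (%.3g m2)%s>\n",
              x$id, d[1], d[2], x$gsd, tile_area_m2(x),
              if (is.na(x$label)) "" else paste0(", class ", x$label)))
  invisible(x)
}

#' Ground area of a tile in square metres
#'
#' @param tile An [image_tile()].
#' @return H * W * gsd^2 in square metres.
#' @export
tile_area_m2 <- function(tile) {
  d <- dim(tile$pixels)
  d[1] * d[2] * tile$gsd^2
}
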