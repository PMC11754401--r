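# Colour vegetation indices.
#
# Twelve RGB indices computed from per-tile mean channel values on the
# 0-255 scale (mean-then-index; channel means are the R, G, B entering each
# formula). ExG, ExR, ExGR and INT are therefore scale-dependent; the
# ratio-form indices are invariant to a common channel rescaling.

#' Canonical names of the twelve colour vegetation indices
#'
#' Feature order used in tables, screening priority and combos.
#'
#' @format Character vector of length 12.
#' @export
AP_COLOR_FEATURES <- c("ExG", "INT", "IKAW", "VARI", "ExR", "GLI",
                       "ExGR", "NGRDI", "NGBDI", "MGRVI", "RGBVI", "RGRI")

#' Per-channel mean pixel values of a tile
#'
#' @param tile An [image_tile()].
#' @return Named numeric vector `c(R =, G =, B =)` of arithmetic channel
#'   means over all pixels.
#' @export
channel_means <- function(tile) {
  ap_assert(inherits(tile, "ap_tile"), "tile must be an image_tile")
  c(R = mean(tile$pixels[, , 1]),
    G = mean(tile$pixels[, , 2]),
    B = mean(tile$pixels[, , 3]))
}

# Guarded ratio: returns NA where the denominator is 0 rather than Inf/NaN.
safe_div <- function(num, den) ifelse(den == 0, NA_real_, num / den)

#' Twelve colour vegetation indices from mean channel values
#'
#' Computes, from mean red/green/blue values on the 0--255 scale:
#' excess green `ExG = 2G - R - B`; intensity `INT = (R+G+B)/3`; Kawashima
#' index `IKAW = (R-B)/(R+B)`; `VARI = (G-R)/(G+R-B)`; excess red
#' `ExR = 1.4R - G`; green-leaf index `GLI = (2G-R-B)/(2G+R+B)`;
#' `ExGR = 3G - 2.4R - B` (identically `ExG - ExR`); `NGRDI = (G-R)/(G+R)`;
#' `NGBDI = (G-B)/(G+B)`; `MGRVI = (G^2-R^2)/(G^2+R^2)`;
#' `RGBVI = (G^2 - B R)/(G^2 + B R)`; and the red-green ratio `RGRI = R/G`.
#'
#' A zero denominator yields `NA` (a missing-value sentinel carried through
#' feature tables and imputed at model-fitting time), never an error.
#'
#' RGBVI is sometimes printed with a product in the numerator; the
#' difference form `(G^2 - B R)/(G^2 + B R)` used here is the consistent
#' normalised-difference definition from the index's original literature.
#'
#' @param R,G,B Mean channel values in \[0, 255\] (vectorised).
#' @return A data.frame with the 12 index columns, one row per input.
#' @examples
#' color_indices(100, 150, 50)
#' @export
color_indices <- function(R, G, B) {
  ap_assert(is.numeric(R) && is.numeric(G) && is.numeric(B) &&
              length(R) == length(G) && length(G) == length(B),
            "R, G, B must be numeric vectors of equal length")
  ap_assert(all(is.finite(c(R, G, B))) &&
              all(c(R, G, B) >= 0) && all(c(R, G, B) <= 255),
            "channel means must lie in [0, 255]")
  data.frame(
    ExG   = 2 * G - R - B,
    INT   = (R + G + B) / 3,
    IKAW  = safe_div(R - B, R + B),
    VARI  = safe_div(G - R, G + R - B),
    ExR   = 1.4 * R - G,
    GLI   = safe_div(2 * G - R - B, 2 * G + R + B),
    ExGR  = 3 * G - 2.4 * R - B,
    NGRDI = safe_div(G - R, G + R),
    NGBDI = safe_div(G - B, G + B),
    MGRVI = safe_div(G^2 - R^2, G^2 + R^2),
    RGBVI = safe_div(G^2 - B * R, G^2 + B * R),
    RGRI  = safe_div(R, G)
  )
}

#' Colour feature vector of a tile
#'
#' @param tile An [image_tile()].
#' @param per_pixel If `TRUE`, evaluate each index per pixel and average the
#'   per-pixel values instead of the default mean-then-index order.
#' @return One-row data.frame of the 12 colour indices.
#' @export
color_features <- function(tile, per_pixel = FALSE) {
  if (!per_pixel) {
    m <- channel_means(tile)
    return(color_indices(m[["R"]], m[["G"]], m[["B"]]))
  }
  v <- color_indices(as.vector(tile$pixels[, , 1]),
                     as.vector(tile$pixels[, , 2]),
                     as.vector(tile$pixels[, , 3]))
  as.data.frame(lapply(v, mean, na.rm = TRUE))
}
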