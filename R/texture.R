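# Gray-level co-occurrence matrix (GLCM) contrast.
#
# A tile is reduced to luminance, uniformly quantized to a small number of
# gray levels, co-occurrences of level pairs are counted at a set of pixel
# displacements, and the contrast statistic sum_ij (i-j)^2 C_ij summarises
# how deep the surface's texture grooves are: 0 for a flat surface, large
# for fine-grained or strongly striped ones.

#' GLCM parameters
#'
#' @param levels Number of gray levels after quantization (>= 2).
#' @param offsets List of `(delta_row, delta_col)` displacements; the default
#'   four unit directions (0,1), (1,0), (1,1), (1,-1) are pooled into a
#'   single co-occurrence matrix before normalization, yielding one
#'   orientation-averaged contrast per image.
#' @param symmetric Count each pair in both directions.
#' @param normalized Scale counts so entries sum to 1.
#' @return An object of class `ap_glcm_config`.
#' @export
glcm_config <- function(levels = 32L,
                        offsets = list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L)),
                        symmetric = TRUE, normalized = TRUE) {
  ap_assert(is_count(levels, 2L), "levels must be a count >= 2")
  ap_assert(is.list(offsets) && length(offsets) >= 1L, "offsets must be a non-empty list")
  for (off in offsets) {
    ap_assert(is.numeric(off) && length(off) == 2L && all(off == round(off)),
              "each offset must be an integer (delta_row, delta_col) pair")
    ap_assert(any(off != 0), "the (0,0) offset is not a displacement")
  }
  structure(list(levels = as.integer(levels),
                 offsets = lapply(offsets, as.integer),
                 symmetric = isTRUE(symmetric), normalized = isTRUE(normalized)),
            class = "ap_glcm_config")
}

#' Quantize a tile to gray levels
#'
#' Luminance is the Rec.601 weighting `0.299 R + 0.587 G + 0.114 B`;
#' quantization is uniform over \[0, 255\]: bin `floor(lum * levels / 256)`,
#' capped at `levels - 1`.
#'
#' @param tile An [image_tile()], or an H x W matrix already on \[0, 255\]
#'   (single-channel mode).
#' @param levels Number of gray levels.
#' @return An object of class `ap_gray` with fields `values` (H x W integer
#'   matrix in \[0, levels-1\]) and `levels`.
#' @export
to_gray <- function(tile, levels = 32L) {
  ap_assert(is_count(levels, 2L), "levels must be a count >= 2")
  lum <- if (inherits(tile, "ap_tile")) {
    0.299 * tile$pixels[, , 1] + 0.587 * tile$pixels[, , 2] + 0.114 * tile$pixels[, , 3]
  } else {
    ap_assert(is.matrix(tile), "tile must be an image_tile or a matrix")
    tile
  }
  gray_matrix(pmin(floor(lum * levels / 256), levels - 1L), levels)
}

#' Construct a quantized gray image
#'
#' @param values H x W matrix of integer levels in \[0, levels-1\].
#' @param levels Level count (>= 2).
#' @return An object of class `ap_gray`.
#' @export
gray_matrix <- function(values, levels) {
  ap_assert(is.matrix(values) && all(is.finite(values)), "values must be a finite matrix")
  ap_assert(is_count(levels, 2L), "levels must be a count >= 2")
  ap_assert(all(values >= 0) && all(values < levels) && all(values == round(values)),
            "all values must be integers in [0, levels-1]")
  structure(list(values = matrix(as.integer(values), nrow(values), ncol(values)),
                 levels = as.integer(levels)),
            class = "ap_gray")
}

#' Gray-level co-occurrence matrix
#'
#' Counts, for every displacement in `config$offsets`, how often a pixel of
#' level i has a neighbour of level j at that displacement; offsets are
#' pooled into one matrix. With `symmetric` each pair is also counted
#' reversed; with `normalized` the entries sum to 1.
#'
#' @param gray An `ap_gray` from [to_gray()] or [gray_matrix()].
#' @param config A [glcm_config()].
#' @return `levels x levels` numeric matrix.
#' @export
glcm <- function(gray, config = glcm_config()) {
  ap_assert(inherits(gray, "ap_gray"), "gray must be an ap_gray")
  ap_assert(inherits(config, "ap_glcm_config"), "config must be a glcm_config")
  L <- gray$levels
  v <- gray$values
  nr <- nrow(v); nc <- ncol(v)
  counts <- numeric(L * L)
  any_pair <- FALSE
  for (off in config$offsets) {
    dr <- off[1]; dc <- off[2]
    r1 <- max(1L, 1L - dr); r2 <- min(nr, nr - dr)
    c1 <- max(1L, 1L - dc); c2 <- min(nc, nc - dc)
    if (r1 > r2 || c1 > c2) next
    any_pair <- TRUE
    a <- v[r1:r2, c1:c2, drop = FALSE]
    b <- v[(r1 + dr):(r2 + dr), (c1 + dc):(c2 + dc), drop = FALSE]
    counts <- counts + tabulate(as.vector(a) * L + as.vector(b) + 1L, nbins = L * L)
  }
  if (!any_pair)
    ap_stop("image contains no pixel pair for any configured offset",
            class = "ap_degenerate_error")
  C <- matrix(counts, L, L, byrow = TRUE)  # row index = first pixel's level i
  if (config$symmetric) C <- C + t(C)
  if (config$normalized) C <- C / sum(C)
  C
}

#' GLCM contrast (feature CON)
#'
#' `sum_i sum_j (i - j)^2 C_ij` with i, j the 0-based level indices: the
#' depth of the texture grooves of the surface.
#'
#' @param C Square non-negative co-occurrence matrix.
#' @return Non-negative scalar; 0 iff all co-occurring pairs share a level.
#' @export
glcm_contrast <- function(C) {
  ap_assert(is.matrix(C) && nrow(C) == ncol(C),
            "co-occurrence matrix must be square")
  ap_assert(all(is.finite(C)) && all(C >= 0),
            "co-occurrence matrix must be non-negative")
  idx <- seq_len(nrow(C)) - 1L
  sum(outer(idx, idx, function(i, j) (i - j)^2) * C)
}

#' Texture feature (CON) of a tile
#'
#' Convenience wrapper: quantize, build the GLCM, return contrast.
#'
#' @param tile An [image_tile()].
#' @param config A [glcm_config()].
#' @param channel `"luminance"` (default) or 1, 2, 3 to quantize a single
#'   channel instead.
#' @return Scalar contrast, named `CON`.
#' @export
texture_features <- function(tile, config = glcm_config(), channel = "luminance") {
  g <- if (identical(channel, "luminance")) {
    to_gray(tile, config$levels)
  } else {
    ap_assert(channel %in% 1:3, "channel must be 'luminance' or 1, 2, 3")
    to_gray(tile$pixels[, , channel], config$levels)
  }
  c(CON = glcm_contrast(glcm(g, config)))
}
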