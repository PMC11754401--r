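# Synthetic six-class field-tile generator.
#
# Real rice-wheat rotation tile sets are rarely shareable, so the package
# ships a generator whose six default classes encode the qualitative feature
# structure observed over a rotation season: immature rice is far greener
# than everything else; harvested stubble carries a strong row-stripe
# texture; ploughed land is the smoothest surface; rotary-tilled and sown
# fields share the same colour distribution and differ only in surface
# texture. Every downstream stage of the pipeline is testable against it.

#' Specification of one synthetic field class
#'
#' Describes the colour and texture of a synthetic surface. Colour is a mean
#' RGB triple plus a per-tile Gaussian jitter of that mean; texture is a
#' zero-mean correlated-noise field (white noise box-smoothed over
#' `correlation_length` pixels, rescaled to standard deviation `noise_sigma`)
#' plus an optional additive sinusoidal stripe pattern, both applied equally
#' to the three channels so that texture lives in luminance.
#'
#' @param class_id One of [AP_CLASSES].
#' @param base_rgb Mean channel values, each in \[0, 255\].
#' @param rgb_jitter Per-channel standard deviation of the tile-level colour
#'   shift (a whole tile is brighter/greener, as lighting and moisture vary
#'   between plots).
#' @param noise_sigma Pixel-level texture amplitude (standard deviation of
#'   the correlated-noise field, digital numbers).
#' @param correlation_length Spatial smoothing scale of the noise field in
#'   pixels; larger values give blobbier, lower-contrast surfaces.
#' @param stripe_period Row-pattern period in pixels; 0 disables stripes.
#' @param stripe_amplitude Additive stripe strength (digital numbers).
#' @param stripe_orientation Stripe orientation in degrees (0 = horizontal
#'   bands varying along rows).
#' @return An object of class `ap_class_spec`.
#' @seealso [default_class_specs()], [generate_tile()]
#' @export
class_spec <- function(class_id, base_rgb, rgb_jitter = 0, noise_sigma = 0,
                       correlation_length = 1, stripe_period = 0,
                       stripe_amplitude = 0, stripe_orientation = 0) {
  ap_assert(length(class_id) == 1L && class_id %in% AP_CLASSES,
            "class_id must be one of ", paste(AP_CLASSES, collapse = ", "))
  ap_assert(is.numeric(base_rgb) && length(base_rgb) == 3L &&
              all(is.finite(base_rgb)) && all(base_rgb >= 0 & base_rgb <= 255),
            "base_rgb components must lie in [0, 255]")
  for (nm in c("rgb_jitter", "noise_sigma", "stripe_amplitude")) {
    v <- get(nm)
    ap_assert(is_number(v, min = 0), nm, " must be a non-negative number")
  }
  ap_assert(is_number(correlation_length, min = 0),
            "correlation_length must be a non-negative number")
  ap_assert(is_number(stripe_period, min = 0),
            "stripe_period must be a non-negative number")
  ap_assert(is_number(stripe_orientation), "stripe_orientation must be a number")
  structure(list(class_id = class_id, base_rgb = as.numeric(base_rgb),
                 rgb_jitter = rgb_jitter, noise_sigma = noise_sigma,
                 correlation_length = correlation_length,
                 stripe_period = stripe_period,
                 stripe_amplitude = stripe_amplitude,
                 stripe_orientation = stripe_orientation),
            class = "ap_class_spec")
}

#' Default specifications of the six synthetic field classes
#'
#' The defaults encode the qualitative structure of the six field states:
#' \describe{
#'   \item{I (immature rice)}{vivid green; its green-minus-red and
#'     green-minus-blue margins strictly exceed every other class, so
#'     excess-green style indices single it out.}
#'   \item{II (harvestable rice)}{golden-yellow canopy, moderate texture.}
#'   \item{III (harvested rice)}{brown stubble with a strong periodic
#'     row-stripe texture (the combine's cutting rows).}
#'   \item{IV (ploughed land)}{dark soil, long-correlation smooth surface:
#'     the lowest co-occurrence contrast of the six.}
#'   \item{V (rotary-tilled land)}{fine seedbed: high-amplitude,
#'     short-correlation grain, the highest contrast.}
#'   \item{VI (sown wheat)}{identical colour and colour jitter to class V
#'     (colour-indistinguishable) but a smooth surface crossed by seeder
#'     rows: texture alone separates V from VI.}
#' }
#'
#' @return Named list of six [class_spec()] objects, names `I` to `VI`.
#' @export
default_class_specs <- function() {
  specs <- list(
    class_spec("I",   base_rgb = c(62, 142, 58),  rgb_jitter = 8,
               noise_sigma = 10, correlation_length = 2),
    class_spec("II",  base_rgb = c(158, 138, 72), rgb_jitter = 8,
               noise_sigma = 9,  correlation_length = 2),
    class_spec("III", base_rgb = c(138, 118, 86), rgb_jitter = 8,
               noise_sigma = 12, correlation_length = 1,
               stripe_period = 12, stripe_amplitude = 35,
               stripe_orientation = 0),
    class_spec("IV",  base_rgb = c(96, 82, 66),   rgb_jitter = 7,
               noise_sigma = 6,  correlation_length = 6),
    class_spec("V",   base_rgb = c(120, 104, 82), rgb_jitter = 7,
               noise_sigma = 22, correlation_length = 1),
    class_spec("VI",  base_rgb = c(120, 104, 82), rgb_jitter = 7,
               noise_sigma = 5,  correlation_length = 3,
               stripe_period = 10, stripe_amplitude = 25,
               stripe_orientation = 90)
  )
  names(specs) <- vapply(specs, `[[`, "", "class_id")
  specs
}

#' Specification of a synthetic dataset
#'
#' @param n_per_class Tiles generated per class (>= 1).
#' @param tile_pixels Tile side length in pixels (>= 16). The default, 150 px
#'   at the default GSD, corresponds to the 0.60 m tile used throughout the
#'   package.
#' @param gsd Ground-sampling distance in metres per pixel; the default
#'   0.004 m/px is typical of a 20 MP RGB camera flown at 15 m.
#' @param seed Integer seed; per-tile streams are split from it so that
#'   changing `n_per_class` does not perturb other tiles.
#' @param class_specs List of exactly six [class_spec()]s with distinct
#'   class ids; defaults to [default_class_specs()].
#' @return An object of class `ap_dataset_spec`.
#' @export
dataset_spec <- function(n_per_class, tile_pixels = 150, gsd = 0.004,
                         seed = 1L, class_specs = default_class_specs()) {
  ap_assert(is_count(n_per_class, 1L), "n_per_class must be a count >= 1")
  ap_assert(is_count(tile_pixels, 16L), "tile_pixels must be a count >= 16")
  ap_assert(is_number(gsd) && gsd > 0, "gsd must be a positive number")
  ap_assert(is.numeric(seed) && length(seed) == 1L && is.finite(seed) &&
              seed == round(seed), "seed must be an integer")
  ap_assert(is.list(class_specs) && length(class_specs) == 6L,
            "class_specs must hold exactly six class_spec records")
  ids <- vapply(class_specs, function(s) {
    ap_assert(inherits(s, "ap_class_spec"), "class_specs entries must be class_spec objects")
    s$class_id
  }, "")
  ap_assert(!anyDuplicated(ids) && setequal(ids, AP_CLASSES),
            "class_specs must cover the six classes I-VI exactly once")
  structure(list(n_per_class = as.integer(n_per_class),
                 tile_pixels = as.integer(tile_pixels), gsd = gsd,
                 seed = seed, class_specs = class_specs[order(match(ids, AP_CLASSES))]),
            class = "ap_dataset_spec")
}

# Box-smooth a matrix with an integral image; window w cells, edge windows
# shrink (no wrap-around), so the result is deterministic and bias-free.
box_smooth <- function(m, w) {
  if (w <= 1L) return(m)
  h <- floor(w / 2)
  nr <- nrow(m); nc <- ncol(m)
  S <- matrix(0, nr + 1L, nc + 1L)
  S[-1L, -1L] <- apply(m, 2L, cumsum)
  S[-1L, -1L] <- t(apply(S[-1L, -1L, drop = FALSE], 1L, cumsum))
  r1 <- pmax(1L, seq_len(nr) - h); r2 <- pmin(nr, seq_len(nr) + h)
  c1 <- pmax(1L, seq_len(nc) - h); c2 <- pmin(nc, seq_len(nc) + h)
  # window sums via the four-corner identity on the padded integral image
  sums <- S[r2 + 1L, c2 + 1L, drop = FALSE] - S[r1, c2 + 1L, drop = FALSE] -
    S[r2 + 1L, c1, drop = FALSE] + S[r1, c1, drop = FALSE]
  counts <- outer(r2 - r1 + 1L, c2 - c1 + 1L)
  sums / counts
}

#' Generate one synthetic field tile
#'
#' Deterministic for a fixed (spec, seed) pair: a tile-level colour shift is
#' drawn, then a correlated-noise texture field and (optionally) a phased
#' sinusoidal stripe pattern are added to all three channels, and the result
#' is clipped to \[0, 255\] and rounded to integers.
#'
#' @param spec A [class_spec()].
#' @param tile_pixels Side length in pixels.
#' @param gsd Metres per pixel.
#' @param seed Integer seed for this tile.
#' @return An [image_tile()] labelled with `spec$class_id`.
#' @examples
#' spec <- class_spec("IV", base_rgb = c(120, 120, 120))
#' tile <- generate_tile(spec, tile_pixels = 32, gsd = 0.004, seed = 7)
#' unique(as.vector(tile$pixels))  # all dispersion off: exactly 120
#' @export
generate_tile <- function(spec, tile_pixels, gsd, seed) {
  ap_assert(inherits(spec, "ap_class_spec"), "spec must be a class_spec")
  ap_assert(is_count(tile_pixels, 1L), "tile_pixels must be a positive count")
  ap_assert(is_number(gsd) && gsd > 0, "gsd must be a positive number")
  n <- as.integer(tile_pixels)
  px <- ap_with_seed(seed, {
    base <- spec$base_rgb + rnorm(3L) * spec$rgb_jitter
    phase <- runif(1L, 0, 2 * pi)
    tex <- matrix(0, n, n)
    if (spec$noise_sigma > 0) {
      f <- box_smooth(matrix(rnorm(n * n), n, n),
                      max(1L, as.integer(round(spec$correlation_length))))
      s <- sd(as.vector(f))
      if (s > 0) tex <- f / s * spec$noise_sigma
    }
    if (spec$stripe_period > 0 && spec$stripe_amplitude > 0) {
      th <- spec$stripe_orientation * pi / 180
      u <- outer((seq_len(n) - 1L) * cos(th), (seq_len(n) - 1L) * sin(th), "+")
      tex <- tex + spec$stripe_amplitude * sin(2 * pi * u / spec$stripe_period + phase)
    }
    arr <- array(0, c(n, n, 3L))
    for (ch in 1:3) arr[, , ch] <- clip255(base[ch] + tex)
    round(arr)
  })
  image_tile(px, gsd = gsd, label = spec$class_id,
             id = sprintf("%s_s%d", spec$class_id, as.integer(seed %% 2147483647)))
}

#' Generate a balanced labelled synthetic dataset
#'
#' @param spec A [dataset_spec()].
#' @return List of `6 * n_per_class` labelled [image_tile()]s, classes in
#'   I..VI order, `n_per_class` tiles each; reproducible from `spec$seed`.
#' @export
generate_dataset <- function(spec) {
  ap_assert(inherits(spec, "ap_dataset_spec"), "spec must be a dataset_spec")
  tiles <- vector("list", 6L * spec$n_per_class)
  i <- 0L
  for (ci in seq_along(spec$class_specs)) {
    cs <- spec$class_specs[[ci]]
    for (k in seq_len(spec$n_per_class)) {
      i <- i + 1L
      tile <- generate_tile(cs, spec$tile_pixels, spec$gsd,
                            seed = ap_tile_seed(spec$seed, ci, k))
      tile$id <- sprintf("%s_%04d", cs$class_id, k)
      tiles[[i]] <- tile
    }
  }
  tiles
}
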