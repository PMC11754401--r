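# Internal helpers shared across modules.

ap_stop <- function(..., class = "ap_error") {
  stop(structure(class = c(class, "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

ap_assert <- function(cond, ..., class = "ap_validation_error") {
  if (!isTRUE(cond)) ap_stop(..., class = class)
}

# Run `expr` under a fixed RNG seed without disturbing the caller's stream.
ap_with_seed <- function(seed, expr) {
  withr::with_seed(as.integer(seed %% 2147483647L), expr)
}

# Derive a per-tile seed from a dataset seed so that streams are split per
# tile: changing n_per_class leaves earlier tiles' content untouched.
ap_tile_seed <- function(dataset_seed, class_index, k) {
  h <- as.numeric(dataset_seed) %% 2147483647
  (h * 31 + class_index * 7919 + k * 104729) %% 2147483647
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_number <- function(x, min = -Inf) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min
}
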