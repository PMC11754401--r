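# Activation-map texture features.
#
# Each labelled backbone layer yields one 2-D activation image per tile
# (channels aggregated by mean); the image is min-max normalized, quantized,
# and summarised by GLCM contrast ("LxxCON"). Layers are ranked for class
# separability of their contrast by the correlation ratio eta^2, and the
# final conv stage's per-channel spatial means form the pooled deep-feature
# vector.

aggregate_channels <- function(tensor, agg = "mean") {
  d <- dim(tensor)
  if (identical(agg, "mean"))
    return(matrix(rowMeans(matrix(tensor, d[1] * d[2], d[3])), d[1], d[2]))
  if (identical(agg, "max")) {
    m <- tensor[, , 1]
    for (ch in seq_len(d[3])[-1]) m <- pmax(m, tensor[, , ch])
    return(m)
  }
  if (grepl("^channel:\\d+$", agg)) {
    k <- as.integer(sub("channel:", "", agg))
    ap_assert(k >= 1L && k <= d[3], "channel index out of range (1..", d[3], ")")
    return(tensor[, , k])
  }
  ap_stop("unknown aggregation rule: ", agg, class = "ap_config_error")
}

#' Extract 2-D activation maps for a tile
#'
#' Runs the backbone forward (resizing first when the backbone declares an
#' input size) and aggregates each requested post-nonlinearity tensor over
#' channels into a single activation image.
#'
#' @param tile An [image_tile()].
#' @param backbone An `ap_backbone`.
#' @param layer_labels Subset of `backbone$layer_labels`; default all.
#' @param agg Channel aggregation: `"mean"` (default), `"max"`, or
#'   `"channel:<k>"`.
#' @return Named list of `ap_activation` objects (fields `layer_label`,
#'   `values`), in requested order.
#' @export
extract_activation_maps <- function(tile, backbone,
                                    layer_labels = backbone$layer_labels,
                                    agg = "mean") {
  unknown <- setdiff(layer_labels, backbone$layer_labels)
  if (length(unknown))
    ap_stop("unknown layer label(s): ", paste(unknown, collapse = ", "),
            "; valid labels: ", paste(backbone$layer_labels, collapse = ", "),
            class = "ap_lookup_error")
  acts <- backbone_forward(tile, backbone)
  out <- lapply(layer_labels, function(lab) {
    structure(list(layer_label = lab,
                   values = aggregate_channels(acts[[lab]], agg)),
              class = "ap_activation")
  })
  names(out) <- layer_labels
  out
}

#' GLCM contrast of an activation map (feature LxxCON)
#'
#' The map is min-max normalized to \[0, 1\] (a constant map is defined to
#' have contrast 0), uniformly quantized to `config$levels` gray levels,
#' and summarised by [glcm_contrast()]. Because of the normalization the
#' statistic is invariant under any positive affine rescaling of the map.
#'
#' @param map An `ap_activation` (or bare numeric matrix).
#' @param config A [glcm_config()].
#' @return Non-negative scalar contrast.
#' @export
activation_contrast <- function(map, config = glcm_config()) {
  v <- if (inherits(map, "ap_activation")) map$values else map
  ap_assert(is.matrix(v) && all(is.finite(v)), "activation map must be a finite matrix")
  rng <- max(v) - min(v)
  if (rng == 0) return(0)
  u <- (v - min(v)) / rng
  q <- pmin(floor(u * config$levels), config$levels - 1L)
  glcm_contrast(glcm(gray_matrix(q, config$levels), config))
}

#' Pooled deep-feature vector of a tile
#'
#' Spatial mean of every channel of the final labelled conv stage (2048
#' values for the pretrained residual backbone; the final channel count of
#' a fixture backbone).
#'
#' @param tile An [image_tile()].
#' @param backbone An `ap_backbone`.
#' @return Named numeric vector `RN0001`..`RN<k>`.
#' @export
pooled_features <- function(tile, backbone) {
  acts <- backbone_forward(tile, backbone)
  if (!length(acts))
    ap_stop("backbone has no labelled feature stage", class = "ap_capability_error")
  final <- acts[[length(acts)]]
  v <- colMeans(matrix(final, prod(dim(final)[1:2]), dim(final)[3]))
  names(v) <- sprintf("RN%04d", seq_along(v))
  v
}

# correlation ratio: between-class share of the total sum of squares;
# defined as 0 for a constant score vector.
eta_squared <- function(score, label) {
  ss_tot <- sum((score - mean(score))^2)
  if (ss_tot == 0) return(0)
  ss_b <- sum(tapply(score, label, function(v) length(v) * (mean(v) - mean(score))^2))
  ss_b / ss_tot
}

#' Rank activation layers by class separability of their contrast
#'
#' For every labelled layer, computes LxxCON per tile and scores the layer
#' by the correlation ratio eta^2 of those contrasts across the class
#' labels (between-class sum of squares over total). Layers are returned
#' sorted by score, ties broken by forward layer order.
#'
#' @param tiles List of labelled [image_tile()]s (>= 2 classes, >= 2 tiles
#'   per class).
#' @param backbone An `ap_backbone`.
#' @param config A [glcm_config()].
#' @param agg Channel aggregation rule (see [extract_activation_maps()]).
#' @param statistic `"eta_sq"` (default) or `"kruskal_eps_sq"` for the
#'   rank-based Kruskal-Wallis epsilon^2 analogue.
#' @return An `ap_layer_ranking`: data.frame with `layer`, `score`, sorted
#'   descending; attribute `contrasts` holds the tile-by-layer score matrix.
#' @export
rank_layers <- function(tiles, backbone, config = glcm_config(),
                        agg = "mean", statistic = "eta_sq") {
  labels <- vapply(tiles, `[[`, "", "label")
  ap_assert(!anyNA(labels), "all tiles must be labelled")
  counts <- table(labels)
  ap_assert(length(counts) >= 2L, "need at least 2 classes")
  if (any(counts < 2L))
    ap_stop("class(es) with fewer than 2 tiles: ",
            paste(names(counts)[counts < 2L], collapse = ", "))
  lab <- factor(labels)
  layer_labels <- backbone$layer_labels
  con <- matrix(NA_real_, length(tiles), length(layer_labels),
                dimnames = list(NULL, layer_labels))
  for (i in seq_along(tiles)) {
    maps <- extract_activation_maps(tiles[[i]], backbone, layer_labels, agg)
    con[i, ] <- vapply(maps, activation_contrast, 0, config = config)
  }
  score <- vapply(layer_labels, function(l) {
    s <- con[, l]
    if (identical(statistic, "kruskal_eps_sq")) eta_squared(rank(s), lab)
    else eta_squared(s, lab)
  }, 0)
  ord <- order(-score, match(layer_labels, backbone$layer_labels))
  out <- data.frame(layer = layer_labels[ord], score = score[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "contrasts") <- con
  class(out) <- c("ap_layer_ranking", "data.frame")
  out
}
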