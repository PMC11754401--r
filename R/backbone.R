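# Pluggable CNN backbones.
#
# A backbone is an ordered stack of layers applied to a raw 0-255 RGB
# tensor. Conv layers (zero-padded "same" convolution + bias + rectifier)
# carry the activation-layer labels L01..Lnn in forward order; mean-pool
# layers halve the resolution between stages; a "noise" layer type (a
# data-independent pseudo-random map, useful as a null layer in separability
# studies) is also available. The shipped `fixture-cnn` is fully
# deterministic: its first stage is a hand-crafted filter bank (luminance
# blur, horizontal/vertical gradient, Laplacian, green-red opponency) and
# the deeper stages use weights frozen from a fixed seed constant. A
# `resnet50-pretrained` spec is provided for users with an external weights
# source; without weights its forward pass raises a capability error.

FIXTURE_SEED <- 830103L

#' Construct a backbone specification
#'
#' @param name Backbone identifier.
#' @param layers List of layer records: `list(type = "conv", label, W, b)`
#'   with `W` a (kh, kw, in, out) weight array and `b` a length-out bias;
#'   `list(type = "pool")` (2x2 mean-pool, stride 2); or
#'   `list(type = "noise", label, sigma)`.
#' @param input_size Optional (H, W) the tile is bilinearly resized to
#'   before the forward pass; NULL = native tile size.
#' @return Object of class `ap_backbone`, with `layer_labels` the ordered
#'   activation-layer labels.
#' @export
backbone_spec <- function(name, layers, input_size = NULL) {
  labels <- unlist(lapply(layers, function(l) l$label %||% character(0)))
  ap_assert(!anyDuplicated(labels), "layer labels must be unique")
  for (l in layers) {
    ap_assert(l$type %in% c("conv", "pool", "noise"),
              "unknown layer type: ", l$type)
    if (l$type == "conv") {
      ap_assert(is.array(l$W) && length(dim(l$W)) == 4L, "conv weights must be 4-D")
      ap_assert(length(l$b) == dim(l$W)[4], "bias length must equal output channels")
    }
  }
  structure(list(name = name, layers = layers, input_size = input_size,
                 layer_labels = labels),
            class = "ap_backbone")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.ap_backbone <- function(x, ...) {
  cat(sprintf("<ap_backbone %s: %d layers (%s)%s>\n", x$name,
              length(x$layers), paste(x$layer_labels, collapse = ", "),
              if (is.null(x$input_size)) "" else
                sprintf(", input %dx%d", x$input_size[1], x$input_size[2])))
  invisible(x)
}

#' The deterministic fixture CNN
#'
#' Three rectified conv stages (8, 12 and 16 channels) separated by 2x2
#' mean-pools, labelled L01..L03; accepts tiles at native size. Stage one is
#' a hand-crafted filter bank whose oriented-gradient channels make stripe
#' and grain textures visible in the activation maps; stages two and three
#' use weights frozen from a fixed seed constant, so every forward pass is
#' bit-reproducible.
#'
#' @return An `ap_backbone` named `"fixture-cnn"`.
#' @export
fixture_backbone <- function() {
  lum <- c(0.299, 0.587, 0.114)
  k_box <- matrix(1 / 9, 3, 3)
  k_sx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, 3)        # column gradient
  k_sy <- t(k_sx)                                               # row gradient
  k_lap <- matrix(c(0, 1, 0, 1, -4, 1, 0, 1, 0), 3, 3)
  W1 <- array(0, c(3, 3, 3, 8))
  for (ch in 1:3) {
    W1[, , ch, 1] <- k_box * lum[ch]
    W1[, , ch, 2] <- k_sx * lum[ch]
    W1[, , ch, 3] <- k_sy * lum[ch]
    W1[, , ch, 4] <- k_lap * lum[ch]
  }
  W1[2, 2, , 5] <- c(-1, 1, 0)   # green-red opponency
  ap_with_seed(FIXTURE_SEED, {
    W1[, , , 6:8] <- rnorm(3 * 3 * 3 * 3, sd = 0.15)
    W2 <- array(rnorm(3 * 3 * 8 * 12, sd = 1 / sqrt(9 * 8)), c(3, 3, 8, 12))
    W3 <- array(rnorm(3 * 3 * 12 * 16, sd = 1 / sqrt(9 * 12)), c(3, 3, 12, 16))
  })
  backbone_spec("fixture-cnn", list(
    list(type = "conv", label = "L01", W = W1, b = rep(0, 8)),
    list(type = "pool"),
    list(type = "conv", label = "L02", W = W2, b = rep(0, 12)),
    list(type = "pool"),
    list(type = "conv", label = "L03", W = W3, b = rep(0, 16))
  ))
}

#' Specification of a pretrained 50-layer residual backbone
#'
#' Enumerates the 49 rectifier outputs of the standard 50-layer residual
#' architecture as L01..L49 with a 224x224 input contract. Weights are an
#' optional external download; without them the forward pass raises a
#' capability error pointing at [fixture_backbone()], which all bundled
#' analyses use.
#'
#' @return An `ap_backbone` named `"resnet50-pretrained"` (metadata only).
#' @export
resnet50_backbone <- function() {
  structure(list(name = "resnet50-pretrained",
                 layers = list(),
                 input_size = c(224L, 224L),
                 layer_labels = sprintf("L%02d", 1:49)),
            class = "ap_backbone")
}

# im2col "same" convolution: zero-padded patches flattened to a
# (H*W) x (kh*kw*Cin) matrix, multiplied once against the kernel matrix.
conv2d_same <- function(x, W, b) {
  d <- dim(x); H <- d[1]; Wd <- d[2]; Cin <- d[3]
  kh <- dim(W)[1]; kw <- dim(W)[2]; Cout <- dim(W)[4]
  ph <- (kh - 1L) %/% 2L; pw <- (kw - 1L) %/% 2L
  xp <- array(0, c(H + 2L * ph, Wd + 2L * pw, Cin))
  xp[ph + seq_len(H), pw + seq_len(Wd), ] <- x
  cols <- matrix(0, H * Wd, kh * kw * Cin)
  k <- 0L
  for (c_in in seq_len(Cin)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    k <- k + 1L
    cols[, k] <- as.vector(xp[(di - 1L) + seq_len(H), (dj - 1L) + seq_len(Wd), c_in])
  }
  Wm <- matrix(0, kh * kw * Cin, Cout)
  k <- 0L
  for (c_in in seq_len(Cin)) for (dj in seq_len(kw)) for (di in seq_len(kh)) {
    k <- k + 1L
    Wm[k, ] <- W[di, dj, c_in, ]
  }
  out <- cols %*% Wm
  out <- sweep(out, 2L, b, `+`)
  array(out, c(H, Wd, Cout))
}

mean_pool2 <- function(x) {
  d <- dim(x)
  H <- (d[1] %/% 2L) * 2L; W <- (d[2] %/% 2L) * 2L
  if (H < 2L || W < 2L) return(x)
  x <- x[seq_len(H), seq_len(W), , drop = FALSE]
  out <- array(0, c(H %/% 2L, W %/% 2L, d[3]))
  for (ch in seq_len(d[3])) {
    m <- x[, , ch]
    out[, , ch] <- (m[seq(1, H, 2), seq(1, W, 2)] + m[seq(2, H, 2), seq(1, W, 2)] +
                      m[seq(1, H, 2), seq(2, W, 2)] + m[seq(2, H, 2), seq(2, W, 2)]) / 4
  }
  out
}

relu <- function(x) { x[x < 0] <- 0; x }

# bilinear resize of an H x W x C array to (h, w)
bilinear_resize <- function(x, h, w) {
  d <- dim(x)
  if (d[1] == h && d[2] == w) return(x)
  if (requireNamespace("EBImage", quietly = TRUE)) {
    y <- EBImage::resize(EBImage::Image(aperm(x, c(2, 1, 3)), colormode = "Color"),
                         w = w, h = h)
    return(aperm(EBImage::imageData(y), c(2, 1, 3)))
  }
  rs <- (seq_len(h) - 0.5) * d[1] / h - 0.5
  cs <- (seq_len(w) - 0.5) * d[2] / w - 0.5
  r0 <- pmin(pmax(floor(rs), 0), d[1] - 1L); r1 <- pmin(r0 + 1L, d[1] - 1L)
  c0 <- pmin(pmax(floor(cs), 0), d[2] - 1L); c1 <- pmin(c0 + 1L, d[2] - 1L)
  fr <- pmin(pmax(rs - r0, 0), 1); fc <- pmin(pmax(cs - c0, 0), 1)
  out <- array(0, c(h, w, d[3]))
  for (ch in seq_len(d[3])) {
    m <- x[, , ch]
    a <- m[r0 + 1L, c0 + 1L, drop = FALSE]; b <- m[r0 + 1L, c1 + 1L, drop = FALSE]
    cc <- m[r1 + 1L, c0 + 1L, drop = FALSE]; dd <- m[r1 + 1L, c1 + 1L, drop = FALSE]
    top <- a * outer(rep(1, h), 1 - fc) + b * outer(rep(1, h), fc)
    bot <- cc * outer(rep(1, h), 1 - fc) + dd * outer(rep(1, h), fc)
    out[, , ch] <- top * outer(1 - fr, rep(1, w)) + bot * outer(fr, rep(1, w))
  }
  out
}

# Forward pass: returns a named list of post-nonlinearity tensors per
# labelled layer, plus the final labelled tensor under $final.
backbone_forward <- function(tile, backbone) {
  ap_assert(inherits(backbone, "ap_backbone"), "backbone must be an ap_backbone")
  if (identical(backbone$name, "resnet50-pretrained"))
    ap_stop("pretrained weights for 'resnet50-pretrained' are not bundled; ",
            "supply a weights source or use fixture_backbone()",
            class = "ap_capability_error")
  x <- tile$pixels * 1.0
  if (!is.null(backbone$input_size))
    x <- bilinear_resize(x, backbone$input_size[1], backbone$input_size[2])
  acts <- list()
  for (l in backbone$layers) {
    if (l$type == "conv") {
      x <- relu(conv2d_same(x, l$W, l$b))
      acts[[l$label]] <- x
    } else if (l$type == "pool") {
      x <- mean_pool2(x)
    } else if (l$type == "noise") {
      seed <- (floor(sum(x)) + (l$seed %||% 0)) %% 2147483647
      x <- ap_with_seed(seed,
                        array(rnorm(prod(dim(x)[1:2])) * (l$sigma %||% 1),
                              c(dim(x)[1:2], 1L)))
      acts[[l$label]] <- x
    }
  }
  acts
}
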