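# Independent brute-force oracles. These deliberately share no code with
# the package: plain loops and textbook formulas only.

# GLCM contrast by explicit pixel-pair enumeration: visit every pixel, every
# offset, accumulate (level_a - level_b)^2 over all co-occurring pairs
# (both directions when symmetric), divide by the number of pairs.
oracle_contrast <- function(values, offsets, symmetric = TRUE) {
  nr <- nrow(values); nc <- ncol(values)
  total <- 0; n_pairs <- 0
  for (off in offsets) {
    for (r in seq_len(nr)) {
      for (cc in seq_len(nc)) {
        r2 <- r + off[1]; c2 <- cc + off[2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        d2 <- (values[r, cc] - values[r2, c2])^2
        if (symmetric) { total <- total + 2 * d2; n_pairs <- n_pairs + 2 }
        else { total <- total + d2; n_pairs <- n_pairs + 1 }
      }
    }
  }
  total / n_pairs
}

# Tile-grid enumerator: walk every grid cell of an R x C raster with side s
# pixels, compute its clipped area, count cells meeting the area rule.
oracle_tile_count <- function(R, C, s, gsd, min_area) {
  n <- 0
  r0 <- 0
  while (r0 < R) {
    c0 <- 0
    while (c0 < C) {
      h <- min(s, R - r0); w <- min(s, C - c0)
      if (h * w * gsd^2 >= min_area - 1e-9) n <- n + 1
      c0 <- c0 + s
    }
    r0 <- r0 + s
  }
  n
}

# Confusion-matrix metrics recounted from the raw label lists.
oracle_metrics <- function(truth, pred, classes) {
  per <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    list(tp = tp, fp = fp, fn = fn, tn = tn, precision = p, recall = r, f1 = f1)
  })
  list(accuracy = sum(truth == pred) / length(truth),
       macro_recall = mean(vapply(per, `[[`, 0, "recall")),
       macro_f1 = mean(vapply(per, `[[`, 0, "f1")),
       per = per)
}

# Explained-variance ratios from a hand-rolled eigendecomposition of the
# correlation (standardized covariance) matrix.
oracle_pca_ratios <- function(X) {
  Z <- scale(X)
  S <- t(Z) %*% Z / (nrow(Z) - 1)
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values, decreasing = TRUE)
  ev / sum(ev)
}
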