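# Feature screening: Pearson correlation across features, greedy redundancy
# pruning, and standardized-PCA summaries.

#' Pairwise Pearson correlation matrix of a feature table
#'
#' Correlations are computed over pairwise-complete rows so that missing
#' sentinels in one feature do not delete whole rows. A constant feature, or
#' a pair with fewer than 3 complete rows, yields NA against all partners
#' (with a warning); the diagonal is 1 by definition.
#'
#' @param table An `ap_features` table (or bare numeric data.frame/matrix).
#' @return Symmetric features x features correlation matrix.
#' @export
pearson_matrix <- function(table) {
  X <- if (inherits(table, "ap_features")) feature_matrix(table) else as.matrix(table)
  ap_assert(nrow(X) >= 3L, "need at least 3 rows for correlation screening")
  r <- suppressWarnings(cor(X, use = "pairwise.complete.obs"))
  const <- vapply(seq_len(ncol(X)), function(j) {
    v <- X[, j][!is.na(X[, j])]
    length(v) < 2L || sd(v) == 0
  }, TRUE)
  if (any(const)) {
    warning("constant feature(s) flagged: ",
            paste(colnames(X)[const], collapse = ", "))
    r[const, ] <- NA_real_
    r[, const] <- NA_real_
  }
  # pairs with < 3 complete observations are unreliable: sentinel + warning
  obs <- crossprod(!is.na(X))
  if (any(obs < 3L & upper.tri(obs))) {
    warning("feature pair(s) with fewer than 3 complete rows set to NA")
    r[obs < 3L] <- NA_real_
  }
  diag(r) <- 1
  r
}

#' Drop redundant features by greedy correlation pruning
#'
#' Features are scanned in `priority` order; a feature is dropped when its
#' absolute correlation with an already-retained feature reaches
#' `threshold`, and the retained partner is recorded. NA correlations never
#' trigger a drop.
#'
#' @param matrix Correlation matrix from [pearson_matrix()].
#' @param threshold Absolute-correlation cutoff in (0, 1]; default 0.90.
#' @param priority Feature names in retention-priority order; defaults to
#'   the matrix column order (canonical order: the twelve colour indices,
#'   then CON, then activation-layer contrasts).
#' @return An object of class `ap_screening`: list with `correlation`,
#'   `threshold`, `kept` (character), and `dropped` (data.frame with
#'   `feature`, `partner`, `r`).
#' @export
drop_redundant <- function(matrix, threshold = 0.90, priority = colnames(matrix)) {
  ap_assert(is.matrix(matrix) && nrow(matrix) == ncol(matrix),
            "correlation matrix must be square")
  ap_assert(is_number(threshold) && threshold > 0 && threshold <= 1,
            "threshold must lie in (0, 1]")
  ap_assert(setequal(priority, colnames(matrix)),
            "priority must be a permutation of the matrix's feature names")
  kept <- character(0)
  dropped <- data.frame(feature = character(0), partner = character(0),
                        r = numeric(0), stringsAsFactors = FALSE)
  for (f in priority) {
    rs <- abs(matrix[f, kept])
    hit <- which(!is.na(rs) & rs >= threshold)
    if (length(hit)) {
      dropped <- rbind(dropped, data.frame(
        feature = f, partner = kept[hit[1]], r = matrix[f, kept[hit[1]]],
        stringsAsFactors = FALSE))
    } else {
      kept <- c(kept, f)
    }
  }
  structure(list(correlation = matrix, threshold = threshold,
                 kept = kept, dropped = dropped),
            class = "ap_screening")
}

#' @export
print.ap_screening <- function(x, ...) {
  cat(sprintf("<ap_screening: |r| >= %.2f, kept %d, dropped %d>\n",
              x$threshold, length(x$kept), nrow(x$dropped)))
  if (nrow(x$dropped)) print(x$dropped)
  invisible(x)
}

#' Standardized principal component summary
#'
#' Missing sentinels are imputed by the feature's median, features are
#' standardized to zero mean and unit variance, and the decomposition's
#' sign convention is fixed (the largest-magnitude loading of each
#' component is made positive) so that outputs are reproducible.
#'
#' @param table An `ap_features` table or numeric data.frame/matrix.
#' @param n_components Number of component score columns to return.
#' @return List with `explained` (variance ratios of all components,
#'   non-increasing, summing to 1), `scores` (rows x n_components), and
#'   `loadings` (features x n_components).
#' @export
pca_summary <- function(table, n_components = 2L) {
  X <- if (inherits(table, "ap_features")) feature_matrix(table) else as.matrix(table)
  ap_assert(ncol(X) >= 2L && nrow(X) >= 3L, "PCA needs >= 2 features and >= 3 rows")
  for (j in seq_len(ncol(X))) {
    nas <- is.na(X[, j])
    if (any(nas)) X[nas, j] <- median(X[, j], na.rm = TRUE)
  }
  keep <- apply(X, 2L, sd) > 0
  if (!all(keep)) {
    warning("zero-variance feature(s) excluded from PCA: ",
            paste(colnames(X)[!keep], collapse = ", "))
    X <- X[, keep, drop = FALSE]
    ap_assert(ncol(X) >= 2L, "fewer than 2 non-constant features remain")
  }
  p <- prcomp(X, center = TRUE, scale. = TRUE)
  flip <- vapply(seq_len(ncol(p$rotation)), function(k) {
    l <- p$rotation[, k]
    sign(l[which.max(abs(l))])
  }, 0)
  flip[flip == 0] <- 1
  p$rotation <- sweep(p$rotation, 2L, flip, `*`)
  p$x <- sweep(p$x, 2L, flip, `*`)
  n_components <- min(n_components, ncol(p$x))
  list(explained = p$sdev^2 / sum(p$sdev^2),
       scores = p$x[, seq_len(n_components), drop = FALSE],
       loadings = p$rotation[, seq_len(n_components), drop = FALSE])
}
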