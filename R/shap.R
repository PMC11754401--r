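# Additive tree-path feature attributions for random forests.
#
# For each tree, the class-probability "value" of every node is the class
# distribution of the training rows reaching it; a test row's prediction is
# then the root value plus, at every split on its path, the change in value
# from parent to child, attributed to the split feature. Summed over trees
# this yields an exact additive decomposition (base value + per-feature
# contributions = the forest's leaf-distribution score for the row), the
# per-tree-path member of the Shapley-value family of explanations.

# Route rows of X (matrix, model feature order) through one getTree matrix;
# returns integer node assignment per row at the terminal, and a list of
# row indices per node.
route_rows <- function(tree, X) {
  n_nodes <- nrow(tree)
  node_rows <- vector("list", n_nodes)
  node_rows[[1L]] <- seq_len(nrow(X))
  for (nd in seq_len(n_nodes)) {
    rows <- node_rows[[nd]]
    if (is.null(rows) || tree[nd, "status"] == -1L) next
    v <- tree[nd, "split var"]; pt <- tree[nd, "split point"]
    left <- X[rows, v] <= pt
    node_rows[[tree[nd, "left daughter"]]] <- rows[left]
    node_rows[[tree[nd, "right daughter"]]] <- rows[!left]
  }
  node_rows
}

# class-distribution value of every node from training rows routed to it
node_values <- function(tree, node_rows, y, classes) {
  V <- matrix(0, nrow(tree), length(classes))
  for (nd in seq_len(nrow(tree))) {
    rows <- node_rows[[nd]]
    if (is.null(rows) || !length(rows)) next
    V[nd, ] <- tabulate(as.integer(y[rows]), nbins = length(classes)) / length(rows)
  }
  V
}

#' Tree-path attributions of a random-forest model
#'
#' Computes, for every test row, feature and class, the additive tree-path
#' contribution of the feature to the model's class score, and summarises
#' contributions as the mean absolute value per feature and class (the
#' stacked-bar summary in which longer bars mean larger contributions).
#' Features never used by any tree receive exactly 0. Additivity holds
#' exactly: `base + rowSums over features = score` for every row and class.
#'
#' @param model An `ap_model` from [train_rf()].
#' @param test Test `ap_features` table.
#' @param n_trees Optionally restrict to the first n trees (all by default).
#' @return An `ap_shap`: list with `mean_abs` (features x classes matrix,
#'   rows ordered by total contribution), `base` (class score at the root,
#'   averaged over trees), `attributions` (rows x features x classes
#'   array), and `scores` (rows x classes forest leaf-distribution scores).
#' @export
shap_summary <- function(model, test, n_trees = NULL) {
  ap_assert(inherits(model, "ap_model"), "model must be a trained ap_model")
  Xte <- impute_with(feature_matrix(test, model$features), model$medians)
  p <- length(model$features); K <- length(model$classes); n <- nrow(Xte)
  nt <- if (is.null(n_trees)) model$rf$ntree else min(n_trees, model$rf$ntree)
  contrib <- array(0, c(n, p, K),
                   dimnames = list(NULL, model$features, model$classes))
  base <- numeric(K)
  scores <- matrix(0, n, K, dimnames = list(NULL, model$classes))
  for (t in seq_len(nt)) {
    tree <- randomForest::getTree(model$rf, t, labelVar = FALSE)
    tr_rows <- route_rows(tree, model$train_x)
    V <- node_values(tree, tr_rows, model$train_y, model$classes)
    base <- base + V[1L, ]
    te_rows <- vector("list", nrow(tree))
    te_rows[[1L]] <- seq_len(n)
    for (nd in seq_len(nrow(tree))) {
      rows <- te_rows[[nd]]
      if (is.null(rows) || !length(rows)) next
      if (tree[nd, "status"] == -1L) {
        scores[rows, ] <- scores[rows, ] + rep(V[nd, ], each = length(rows))
        next
      }
      v <- tree[nd, "split var"]; pt <- tree[nd, "split point"]
      left <- rows[Xte[rows, v] <= pt]
      right <- setdiff(rows, left)
      for (side in list(list(ch = tree[nd, "left daughter"], rws = left),
                        list(ch = tree[nd, "right daughter"], rws = right))) {
        if (!length(side$rws)) next
        delta <- V[side$ch, ] - V[nd, ]
        contrib[side$rws, v, ] <- contrib[side$rws, v, ] +
          rep(delta, each = length(side$rws))
        te_rows[[side$ch]] <- side$rws
      }
    }
  }
  contrib <- contrib / nt
  base <- base / nt
  scores <- scores / nt
  mean_abs <- apply(abs(contrib), c(2, 3), mean)
  mean_abs <- mean_abs[order(-rowSums(mean_abs)), , drop = FALSE]
  structure(list(mean_abs = mean_abs, base = stats::setNames(base, model$classes),
                 attributions = contrib, scores = scores),
            class = "ap_shap")
}

#' @export
print.ap_shap <- function(x, ...) {
  cat("<ap_shap: mean |contribution| per feature (rows) and class (cols)>\n")
  print(round(x$mean_abs, 4))
  invisible(x)
}
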