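# Random-forest classification of field states and confusion-matrix
# evaluation. Binary-form metrics (accuracy = (TP+TN)/(TP+FP+FN+TN),
# recall = TP/(TP+FN), F1 = 2PR/(P+R)) are applied per class one-vs-rest
# and macro-averaged; the overall multiclass accuracy is the confusion
# matrix trace over the test size.

#' Train/test split specification
#'
#' @param test_fraction Fraction of rows held out for testing (default 0.5,
#'   the 5:5 protocol).
#' @param stratified Split within each class (default TRUE).
#' @param seed Integer seed; the split is deterministic per seed.
#' @return Object of class `ap_split_spec`.
#' @export
split_spec <- function(test_fraction = 0.5, stratified = TRUE, seed = 20251L) {
  ap_assert(is_number(test_fraction) && test_fraction > 0 && test_fraction < 1,
            "test_fraction must lie in (0, 1)")
  structure(list(test_fraction = test_fraction, stratified = isTRUE(stratified),
                 seed = seed),
            class = "ap_split_spec")
}

#' Random-forest configuration
#'
#' @param n_trees Number of trees (default 500).
#' @param max_features Per-split feature rule: `"sqrt"` (default) or a count.
#' @param min_leaf Minimum terminal-node size (default 1).
#' @param seed Integer seed for reproducible fits.
#' @return Object of class `ap_rf_config`.
#' @export
rf_config <- function(n_trees = 500L, max_features = "sqrt", min_leaf = 1L,
                      seed = 20251L) {
  ap_assert(is_count(n_trees, 1L), "n_trees must be >= 1")
  ap_assert(identical(max_features, "sqrt") || is_count(max_features, 1L),
            "max_features must be 'sqrt' or a count")
  ap_assert(is_count(min_leaf, 1L), "min_leaf must be >= 1")
  structure(list(n_trees = as.integer(n_trees), max_features = max_features,
                 min_leaf = as.integer(min_leaf), seed = seed),
            class = "ap_rf_config")
}

#' Split a feature table into train and test tables
#'
#' Stratified splits draw `round(n_class * test_fraction)` test rows per
#' class, so per-class proportions are within one row of the target; the
#' split is disjoint, exhaustive and deterministic per seed.
#'
#' @param table An `ap_features` table with labels.
#' @param spec A [split_spec()].
#' @return List with `train` and `test` tables.
#' @export
split_table <- function(table, spec = split_spec()) {
  ap_assert(inherits(table, "ap_features"), "table must be an ap_features table")
  lab <- table$label
  ap_assert(!anyNA(lab), "all rows must be labelled to split")
  test_idx <- ap_with_seed(spec$seed, {
    if (spec$stratified) {
      counts <- table(droplevels(lab))
      if (any(counts < 2L))
        ap_stop("stratified split needs >= 2 rows per class; offending: ",
                paste(names(counts)[counts < 2L], collapse = ", "))
      unlist(lapply(levels(droplevels(lab)), function(cl) {
        rows <- which(lab == cl)
        sample(rows, round(length(rows) * spec$test_fraction))
      }))
    } else {
      sample(nrow(table), round(nrow(table) * spec$test_fraction))
    }
  })
  list(train = table[-test_idx, , drop = FALSE],
       test = table[sort(test_idx), , drop = FALSE])
}

#' Named feature combination
#'
#' @param name Combination name (e.g. `"color+texture"`).
#' @param features Member feature names.
#' @return Object of class `ap_combo`.
#' @export
feature_combo <- function(name, features) {
  ap_assert(is.character(features) && length(features) >= 1L,
            "features must be a non-empty character vector")
  structure(list(name = name, features = unique(features)), class = "ap_combo")
}

#' Train a random forest on a feature combination
#'
#' Missing sentinels are imputed by training-set medians (stored with the
#' model and re-applied at prediction time); the fit is deterministic per
#' `config$seed`. The returned handle carries everything needed for
#' prediction and for tree-path attributions, and survives saveRDS/readRDS
#' with identical predictions.
#'
#' @param table Training `ap_features` table.
#' @param combo An [feature_combo()] (or character vector of feature names).
#' @param config An [rf_config()].
#' @return Object of class `ap_model`.
#' @export
train_rf <- function(table, combo, config = rf_config()) {
  if (is.character(combo)) combo <- feature_combo("custom", combo)
  ap_assert(inherits(combo, "ap_combo"), "combo must be a feature_combo")
  X <- feature_matrix(table, combo$features)
  y <- droplevels(table$label)
  ap_assert(!anyNA(y), "all training rows must be labelled")
  medians <- apply(X, 2L, median, na.rm = TRUE)
  medians[is.na(medians)] <- 0
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- medians[j]
  mtry <- if (identical(config$max_features, "sqrt"))
    max(1L, floor(sqrt(ncol(X)))) else min(ncol(X), config$max_features)
  rf <- ap_with_seed(config$seed,
                     randomForest::randomForest(x = X, y = y, ntree = config$n_trees,
                                                mtry = mtry, nodesize = config$min_leaf))
  structure(list(rf = rf, combo = combo, features = combo$features,
                 medians = medians, classes = levels(y),
                 train_x = X, train_y = y, config = config),
            class = "ap_model")
}

impute_with <- function(X, medians) {
  for (j in seq_len(ncol(X))) X[is.na(X[, j]), j] <- medians[colnames(X)[j]]
  X
}

#' @export
predict.ap_model <- function(object, newdata, ...) {
  X <- impute_with(feature_matrix(newdata, object$features), object$medians)
  predict(object$rf, X)
}

# one-vs-rest counts and binary-form metrics for class k of a confusion
# matrix (rows = truth, cols = predicted)
ovr_metrics <- function(cm, k) {
  tp <- cm[k, k]
  fn <- sum(cm[k, ]) - tp
  fp <- sum(cm[, k]) - tp
  tn <- sum(cm) - tp - fn - fp
  p <- if (tp + fp == 0) 0 else tp / (tp + fp)
  r <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (p + r == 0) 0 else 2 * p * r / (p + r)
  c(TP = tp, FP = fp, FN = fn, TN = tn,
    accuracy = (tp + tn) / (tp + fp + fn + tn),
    precision = p, recall = r, f1 = f1)
}

#' Evaluate a model on a test table
#'
#' @param model An `ap_model` from [train_rf()].
#' @param test Test `ap_features` table with labels; its features must
#'   include the model's.
#' @return An `ap_report`: list with `confusion` (classes x classes, rows =
#'   true), `accuracy` (trace / test size), `macro_recall`, `macro_f1`,
#'   `per_class` (data.frame of one-vs-rest TP/FP/FN/TN and metrics),
#'   `n_test`.
#' @export
evaluate_model <- function(model, test) {
  ap_assert(nrow(test) >= 1L, "test table must be non-empty")
  missing <- setdiff(model$features, names(test))
  if (length(missing))
    ap_stop("test table lacks model feature(s): ", paste(missing, collapse = ", "),
            class = "ap_schema_error")
  pred <- predict(model, test)
  truth <- factor(as.character(test$label), levels = model$classes)
  ap_assert(!anyNA(truth), "test labels must come from the model's class set")
  classification_report(truth, factor(as.character(pred), levels = model$classes))
}

#' Confusion matrix and macro metrics from labels
#'
#' @param truth,pred Factors on a common level set.
#' @return An `ap_report` (see [evaluate_model()]).
#' @export
classification_report <- function(truth, pred) {
  ap_assert(identical(levels(truth), levels(pred)),
            "truth and pred must share a level set")
  cm <- table(truth = truth, pred = pred)
  cm <- matrix(as.integer(cm), nrow(cm), ncol(cm), dimnames = dimnames(cm))
  per <- t(vapply(seq_along(levels(truth)), function(k) ovr_metrics(cm, k),
                  numeric(8)))
  per <- data.frame(class = levels(truth), per, row.names = NULL)
  if (any(per$TP + per$FP == 0))
    warning("empty predicted class(es); their precision/F1 defined as 0")
  structure(list(confusion = cm,
                 accuracy = sum(diag(cm)) / sum(cm),
                 macro_recall = mean(per$recall),
                 macro_f1 = mean(per$f1),
                 per_class = per,
                 n_test = sum(cm)),
            class = "ap_report")
}

#' @export
print.ap_report <- function(x, ...) {
  cat(sprintf("<ap_report: n=%d, accuracy %.4f, macro recall %.4f, macro F1 %.4f>\n",
              x$n_test, x$accuracy, x$macro_recall, x$macro_f1))
  print(x$confusion)
  invisible(x)
}

#' Confusion mass between two classes
#'
#' Share of all rows truly in classes `a` or `b` that were predicted as the
#' other one — the pairwise misidentification + omission mass.
#'
#' @param report An `ap_report`.
#' @param a,b Class labels.
#' @return Scalar in \[0, 1\].
#' @export
pair_confusion_mass <- function(report, a = "V", b = "VI") {
  cm <- report$confusion
  (cm[a, b] + cm[b, a]) / (sum(cm[a, ]) + sum(cm[b, ]))
}
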