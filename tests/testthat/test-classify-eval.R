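test_that("stratified splits hit exact per-class counts and are seed-stable", {
  tab <- toy_table(10, classes = AP_CLASSES)          # 60 rows, 10 per class
  halves <- split_table(tab, split_spec(0.5, seed = 60))
  expect_equal(nrow(halves$train), 30L)
  expect_equal(nrow(halves$test), 30L)
  expect_true(all(table(droplevels(halves$test$label)) == 5L))
  again <- split_table(tab, split_spec(0.5, seed = 60))
  expect_identical(halves$test$id, again$test$id)
  expect_length(intersect(halves$train$id, halves$test$id), 0)
  expect_setequal(c(halves$train$id, halves$test$id), tab$id)

  q <- split_table(toy_table(8, classes = c("I", "II")), split_spec(0.25, seed = 61))
  expect_true(all(table(droplevels(q$test$label)) == 2L))
})

test_that("a one-row class cannot be stratified", {
  tab <- feature_table(data.frame(x = c(1, 2, 3)), label = c("I", "I", "II"))
  expect_error(split_table(tab, split_spec(0.5)), "2 rows per class")
})

test_that("refitting with the same seed reproduces predictions; models round-trip", {
  tab <- toy_table(20, classes = c("I", "II", "III"))
  halves <- split_table(tab, split_spec(0.5, seed = 62))
  cfg <- rf_config(n_trees = 50, seed = 63)
  m1 <- train_rf(halves$train, c("sep", "noise"), cfg)
  m2 <- train_rf(halves$train, c("sep", "noise"), cfg)
  expect_identical(predict(m1, halves$test), predict(m2, halves$test))
  p <- withr::local_tempfile(fileext = ".rds")
  saveRDS(m1, p)
  m3 <- readRDS(p)
  expect_identical(predict(m1, halves$test), predict(m3, halves$test))
})

test_that("a feature equal to the class index separates training perfectly", {
  tab <- toy_table(15, classes = c("I", "II", "IV"))
  m <- train_rf(tab, "sep", rf_config(n_trees = 50, seed = 64))
  expect_equal(evaluate_model(m, tab)$accuracy, 1.0)
})

test_that("unknown feature names raise a configuration error listing columns", {
  tab <- toy_table(5)
  expect_error(train_rf(tab, "nope", rf_config(n_trees = 10)),
               "sep", class = "ap_config_error")
})

test_that("perfect predictions give unit metrics and a diagonal matrix", {
  lab <- factor(rep(AP_CLASSES, each = 4), levels = AP_CLASSES)
  rep <- classification_report(lab, lab)
  expect_equal(rep$accuracy, 1.0)
  expect_equal(rep$macro_recall, 1.0)
  expect_equal(rep$macro_f1, 1.0)
  expect_true(all(rep$confusion[upper.tri(rep$confusion)] == 0))
  expect_true(all(rep$confusion[lower.tri(rep$confusion)] == 0))
})

test_that("the binary hand example TP=5 FP=0 FN=2 TN=3 evaluates exactly", {
  truth <- factor(c(rep("I", 7), rep("II", 3)), levels = c("I", "II"))
  pred <- factor(c(rep("I", 5), rep("II", 2), rep("II", 3)), levels = c("I", "II"))
  rep <- classification_report(truth, pred)
  expect_equal(rep$accuracy, 0.8)
  i <- rep$per_class[rep$per_class$class == "I", ]
  expect_equal(unname(unlist(i[c("TP", "FP", "FN", "TN")])), c(5, 0, 2, 3))
  expect_equal(i$precision, 1.0)
  expect_equal(i$recall, 5 / 7)
  expect_equal(i$f1, 10 / 12)
  expect_equal(i$accuracy, 0.8)
})

test_that("reports agree with a recount oracle on random prediction lists", {
  withr::with_seed(65, {
    for (k in 1:10) {
      n <- sample(30:80, 1)
      truth <- factor(sample(AP_CLASSES, n, TRUE), levels = AP_CLASSES)
      pred <- factor(sample(AP_CLASSES, n, TRUE), levels = AP_CLASSES)
      rep <- classification_report(truth, pred)
      orc <- oracle_metrics(as.character(truth), as.character(pred), AP_CLASSES)
      expect_equal(rep$accuracy, orc$accuracy)
      expect_equal(rep$macro_recall, orc$macro_recall)
      expect_equal(rep$macro_f1, orc$macro_f1)
      expect_equal(sum(rep$confusion), n)
      expect_equal(unname(rowSums(rep$confusion)),
                   unname(as.vector(table(truth))))
    }
  })
})

test_that("empty predicted classes yield zero metrics with a warning", {
  truth <- factor(c("I", "I", "II", "II"), levels = c("I", "II", "III"))
  pred <- factor(c("I", "II", "II", "I"), levels = c("I", "II", "III"))
  expect_warning(rep <- classification_report(truth, pred), "empty predicted")
  iii <- rep$per_class[rep$per_class$class == "III", ]
  expect_equal(iii$precision, 0)
  expect_equal(iii$f1, 0)
})

test_that("tree-path attributions are additive and ignore unused features", {
  withr::with_seed(66, {
    tab <- toy_table(25, classes = c("I", "II", "V"))
    tab$dead <- rep(0, nrow(tab))       # constant: no tree can split on it
    class(tab) <- c("ap_features", "data.frame")
    halves <- split_table(tab, split_spec(0.4, seed = 67))
    m <- train_rf(halves$train, c("sep", "noise", "dead"),
                  rf_config(n_trees = 40, seed = 68))
    sh <- shap_summary(m, halves$test)
    expect_true(all(sh$mean_abs["dead", ] == 0))
    # additivity: base + sum over features = leaf-distribution score, per row/class
    recon <- sweep(apply(sh$attributions, c(1, 3), sum), 2, sh$base, `+`)
    expect_equal(unname(recon), unname(sh$scores), tolerance = 1e-12)
    # the separating feature dominates the noise feature for every class
    expect_true(all(sh$mean_abs["sep", ] > sh$mean_abs["noise", ]))
  })
})

test_that("the texture feature drives V/VI attributions on synthetic data", {
  tiles <- Filter(function(t) t$label %in% c("V", "VI"),
                  sample_tiles(40, tile_pixels = 40, seed = 69))
  tab <- extract_features(tiles, sets = c("color", "texture"))
  halves <- split_table(tab, split_spec(0.5, seed = 70))
  m <- train_rf(halves$train, feature_combo("ct", c(AP_COLOR_FEATURES, "CON")),
                rf_config(n_trees = 60, seed = 71))
  sh <- shap_summary(m, halves$test)
  for (cl in c("V", "VI"))
    expect_true(all(sh$mean_abs["CON", cl] >
                      sh$mean_abs[AP_COLOR_FEATURES, cl]))
})

test_that("extraction benchmarks report requested combos with subset monotonicity", {
  tiles <- sample_tiles(10, tile_pixels = 64, seed = 72)
  combos <- list(color = feature_combo("color", AP_COLOR_FEATURES),
                 `color+texture` = feature_combo("color+texture",
                                                 c(AP_COLOR_FEATURES, "CON")))
  bench <- benchmark_extraction(tiles, combos)
  expect_named(bench, c("color", "color+texture"))
  expect_lte(bench[["color"]], bench[["color+texture"]])
  expect_length(benchmark_extraction(tiles, list()), 0)
})
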