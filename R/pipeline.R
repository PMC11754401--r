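# End-to-end pipeline: extract feature tables from tiles, assemble the
# named feature combinations, train/evaluate every combination, and write a
# deterministic JSON/CSV report (timings, being hardware-dependent, go to a
# separate file).

#' Extract a feature table from labelled tiles
#'
#' @param tiles List of [image_tile()]s.
#' @param sets Feature families to extract: any of `"color"` (12 indices),
#'   `"texture"` (CON), `"layers"` (LxxCON per backbone layer), `"pooled"`
#'   (per-channel deep features RN0001..).
#' @param backbone Backbone for `"layers"`/`"pooled"`; default
#'   [fixture_backbone()].
#' @param config A [glcm_config()] shared by CON and LxxCON.
#' @param agg Channel-aggregation rule for activation maps.
#' @return An `ap_features` table with one row per tile, columns in the
#'   order colour indices, CON, LxxCON, pooled.
#' @export
extract_features <- function(tiles, sets = c("color", "texture"),
                             backbone = fixture_backbone(),
                             config = glcm_config(), agg = "mean") {
  ap_assert(length(tiles) >= 1L, "need at least one tile")
  ap_assert(all(sets %in% c("color", "texture", "layers", "pooled")),
            "sets must be among color, texture, layers, pooled")
  rows <- lapply(tiles, function(tile) {
    parts <- list()
    if ("color" %in% sets) parts$color <- color_features(tile)
    if ("texture" %in% sets)
      parts$texture <- data.frame(CON = unname(texture_features(tile, config)))
    if ("layers" %in% sets || "pooled" %in% sets) {
      acts <- backbone_forward(tile, backbone)
      if ("layers" %in% sets) {
        con <- vapply(backbone$layer_labels, function(lab)
          activation_contrast(aggregate_channels(acts[[lab]], agg), config), 0)
        parts$layers <- as.data.frame(as.list(stats::setNames(
          con, paste0(backbone$layer_labels, "CON"))))
      }
      if ("pooled" %in% sets) {
        fin <- acts[[length(acts)]]
        v <- colMeans(matrix(fin, prod(dim(fin)[1:2]), dim(fin)[3]))
        parts$pooled <- as.data.frame(as.list(stats::setNames(
          v, sprintf("RN%04d", seq_along(v)))))
      }
    }
    do.call(cbind, unname(parts))
  })
  feature_table(do.call(rbind, rows),
                label = vapply(tiles, `[[`, "", "label"),
                id = vapply(tiles, `[[`, "", "id"))
}

#' Standard feature combinations
#'
#' Builds the named combinations evaluated by [run_all()] from the columns
#' actually present (and retained by screening): `color`, `color+texture`,
#' `color+LxxCON` (the top-ranked layer's contrast), `color+deep` (pooled
#' features), `color+texture+LxxCON`.
#'
#' @param features Available feature names.
#' @param top_layer Label of the top-ranked activation layer (e.g. "L02"),
#'   or NULL to skip the LxxCON combos.
#' @param include Names to build; default all available.
#' @return Named list of [feature_combo()]s.
#' @export
standard_combos <- function(features, top_layer = NULL,
                            include = c("color", "color+texture", "color+LxxCON",
                                        "color+deep", "color+texture+LxxCON")) {
  color <- intersect(AP_COLOR_FEATURES, features)
  ap_assert(length(color) >= 1L, "no colour features available")
  pooled <- grep("^RN\\d+$", features, value = TRUE)
  lcon <- if (!is.null(top_layer)) paste0(top_layer, "CON") else NULL
  out <- list()
  if ("color" %in% include) out$color <- feature_combo("color", color)
  if ("color+texture" %in% include && "CON" %in% features)
    out$`color+texture` <- feature_combo("color+texture", c(color, "CON"))
  if ("color+LxxCON" %in% include && !is.null(lcon) && lcon %in% features)
    out$`color+LxxCON` <- feature_combo("color+LxxCON", c(color, lcon))
  if ("color+deep" %in% include && length(pooled))
    out$`color+deep` <- feature_combo("color+deep", c(color, pooled))
  if ("color+texture+LxxCON" %in% include && "CON" %in% features &&
      !is.null(lcon) && lcon %in% features)
    out$`color+texture+LxxCON` <-
      feature_combo("color+texture+LxxCON", c(color, "CON", lcon))
  out
}

#' Time feature extraction per combination
#'
#' Wall-clock seconds per tile for extracting exactly the feature families
#' each combination needs. Hardware-dependent by nature: reported for
#' orientation, never an acceptance quantity.
#'
#' @param tiles List of [image_tile()]s.
#' @param combos List of [feature_combo()]s.
#' @param backbone,config Passed to [extract_features()].
#' @return Named numeric vector of seconds per tile, one per combo name.
#' @export
benchmark_extraction <- function(tiles, combos, backbone = fixture_backbone(),
                                 config = glcm_config()) {
  if (!length(combos)) return(stats::setNames(numeric(0), character(0)))
  vapply(combos, function(combo) {
    sets <- c("color",
              if ("CON" %in% combo$features) "texture",
              if (any(grepl("^L\\d+CON$", combo$features))) "layers",
              if (any(grepl("^RN\\d+$", combo$features))) "pooled")
    t0 <- proc.time()[["elapsed"]]
    extract_features(tiles, sets = sets, backbone = backbone, config = config)
    (proc.time()[["elapsed"]] - t0) / length(tiles)
  }, 0)
}

#' Default pipeline configuration
#'
#' @param n_per_class Synthetic tiles per class.
#' @param seed Master seed (generation, split and forest seeds derive from it).
#' @param tile_pixels,gsd Tile geometry (see [dataset_spec()]).
#' @param screening_threshold Absolute-correlation cutoff for
#'   [drop_redundant()].
#' @param n_trees Forest size.
#' @param test_fraction Held-out fraction (default 0.5).
#' @param combos Combination names to run.
#' @param glcm_levels Gray levels for CON / LxxCON.
#' @param benchmark Also time per-combo feature extraction.
#' @return Config list for [run_all()].
#' @export
pipeline_config <- function(n_per_class = 500L, seed = 1L, tile_pixels = 150L,
                            gsd = 0.004, screening_threshold = 0.90,
                            n_trees = 500L, test_fraction = 0.5,
                            combos = c("color", "color+texture", "color+LxxCON",
                                       "color+deep", "color+texture+LxxCON"),
                            glcm_levels = 32L, benchmark = FALSE) {
  as.list(environment())
}

#' Run the full synthetic experiment
#'
#' Generates the six-class synthetic dataset, extracts colour, texture,
#' activation-contrast and pooled deep features, screens redundant features
#' on the training half, ranks activation layers there, trains a random
#' forest per feature combination and evaluates each on the held-out half.
#' The deterministic report is returned and, when `out_dir` is given,
#' written as `report.json` and `summary.csv` (timings, if requested, go to
#' `timings.json` so the report itself is byte-reproducible per seed).
#'
#' @param config List from [pipeline_config()] (or a YAML file path with
#'   the same keys).
#' @param out_dir Optional output directory.
#' @return Invisibly, the report list: `screening`, `layer_ranking`,
#'   `combos` (per combo: features, accuracy, macro recall/F1, per-class
#'   metrics, confusion matrix), `pca` (explained-variance ratios for the
#'   colour and colour+texture feature sets), `n_train`, `n_test`.
#' @export
run_all <- function(config = pipeline_config(), out_dir = NULL) {
  if (is.character(config)) config <- modifyList(pipeline_config(), yaml::read_yaml(config))
  backbone <- fixture_backbone()
  gl <- glcm_config(levels = config$glcm_levels)
  dspec <- dataset_spec(config$n_per_class, tile_pixels = config$tile_pixels,
                        gsd = config$gsd, seed = config$seed)
  tiles <- generate_dataset(dspec)
  sets <- c("color", "texture",
            if (any(grepl("LxxCON", config$combos))) "layers",
            if ("color+deep" %in% config$combos) "pooled")
  tab <- extract_features(tiles, sets = sets, backbone = backbone, config = gl)
  halves <- split_table(tab, split_spec(config$test_fraction, seed = config$seed + 1))

  # screen colour+texture features on the training half only
  screen_cols <- intersect(c(AP_COLOR_FEATURES, "CON"), feature_names(tab))
  scr <- drop_redundant(pearson_matrix(halves$train[, c("id", screen_cols, "label")]),
                        threshold = config$screening_threshold,
                        priority = screen_cols)

  # rank activation layers on the training half
  ranking <- NULL; top_layer <- NULL
  lcon_cols <- grep("^L\\d+CON$", feature_names(tab), value = TRUE)
  if (length(lcon_cols)) {
    lab <- droplevels(halves$train$label)
    score <- vapply(lcon_cols, function(cl) eta_squared(halves$train[[cl]], lab), 0)
    layers <- sub("CON$", "", lcon_cols)
    ord <- order(-score, match(layers, backbone$layer_labels))
    ranking <- data.frame(layer = layers[ord], score = unname(score[ord]))
    top_layer <- ranking$layer[1]
  }

  retained <- c(scr$kept, setdiff(feature_names(tab), screen_cols))
  combos <- standard_combos(retained, top_layer = top_layer, include = config$combos)

  results <- lapply(combos, function(combo) {
    model <- train_rf(halves$train, combo, rf_config(config$n_trees, seed = config$seed + 2))
    rep <- evaluate_model(model, halves$test)
    list(features = combo$features,
         accuracy = rep$accuracy, macro_recall = rep$macro_recall,
         macro_f1 = rep$macro_f1, per_class = rep$per_class,
         confusion = rep$confusion,
         v_vi_confusion = pair_confusion_mass(rep, "V", "VI"))
  })

  pca <- list(
    color = pca_summary(halves$train[, c("id", intersect(AP_COLOR_FEATURES, retained), "label")])$explained,
    color_texture = if ("CON" %in% retained)
      pca_summary(halves$train[, c("id", intersect(c(AP_COLOR_FEATURES, "CON"), retained), "label")])$explained)

  report <- list(
    config = config[setdiff(names(config), "benchmark")],
    n_train = nrow(halves$train), n_test = nrow(halves$test),
    screening = list(threshold = scr$threshold, kept = scr$kept, dropped = scr$dropped),
    layer_ranking = ranking,
    combos = results,
    pca_explained = pca)

  timings <- if (isTRUE(config$benchmark)) {
    bench_tiles <- tiles[seq_len(min(20L, length(tiles)))]
    as.list(benchmark_extraction(bench_tiles, combos, backbone, gl))
  }

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    summ <- do.call(rbind, lapply(names(results), function(nm) {
      r <- results[[nm]]
      data.frame(combo = nm, accuracy = r$accuracy, macro_recall = r$macro_recall,
                 macro_f1 = r$macro_f1, v_vi_confusion = r$v_vi_confusion)
    }))
    data.table::fwrite(summ, file.path(out_dir, "summary.csv"))
    if (!is.null(timings))
      jsonlite::write_json(timings, file.path(out_dir, "timings.json"),
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report$timings <- timings
  invisible(report)
}
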