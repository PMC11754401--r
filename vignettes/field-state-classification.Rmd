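---
title: "Classifying field states in rice-wheat rotation areas from UAV RGB tiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying field states in rice-wheat rotation areas from UAV RGB tiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agroprogress)
```

## The monitoring problem

Between rice harvest and completed wheat sowing, a rotation field passes
through six states: immature rice (I), harvestable rice (II), harvested
rice (III), ploughed land (IV), rotary-tilled land (V) and sown wheat (VI).
Knowing which state every plot is in, daily and without field visits, is
what drives timely harvesting and sowing decisions. A drone flying low
(about 15 m) with an ordinary RGB camera sees each plot at sub-centimetre
ground-sampling distance (GSD), which is enough to classify these states —
provided the right image features are extracted, because some state pairs
are nearly identical in colour and differ only in fine surface texture.

`agroprogress` implements that feature-extraction and classification
pipeline end to end:

1. **Tiling** (`tile_orthomosaic()`): the orthomosaic is cut on a regular
   grid into 0.60 m x 0.60 m tiles; partial edge tiles smaller than
   0.36 m^2 are excluded (exactly 0.36 m^2 is retained — the rule excludes
   strictly smaller tiles). The grid is anchored at the raster's top-left
   corner with 0-based, half-open pixel origins, so retained plus excluded
   footprints partition the raster exactly.
2. **Colour features** (`color_features()`): twelve RGB vegetation indices
   (ExG, INT, IKAW, VARI, ExR, GLI, ExGR, NGRDI, NGBDI, MGRVI, RGBVI,
   RGRI) computed from the tile's *mean* channel values on the 0-255
   scale. Mean-then-index is the contract; a per-pixel mode exists but is
   not the default. Scale-dependent indices (ExG, ExR, ExGR, INT) are
   documented as such; the ratio-form indices are invariant to a common
   channel rescaling.
3. **Texture** (`texture_features()`): gray-level co-occurrence matrix
   (GLCM) contrast, `CON = sum_ij (i-j)^2 C_ij`, on the luminance-
   quantized tile.
4. **Activation-map texture** (`extract_activation_maps()`,
   `activation_contrast()`, `rank_layers()`): the same contrast statistic
   computed on the min-max-normalized 2-D activation maps of a CNN
   backbone, one feature (`LxxCON`) per layer, with layers ranked by how
   well their contrast separates the classes.
5. **Screening** (`pearson_matrix()`, `drop_redundant()`): highly
   correlated features are pruned greedily before modelling.
6. **Classification and evaluation** (`train_rf()`, `evaluate_model()`,
   `shap_summary()`): a random forest per named feature combination,
   confusion-matrix metrics, and additive per-feature attributions.

## Why texture, and why CNN activations

Colour indices separate the vegetated states easily: immature rice is far
greener than anything else, and harvestable rice's golden canopy is
distinct from bare soil. They fail exactly where agronomy needs them most:
a rotary-tilled seedbed (V) and a freshly sown field (VI) are the same
soil at the same moisture — colour-identical — but the rotary tiller
leaves fine-grained high-contrast grain while the strip seeder leaves a
smooth surface crossed by periodic rows. GLCM contrast, and more flexibly
the contrast of oriented-filter activation maps, see that difference.

## The GLCM contrast statistic

A tile is reduced to Rec.601 luminance (`0.299R + 0.587G + 0.114B`),
uniformly quantized to `levels` gray levels (default 32, bin
`floor(lum * levels/256)` capped at `levels - 1`), and co-occurrences of
level pairs are counted at the four unit displacements (0,1), (1,0),
(1,1), (1,-1). The four offsets are pooled into a single matrix before
normalization — one orientation-averaged contrast per tile — and each
pair is counted in both directions (symmetric). Contrast is zero iff all
co-occurring pairs share a level, is invariant to a constant level shift,
and grows with both noise amplitude and stripe sharpness. Level count,
offsets and symmetry are all exposed through `glcm_config()`; whether to
quantize luminance or a single channel is a `texture_features()` argument
(luminance is the default).

For activation maps the map is min-max normalized to [0, 1] before
quantization (a constant map is defined to have contrast 0), which makes
`LxxCON` invariant under any positive affine rescaling of the map — a
property the test suite checks directly. Min-max rather than
standardization was chosen because the quantizer needs bounded input.

## The backbone and its fixture

`backbone_spec()` describes a CNN as an ordered stack of rectified
convolution stages (labelled `L01`, `L02`, ... in forward order),
mean-pool layers and optional data-independent noise layers. Activation
maps are channel-aggregated by mean (``max`` and ``channel:<k>`` are
available) — the aggregation rule is a genuine free choice, since a layer
is displayed as a single image but computed as a channel stack.

The shipped `fixture_backbone()` is deliberately small and fully
deterministic: stage one is a hand-crafted filter bank (luminance blur,
horizontal and vertical gradients, a Laplacian, green-red opponency, plus
three filters frozen from a fixed seed constant), stages two and three are
frozen random filters of 12 and 16 channels. Its final stage supplies the
pooled deep-feature vector (`pooled_features()`, spatial mean per
channel, `RN0001..RN0016`). A `resnet50_backbone()` spec enumerates the
49 rectifier outputs of the standard 50-layer residual network with a
224 x 224 input contract for users who can supply pretrained weights;
without weights its forward pass raises a capability error that points at
the fixture. Everything the package computes, tests and reports runs on
the fixture backbone.

Layer separability is scored by the correlation ratio eta^2 (between-class
sum of squares over total) of the layer's per-tile contrast;
`rank_layers()` sorts layers by it, ties broken by forward order. eta^2 is
the natural multi-class analogue of a correlation analysis between a
feature and a grouping; a rank-based Kruskal-Wallis epsilon^2 variant is
available via `statistic = "kruskal_eps_sq"`.

## The synthetic field generator

Real labelled rotation-season tile corpora are not generally available, so
`generate_dataset()` fabricates one. The generator is *not* a
photorealistic field simulator; it encodes exactly the qualitative feature
structure described above, so that every claim the package makes about
feature behaviour is testable:

* class I's green-minus-red and green-minus-blue margins strictly exceed
  every other class (so excess-green indices single it out);
* class III carries a strong periodic stripe texture (stubble rows);
* class IV is the smoothest surface and has the *lowest* contrast of the
  six — the reported ordering for ploughed land, kept as-is even though
  one might expect clods to look rough at 15 m altitude;
* classes V and VI share `base_rgb` and `rgb_jitter` exactly
  (colour-indistinguishable) and differ only in noise/stripe parameters
  (texture-distinguishable).

Each tile is a mean colour plus a tile-level Gaussian colour shift
(`rgb_jitter`, emulating lighting and moisture variation between plots), a
correlated-noise field (white noise box-smoothed over
`correlation_length` pixels and rescaled to pixel standard deviation
`noise_sigma`), and an optional phased sinusoid (`stripe_period`,
`stripe_amplitude`, `stripe_orientation`), all applied equally to the
three channels so texture lives in luminance. Pixels are clipped to
[0, 255] and rounded. Defaults: 150 px tiles at 0.004 m GSD — a 0.60 m
tile at the resolution a 20 MP camera delivers from 15 m.

Determinism is a contract: per-tile random streams are split from the
dataset seed, so the same `dataset_spec()` reproduces identical bytes and
growing `n_per_class` leaves earlier tiles untouched.

What the generator does *not* emulate — shadows, specular water, stitching
seams, plot-boundary mixtures, vegetation masks, radiometric drift —
bounds what passing tests show: they validate the pipeline's mechanics and
the feature-level claims, not field performance on real imagery.

## Screening, split and model defaults

* Redundancy pruning threshold: |r| >= 0.90, greedy in canonical feature
  order (the twelve colour indices, then CON, then layer contrasts), each
  drop recording its retained partner. Re-screening the retained set is a
  no-op. Correlations use pairwise-complete rows so missing sentinels do
  not delete rows; constant features and pairs with fewer than three
  complete rows become NA with a warning and never trigger a drop.
* Split: stratified 50/50 (`split_spec()`), `round(n_class * fraction)`
  test rows per class, deterministic per seed.
* Random forest: 500 trees, sqrt-features per split, unlimited depth,
  seed-fixed (`rf_config()`). Missing feature values are imputed by
  training-set medians stored with the model and re-applied at prediction
  time.
* Metrics: the binary formulas accuracy = (TP+TN)/(TP+FP+FN+TN),
  recall = TP/(TP+FN), F1 = 2PR/(P+R) are applied per class one-vs-rest
  and macro-averaged; overall accuracy is the confusion-matrix trace over
  the test size. A 0/0 metric (empty predicted class) is defined as 0 with
  a warning.
* Feature attributions: `shap_summary()` computes exact additive tree-path
  attributions — each node's value is the class distribution of training
  rows reaching it, and a test row's path attributes parent-to-child value
  changes to the split feature. Additivity (base + contributions = the
  forest's leaf-distribution score) holds exactly and is tested. The
  summary is the mean absolute contribution per feature and class.
  Features never used by any tree get exactly 0.

## Numerical choices and degenerate inputs

* Colour indices with a zero denominator (e.g. RGRI at G = 0) return NA,
  never an error; the sentinel propagates to the feature table and is
  imputed at fit time. RGBVI is computed as `(G^2 - BR)/(G^2 + BR)`; the
  product form sometimes printed for this index is dimensionally
  inconsistent with its normalised-difference family.
* Tile side in pixels is `round(tile_size_m / gsd)` (half up); the
  exact-threshold area comparison carries a 1e-9 slack so that binary
  representations of 0.36 m^2 do not flip the retention decision.
* A 1 x 1 image has no co-occurring pair and raises a degenerate-input
  error rather than returning NaN.
* PCA (`pca_summary()`) standardizes features, excludes zero-variance
  columns with a warning, and fixes the sign convention (largest-magnitude
  loading positive) so scores are byte-reproducible.
* `run_all()` writes its JSON report without timestamps or timings, so two
  runs at the same seeds are byte-identical; wall-clock extraction
  timings, being hardware-dependent, go to a separate `timings.json`.

## Problem sizes used by the bundled analyses

The synthetic study conditions are 500 tiles per class (3 000 tiles,
split 1 500/1 500) at the 150 px / 0.004 m defaults; that is the size the
acceptance script reruns. Unit and property tests use smaller samples
(tens of tiles, 32-64 px) chosen to keep each statistical check far from
its decision boundary.

## Known limitations

* The pretrained residual backbone is a specification only; bring your own
  weights loader to use it. All shipped results use the fixture CNN, whose
  16 pooled channels stand in for the 2048 of the large backbone.
* Mean-then-index colour features discard within-tile colour covariance;
  the per-pixel mode is available but changes the meaning of the
  ratio-form indices.
* No vegetation masking before channel averaging; if your workflow masks
  background before computing indices, do it upstream of
  `extract_features()`.
* Plot-boundary handling is the user's: tiles straddling plot edges should
  be avoided by pre-cropping rasters to plots.
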