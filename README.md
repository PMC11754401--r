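# agroprogress

Classification of agricultural progress in rice–wheat rotation areas from
UAV RGB imagery.

Between rice harvest and completed wheat sowing, every plot is in one of
six states — immature rice (I), harvestable rice (II), harvested rice
(III), ploughed land (IV), rotary-tilled land (V), sown wheat (VI) — and
farm managers need to know which, plot by plot, in near real time. A
low-altitude drone with an RGB camera sees enough to tell, but the hard
pairs (a rotary-tilled seedbed vs. a freshly sown field) are identical in
colour and differ only in surface texture. `agroprogress` implements the
full image-analysis pipeline for this problem, for agronomists and
remote-sensing practitioners working with orthomosaics or pre-cut tiles.

## What it computes

* **Tiling** — orthomosaics are cut into 0.60 m × 0.60 m tiles on a regular
  grid; partial edge tiles smaller than 0.36 m² are excluded.
* **Colour features** — twelve RGB vegetation indices from per-tile mean
  channel values $(\bar R, \bar G, \bar B)$, e.g.
  $\mathrm{ExG} = 2\bar G - \bar R - \bar B$,
  $\mathrm{VARI} = (\bar G-\bar R)/(\bar G+\bar R-\bar B)$,
  $\mathrm{RGRI} = \bar R/\bar G$.
* **Texture** — gray-level co-occurrence matrix (GLCM) contrast
  $\mathrm{CON} = \sum_i\sum_j (i-j)^2\,C_{ij}$
  on the luminance-quantized tile (32 levels, four pooled unit offsets,
  symmetric, normalized).
* **Activation-map texture** — the same contrast computed on min–max
  normalized 2-D activation maps of a CNN backbone ("LxxCON" per layer),
  with layers ranked by the correlation ratio $\eta^2$ of their contrast
  across classes; plus pooled per-channel deep features. A deterministic
  fixture CNN is bundled; a pretrained 50-layer residual spec is provided
  for users with their own weights.
* **Screening** — Pearson correlation across features with greedy pruning
  of pairs at $|r| \ge 0.90$, and standardized PCA summaries.
* **Classification & evaluation** — a random forest per named feature
  combination (`color`, `color+texture`, `color+LxxCON`, `color+deep`,
  `color+texture+LxxCON`), 6×6 confusion matrices, per-class one-vs-rest
  accuracy/precision/recall/F1 with macro averages, additive tree-path
  feature attributions, and per-combination extraction timings.
* **Synthetic fields** — a six-class tile generator whose defaults encode
  the season's feature structure (class I far greener than the rest;
  stubble stripes in III; ploughed land smoothest; V and VI
  colour-identical but texture-distinct), so the whole pipeline is
  testable without field imagery.

## Worked example

```r
library(agroprogress)

tiles  <- generate_dataset(dataset_spec(n_per_class = 60, tile_pixels = 64, seed = 42))
tab    <- extract_features(tiles, sets = c("color", "texture"))
halves <- split_table(tab, split_spec(0.5, seed = 1))

m_color <- train_rf(halves$train, feature_combo("color", AP_COLOR_FEATURES),
                    rf_config(300, seed = 2))
m_ct    <- train_rf(halves$train,
                    feature_combo("color+texture", c(AP_COLOR_FEATURES, "CON")),
                    rf_config(300, seed = 2))
evaluate_model(m_color, halves$test)
evaluate_model(m_ct, halves$test)
```

```
<ap_report: n=180, accuracy 0.7667, macro recall 0.7667, macro F1 0.7665>
     pred
truth  I II III IV  V VI
  I   30  0   0  0  0  0
  II   0 25   5  0  0  0
  III  0  2  24  0  4  0
  IV   0  0   0 30  0  0
  V    0  0   1  1 15 13
  VI   0  0   1  1 14 14
<ap_report: n=180, accuracy 0.9722, macro recall 0.9722, macro F1 0.9722>
     pred
truth  I II III IV  V VI
  I   30  0   0  0  0  0
  II   0 27   3  0  0  0
  III  0  2  28  0  0  0
  IV   0  0   0 30  0  0
  V    0  0   0  0 30  0
  VI   0  0   0  0  0 30
```

Colour indices alone classify the vegetated states but scramble V and VI
(13 + 14 of 60 tiles crossed between them — they share a colour
distribution by construction); adding one texture feature resolves the
pair completely and lifts accuracy from 0.77 to 0.97. The attribution
summary says why — the texture feature dominates for classes V and VI:

```r
sh <- shap_summary(m_ct, halves$test)
round(sh$mean_abs[1:4, ], 3)
```

```
          I    II   III    IV     V    VI
CON   0.012 0.034 0.080 0.096 0.149 0.107
INT   0.022 0.044 0.098 0.116 0.061 0.072
NGBDI 0.028 0.075 0.032 0.024 0.020 0.030
RGBVI 0.031 0.030 0.015 0.012 0.013 0.016
```

A command-line front end covering `synth`, `tile`, `screen`, `train`,
`eval` and `run-all` ships at `inst/cli/agroprogress.R`.

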