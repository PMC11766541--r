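# standcount

Seedling-stage **plant stand counting** from UAV RGB field imagery, and the
downstream texture analysis that tells you how counting errors distort
cropping-pattern estimates.

Stand counts — established plants per unit area, assessed shortly after
emergence — feed replanting decisions and yield forecasts. `standcount`
implements the full pipeline for estimating them from orthomosaics by
semantic segmentation:

1. **Normalization** of imagery and point/box annotations to a common
   1 px = 1 cm grid (`normalize_scale()`, `infer_scale_from_rows()` when the
   ground sampling distance is unrecorded and must be recovered from known
   crop-row spacing);
2. **Disc masks**: plant centers rasterized as white discs of radius 4 cm on
   black background (`rasterize_centers()`), the training target convention;
3. **Segmentation**: a U-Net-style encoder–decoder with ResNet-family
   encoders (rn18/rn34/rn50), trained with the combined loss
   `DiceCE = BCE(p,t) + 1 − (2Σpt + ε)/(Σp + Σt + ε)` under Adam with a
   linearly decaying learning rate, flip/rotate/scale/photometric
   augmentation, best model by validation IoU (`build_model()`, `train()`,
   `predict_mask()`); the network and backpropagation are implemented in the
   package (RcppArmadillo), with gradients verified against finite
   differences;
4. **Counting**: 8-connected components of the predicted mask, area-filtered
   against noise, with centroids and contours (`extract_plants()`,
   `count_plants()`, `plant_density()`);
5. **Evaluation** on non-overlapping tiles: MAE, MAPE (divided by the
   *predicted* count, with a switch for the conventional form), Pearson r,
   Spearman r_s, pixel IoU (`count_metrics()`, `evaluate_masks()`);
6. **Texture**: GLCM mean/correlation and GLRM long-run/run-ratio over the
   8 unit directions on mask tiles, plus paired bias statistics (mean
   difference, OLS slope/intercept, correlation) between two markups
   (`texture_profile()`, `compare_markups()`).

Because no public orthomosaics with exhaustive per-plant ground truth can be
bundled, the package ships a **synthetic row-crop scene generator**
(`field_spec()`, `generate_field()`, `generate_dataset()`) producing
parallel-row fields with known centers, missing/touching plants, weeds, and
controllable annotation degradation (`degrade_annotations()`) — every stage
of the pipeline is testable offline from a seed.

## Worked example

```r
library(standcount)

# a 256 x 256 cm sugar-beet-like scene: rows 45 cm apart, plants ~20 cm in-row
spec  <- field_spec(256, 256, row_spacing_cm = 45, in_row_spacing_cm = 20)
scene <- generate_field(spec, seed = 1)
scene
#> <field_scene> 256 x 256 px, 81 plants, rows 45 cm (seed 1)

# count plants straight off the ground-truth mask: 78, not 81 — the default
# 5% touch_rate merges a few canopies, the undercount mode the texture
# analysis quantifies
count_plants(scene$truth_mask)
#> [1] 78
plant_density(count_plants(scene$truth_mask), area_m2 = 2.56^2)
#> [1] 119018.6

# train the bundled desk-scale pilot and evaluate on held-out scenes
bench <- pilot_benchmark(seed = 1)
bench$report
#> # A tibble: 1 × 6
#>     mae mape_pct pearson_r spearman_rs pixel_iou n_tiles
#>   <dbl>    <dbl>     <dbl>       <dbl>     <dbl>   <int>
#> 1 0.075    0.486     0.998       0.994     0.731      40
```

`bench$report` reads: across the 40 held-out 128-px tiles, predicted counts
are off by 0.075 plants on average (MAPE 0.49%), correlate with truth at
r = 0.998, and the predicted mask overlaps the 4-cm-disc ground truth at
IoU 0.73. `autoplot(bench$fit)` draws the learning curves;
`autoplot(bench$texture)` shows per-feature truth-vs-predicted texture
scatter with the identity and fitted bias lines.

A thin command-line front end over the same functions lives at
`inst/scripts/standcount.R` (`simulate`, `rasterize`, `count`, `evaluate`,
`texture`, `compare`, `run` with a YAML experiment manifest via
`read_experiment_config()` / `run_experiment()`).

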