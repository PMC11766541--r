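---
title: "Stand counting from UAV imagery: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stand counting from UAV imagery: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Seedling-stage stand counts — how many established plants a field carries per
unit area — drive replanting decisions, yield forecasts and the assessment of
sowing quality. Counting from UAV RGB orthomosaics replaces transect walks
with a per-pixel classification problem: at the seedling stage canopies are
small, green and mostly non-touching, so a semantic segmentation network can
mark plant locations and a connected-component pass can count them.

`standcount` implements that pipeline end to end, together with the
downstream question that motivates much of its design: *how do detection
errors distort cropping-pattern statistics* (second-order texture features of
the plant mask) that an agronomist might compute next?

## The common grid and the disc-mask convention

Everything operates at **1 px = 1 cm**. Orthomosaics with a known ground
sampling distance are resampled to this grid (`normalize_scale()`, bilinear
for imagery, nearest for masks so they stay two-valued); frames with no
recorded GSD can recover it from agronomy via `infer_scale_from_rows()`,
which projects plant centers onto the axis orthogonal to the principal row
direction and reads the dominant inter-row gap in pixels — knowing the
crop's row spacing in cm fixes the scale. The estimator needs at least two
detectable rows and ten centers; collinear or aperiodic point sets raise a
diagnostic error rather than returning a guess.

Training targets are **discs of radius 4 cm** around each plant center
(`rasterize_centers()`). A pixel belongs to a disc iff its center lies
within the radius — an unambiguous, testable set definition; overlapping
discs merge, out-of-canvas parts are clipped. Centers may come from manual
points or from bounding boxes (midpoints, `boxes_to_centers()`), the usual
route for harmonizing public box-labelled datasets.

Coordinates are `(x_cm, y_cm)` with origin at the top-left pixel corner,
x rightward and y downward; 1-based pixel `[i, j]` has center
`(j - 0.5, i - 0.5)`. All modules share this convention.

## The synthetic field generator

No suitable public orthomosaics with exhaustive per-plant ground truth can be
bundled, so the package generates its own scenes (`field_spec()`,
`generate_field()`): parallel rows at a configurable spacing (45/60/90 cm
regimes mirror sugar-beet vs potato practice), quasi-regular in-row placement
(Gaussian jitter, sd 10% of the in-row spacing along the row and 4% of the
row spacing across it), soft-edged green radial blobs with per-plant radius
and brightness variation over a brown soil field built from low-frequency
noise plus per-pixel speckle, optional off-row weed distractors, missing
plants (Bernoulli), and touching plants: a fraction `touch_rate` of plants is
cloned at an offset drawn uniformly in (0.8 r, 1.6 r), reproducing the
merged-contour failure mode that dominates counting error in dense fields.

The generator's job is to be *learnable and diagnostic*, not photorealistic:
plants are green-dominant blobs because color is the signal a small
CPU-trainable network can exploit; the soil has enough structure that the
classifier cannot win by thresholding brightness alone. What the scenes do
**not** emulate: perspective and stitching artifacts, shadows, radiometric
variation between flights, real weed morphology, growth-stage mixtures.
Passing the bundled benchmark therefore demonstrates that the pipeline's
machinery is correct and well-calibrated at desk scale — not that the tiny
pilot network would transfer to real orthomosaics.

Annotation degradation (`degrade_spec()`, `degrade_annotations()`) emulates
low-quality markup: center jitter, dropped plants, Poisson spurious centers,
and box-quantized centers. These knobs are free parameters — no quantitative
error model of crowd-sourced markup exists to calibrate them against — so
experiments treat them as controlled contrasts, not as estimates of any
particular dataset's quality.

## Segmentation model and training

`build_model()` constructs a U-Net-style encoder–decoder. The encoder
follows the ResNet family — `rn18`/`rn34` with basic blocks (depths
\[2,2,2,2\] / \[3,4,6,3\]), `rn50` with bottleneck blocks (expansion 4) — a
7×7/2 stem, 3×3/2 max-pool, and stride-2 stages, for a 32× downsampling: at
full width and 512 px tiles the rn18 bottleneck is 512 channels × 16 × 16.
The decoder upsamples (nearest, 2×) five times, concatenating the encoder
feature map of matching resolution at each step, and ends in a 3×3
convolution and a sigmoid, so the output is an H × W plant-probability map.
`width_multiplier` shrinks every stage proportionally; it and the tile size
are desk-scale knobs — (1.0, 512 px) reproduces the full architecture.

The network, backpropagation and the Adam optimizer are implemented in the
package (im2col convolutions over BLAS, batch normalization with running
statistics, max-pool argmax bookkeeping); gradients are verified against
finite differences in the test suite.

The loss is **DiceCE**: binary cross-entropy plus the Dice complement,

$$\mathcal{L} = \mathrm{BCE}(p, t) \;+\; 1 - \frac{2\sum p\,t + \varepsilon}
{\sum p + \sum t + \varepsilon}, \qquad \varepsilon = 1,$$

with sums over the whole batch. The CE term uses the binary formulation
(single-channel mask); ε = 1 is the standard smoothing choice. Two closed
forms anchor the tests: a perfect hard prediction gives ≈ 0, and a uniform
0.5 prediction on an empty target gives ln 2 + 1 − 1/(n/2 + 1) ≈ 1.693.

Training (`train()`) follows the reference protocol: Adam, batch size 8,
learning rate decreasing **linearly** from 1e-4 to 1e-6 over 100 epochs at
full scale, best model selected by validation IoU. Augmentation
(`augment()`) applies flips, rotation up to 90°, scale jitter up to 30%
(geometric transforms identical on image and mask, nearest resampling for
the mask), and brightness/contrast/gamma jitter on the image only.
Rotation samples with clamp-to-edge so no synthetic black corners enter
training.

Whole-image inference (`predict_mask()`) tiles the image with a default
64 px overlap, averages overlapping probabilities, then thresholds at 0.5.
The threshold and the mean-blending rule are package choices: probability
averaging suppresses seam artifacts that hard tile boundaries would
otherwise imprint on the counts.

## Counting and evaluation

`extract_plants()` labels maximal **8-connected** foreground components
(hand-written union-find; the labeling is checked exactly against a
brute-force flood fill on random images) and discards regions below
`min_area_px` as noise — default 10 px, about 20% of a radius-4 disc; the
threshold is exposed everywhere. Centroids are unweighted pixel-center
means; contours are Moore-neighbor boundary walks.

Agreement between two markups is quantified at pixel level (IoU; defined as
1 for two empty masks) and count level over non-overlapping tiles
(`tile_counts()`, 20 × 20 m = 2000 px grid at full scale, configurable for
desk-scale scenes): MAE, MAPE, Pearson r, Spearman r_s (average ranks for
ties). **MAPE divides by the predicted count** — the second series — which
is deliberate fidelity to the reference formula even though conventional
MAPE divides by the reference; `mape_denominator = "manual"` switches to the
conventional form, and a regression test guards the asymmetry against
well-meaning "fixes". Tiles with zero counts in both markups stay in MAE
but leave MAPE; zero predicted counts make MAPE `NA` with a warning rather
than infinite.

A region straddling a tile boundary is split by the crop and may be counted
in two tiles; tile sums can therefore exceed the whole-scene count by the
number of straddlers. This is documented behavior, shared by any tile-wise
evaluation.

## Texture features

Cropping-pattern statistics are computed on the masks, not the imagery:
GLCM (co-occurrence) and GLRM (run-length) matrices over the **8 unit
directions** — left, right, up, down and the four diagonals — on
non-overlapping tiles (1000 × 1000 px at full scale). Four features are
kept: GLCM mean, GLCM correlation, GLRM long-run emphasis
(Σ R[g,l]·l² / n_runs) and run ratio (n_runs / n_pixels, the Galloway run
percentage). Choices the reference text leaves open, decided here:

* gray levels are the native pixel values (\{0, 255\} for masks), not
  re-quantized — a 0–255 scale is what makes sparse binary masks yield
  GLCM means in the tens rather than hundredths;
* features are averaged arithmetically over the 8 directions (vs
  concatenation); since opposite displacements are both in the set, the
  average is symmetric without per-matrix symmetrization;
* constant tiles have undefined GLCM correlation — reported `NA`, never 0 —
  and are dropped pairwise from comparisons with a count;
* the paired test is a two-sided t-test by default, Wilcoxon signed-rank as
  an option (the reference analysis reports significance without naming the
  test);
* the bias regression is unweighted OLS of the compared markup on the
  reference markup (reference on the x axis).

Both matrix constructions are verified exactly against exhaustive
enumeration oracles on random tiles.

Two mechanism-level predictions are tested and also recomputed by the
acceptance script: denser rows (45 vs 90 cm at equal plant size) raise the
GLCM mean, and merged touching plants inflate the long-run emphasis — the
two effects through which detection errors distort cropping-pattern
estimates.

## The bundled benchmark and problem sizes

`pilot_benchmark()` fixes one desk-scale protocol: 3 row-spacing regimes ×
17 scenes of 256 × 256 px (1 px = 1 cm), cut into 128 px tiles (≈ 200
training tiles after the scene-disjoint 60/20/20 split), an rn18 encoder at
width 0.25, 6 epochs of Adam with the learning rate linear from 1e-3 to
1e-5, batch 8, full augmentation. The higher starting rate than the
full-scale protocol reflects the from-scratch initialization and the short
schedule — with ~150 optimizer steps, 1e-4 would leave the schedule mostly
unused. Scene sizes and epoch counts were chosen so a full
simulate–train–predict–count–evaluate–texture cycle completes in minutes on
one CPU; validation IoU on this benchmark typically reaches ≈ 0.6 and
held-out count agreement r > 0.99 with MAPE well under 5%.

Held-out evaluation uses 128 px count tiles. The three spacing regimes give
per-tile true counts ranging from ~4 to ~20, so the count correlation is
measured across genuine density variation, as it is across fields of
different crops at full scale.

## Numerical choices and degenerate inputs

* Disc rasterization: pixel-center-in-circle; ties (distance exactly r)
  are inside.
* Mask resampling is always nearest; masks remain exactly two-valued
  through every transform.
* Probabilities are clamped to \[1e-7, 1 − 1e-7\] inside the CE term only;
  the Dice term uses raw probabilities.
* Batch-norm uses momentum 0.1 running statistics and eps 1e-5; evaluation
  always uses running statistics.
* Weights are He-initialized; the output head's bias starts at −3 (sigmoid
  ≈ 0.05), the foreground prior of disc masks. Without this, sparse-target
  Dice training can spend several epochs collapsed to all-background before
  recovering — a known instability of from-scratch segmentation on rare
  foreground.
* Empty masks: zero count, all-zero profiles, IoU 1 against another empty
  mask; empty annotations rasterize to all-background.
* Degenerate boxes (zero area) yield their corner as center, with a
  warning; inverted boxes are errors.
* `train()` aborts with the epoch index if the loss becomes non-finite.
* All randomness flows through explicit integer seeds; identical
  (spec, seed) pairs produce byte-identical scenes, and training repeats
  bit-for-bit on a single CPU with fixed seeds.

## Known limitations

* The pilot network is ~30× narrower than the full-scale model and is
  trained for 6 epochs, not 100; its IoU (≈ 0.6 on synthetic discs) says
  nothing quantitative about real-field IoU, where ~0.3–0.4 against
  4-cm-disc ground truth is typical because predicted blobs and fixed-radius
  discs overlap only partially even for perfect detection.
* Counting by segmentation undercounts wherever canopies merge; the package
  reproduces and measures this failure mode but, by design, does not try to
  split merged regions (no watershed/marker postprocessing).
* `infer_scale_from_rows()` assumes a single dominant row direction and
  near-constant spacing; orchards on curved terraces or double-row planting
  patterns will defeat it.
* GeoTIFF georeferencing is carried as an opaque tag, never interpreted; no
  reprojection is attempted.
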