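---
title: "Two-stage whale surveys in VHR ocean imagery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-stage whale surveys in VHR ocean imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(whalescan)
```

## The survey problem and the cascade

A coastal survey scene at 0.15–1.5 m/pixel is tiled into square grid
cells of 71 m — twice the length of the largest whales (blue whales reach
30 m), so any individual fits entirely within at least one cell. Whale
cells are rare (well under 1% in realistic surveys), and the confusers
that dominate false positives — ships, wave foam around submerged rocks,
sun glint — are common. `whalescan` therefore splits the survey in two:

1. a three-class **presence classifier** (whale / ship / water + submerged
   rocks) scores every cell and passes only cells with predicted whale
   presence;
2. a **detector** localises whales with scored boxes in the passed cells;
   the count is the number of boxes retained after non-maximum
   suppression (NMS).

The split buys two things. Detection is roughly an order of magnitude
more expensive per cell than classification, so filtering first makes
large surveys tractable (the package records detector invocations in
every report; in cascade mode they never exceed the number of cells and
in practice cover a small fraction of them). And because the detector is
trained on whales-plus-background imagery only — the composition such
training sets actually have — it has never seen a ship or a foam ring;
run alone it converts them into false positives, which is exactly what
the three-class filter removes. `runBaseline()` measures that effect.

## Coordinate and labelling conventions

Pixel coordinates have their origin at the top-left corner, x rightward,
y downward, with half-open intervals; metric bounds are pixel bounds
times the pixel size, with a one-pixel tolerance on the nominal cell
size. A ground-truth box belongs to exactly one cell: the cell containing
its centre (this prevents whales straddling a border from being counted
twice). Cell labels follow the priority whale > ship > water + submerged
rocks. Edge cells are padded by mirror reflection by default — zero
padding would create artificial dark borders the classifier would learn.

## The synthetic-scene generator

The imagery that motivates this pipeline is not redistributable, so the
package generates annotated ocean scenes: a clean object layer (whale
bodies, blow plumes, ship hulls and wakes, rock cores with foam rings) is
composed with a water base, low-frequency wave texture scaled by a sea
state in [0, 1], and sparse blurred sun-glint specks. The clean layer and
a per-object mask are returned with every scene, which is what makes
oracle-style tests possible (connected components of the clean layer
recover the placed objects exactly; annotation boxes are tight mask
bounding boxes by construction).

Whale appearance is controlled per posture (`posturePresets()`):

| posture    | body contrast | visible fraction | plume |
|------------|---------------|------------------|-------|
| breaching  | 0.20–0.35     | 0.8              | yes   |
| blowing    | 0.15–0.30     | 1.0              | yes   |
| peduncle   | 0.12–0.25     | 0.6              | no    |
| logging    | 0.10–0.25     | 1.0              | no    |
| spyhopping | 0.08–0.16     | 0.25 (head only) | no    |
| submerged  | 0.02–0.10     | 0 (faint body)   | no    |

Contrast is relative luminance against the water base; plumes add a
bright blob of contrast 0.5–0.7. These bands were chosen once so that
surface-active postures are conspicuous and submerged bodies sit at the
edge of the wave-texture noise (sd ≈ 0.01 at the default sea state 0.3) —
the gradient that drives the posture-stratified detectability analysis.
The default posture mix (logging 0.40, submerged 0.34, peduncle 0.08,
blowing 0.07, spyhopping 0.06, breaching 0.05) is weighted towards the
passive postures that dominate real breeding-season surveys. Whale
lengths are drawn from 5–30 m; ships are 12–45 m rectangles with wakes;
rocks are 2.5–8 m dark cores inside bright foam annuli. Pixel sizes are
drawn from the grid {0.15, 0.31, 0.46, 0.61, 1.5} m, the resolutions of
the satellite and aerial sensors such surveys actually mix.

What the generator does **not** emulate: cloud and haze occlusion, sea
states beyond simple stationary texture, mother–calf overlapping pairs,
and the full visual diversity of real hulls and coastlines. Passing tests
therefore demonstrate that the pipeline's mechanics are correct and that
its qualitative behaviour (confuser filtering, posture gradients) emerges
under controlled conditions — not that the shipped tiny models would
reach field accuracy on real imagery.

Classification patches come in two styles. `style = "cells"` (default)
crops each patch as a window from a larger rendered mini-scene and labels
it by the same centre rule used for survey cells, so patches contain
partial foam arcs, hull bows and whale flukes overhanging the border —
what deployed cells actually look like. `style = "curated"` renders the
labelling object fully visible, emulating training sets assembled from
photo libraries. Training on cell-style patches proved necessary for the
classifier to transfer to tiled scenes: models trained only on
object-centred patches misread cells crossed by partial confusers.

## Models and training

Both stages share one architecture, chosen for desk-scale verifiability:
a **fixed, seeded convolutional filter bank** (eight 5×5 zero-mean
filters on a 32×32 input, mean- and max-pooled 4×4), concatenated with
pooled raw intensities and a small set of luminance-anomaly statistics
computed at the patch's native resolution (departure from a blurred
background at two scales, plus the area, elongation, contrast and
bounding-box fill of the dominant bright and dark blobs — elongated
bright blobs are whales, round dark cores in bright rings are rocks).
Features are standardised with moments fitted on the training split. The
trainable part is a fully connected stack whose **last two parameter
groups** are updated — the transfer-learning recipe of retraining only
the final fully connected layers on a frozen backbone.

The optimiser is RMSProp with momentum 0.9 and squared-gradient decay
0.9, at an initial learning rate of 0.001 divided by a decay factor of 16
every 30 epochs (`lrSchedule()` exposes the closed form). The recipe's
stated epsilon of 0.1 is unusually large; it is the shipped default,
implemented as written, but at desk scale it throttles the effective step
size so severely that the small heads barely move in 30 epochs. The
package therefore documents `epsilon` as a tuning override, and the
shipped experiments and calibrated fixtures train with `epsilon = 1e-3`,
which converges within the same schedule. Batches are class-balanced
(size 16 by default; the deployment prior of >90% water cells would
otherwise swamp the whale class), and the classifier is additionally
regularised by the augmentation recipe below (two augmented copies per
training patch by default in the experiment harness).

The detector is a two-part design with an architecture-agnostic contract
(boxes + scores out): **proposals** are connected components of the
thresholded anomaly map |luminance − blur(luminance, 6 px)| > 0.05, with
components under 6 px discarded; a **verifier** head (whale vs
background, same feature machinery) scores each candidate crop, enlarged
by a 20% margin. Training positives are the annotated boxes; negatives
are random background crops plus proposal-stage false alarms (hard
negatives). The 0.05 contrast floor sits deliberately inside the
submerged-whale contrast band (0.02–0.10): low-contrast bodies are often
never proposed, which is the realistic failure mode for submerged
animals. Both models are deterministic given their seed under
single-threaded execution, and checkpoints archive config, class map,
seed and weights in a single file.

Plug-in models: `classifyCell()` and `detectWhales()` also accept plain
functions, so a heavier external model can replace either stage without
touching the orchestration (thresholding and NMS still apply).

## Augmentation

The training-time recipe: rotation by an angle drawn from [0°, 360°]
(reflection fill, consistent with cell padding), horizontal flip with
probability 0.5, random crop retaining at least 70% of the area then
resized back, isotropic rescale in [0.75, 1.25], and a brightness
multiplier drawn from [1 − f, 1 + f] with f = 0.5, clamped to the valid
range. Boxes ride through every geometric transform (corners mapped,
axis-aligned hull, clipped) and are dropped with a warning when less than
25% of their original area stays visible — degenerate slivers make bad
detector targets. The crop fraction, scale bounds and drop threshold are
package choices; the identity configuration is exactly pixel-preserving,
which the tests use as an anchor.

## Evaluation

Cell-level performance uses the three-class confusion matrix (rows =
photo-interpreted truth, columns = prediction) with positive predictive
value, sensitivity and F1 per class; 0/0 ratios are defined as 0 so empty
classes yield zero metrics rather than NaN. Percentages are **truncated**
at two decimals, matching the convention in published survey tables
(14/68 prints as 20.58, not 20.59). Whale-level counting is evaluated by
IoU matching of merged detections to ground-truth boxes — greedy in
descending score order by default, with an optimal maximum-bipartite
matcher available as a cross-check (the tests verify greedy ≤ optimal and
optimal against exhaustive enumeration on small instances). Stage-1
cell-level F1 and end-to-end whale-level F1 are reported separately and
never combined into a single figure. Cross-validation uses stratified
k-folds (k = 5 conventionally) with per-fold macro-F1 summarised as mean
± sd.

## The shipped experiment and its scale

`runCascadeExperiment()` fixes the study conditions: 40 scenes of 5×3
cells (600 cells) at 1 m/pixel; whales per scene ~ Poisson(0.8) (~5%
whale-cell prevalence), ships ~ Poisson(0.7), rocks ~ Poisson(1.5);
stage-1 trained on 150 cell-style patches per class and stage-2 on 120
detection images at the survey resolution, 30 epochs each, with the
epsilon override and ×2 augmentation. One replicate runs in about a
minute on one CPU; the acceptance script runs three replicates seeded
from its `--seed`. Under these conditions the cascade consistently beats
the detector-alone baseline on end-to-end counting F1 (gains of roughly
+6 to +15 points across seeds) with several-fold fewer false positives —
the qualitative mechanism behind the large published improvements of
two-step surveys, at a fraction of their scale. The absolute F1 values
(roughly 25–50%) are not comparable to field systems: the models are
deliberately tiny and a third of synthetic whales are near-invisible
submerged bodies.

## Numerical choices and degenerate inputs

- Cell pixel extent is `round(cell_size_m / pixel_size)`; the metric
  invariant holds to one pixel.
- Object placement rejects candidate positions whose padded boxes overlap
  existing objects with IoU > 0.05 and fails with an error after a
  bounded number of attempts (200 by default); the patch builders degrade
  by dropping optional confusers before giving up.
- NMS breaks score ties by input order; it is idempotent, and raising the
  score threshold can only shrink the detection set.
- Cross-cell merging is a global NMS in scene coordinates (IoU 0.5 by
  default); each surviving box keeps the cell it was detected in, so
  per-cell counts sum exactly to the merged total.
- The presence rule is configurable: `argmax` (default) or
  `p_whale ≥ τ` with τ = 0.5 by default; τ = 0 under the threshold rule
  reduces the cascade to the baseline exactly.
- Empty scenes, cells without detections, images without boxes and
  all-background training images are all legal inputs with defined
  results.

## Known limitations

GeoTIFF geotransforms are not parsed (no GDAL binding is required by the
package); pixel size and origin come from JSON sidecars or arguments, and
TIFF pixel data is read when the `tiff` package is present. The fixed
filter bank is not fine-tuned end to end; the `head_only = FALSE` mode
trains all fully connected groups but never the convolutional features.
The detector's recall ceiling is set by the proposal stage: objects below
the contrast floor are invisible to it regardless of the verifier. These
are deliberate trade-offs to keep the reference models trainable in
minutes while leaving the contracts open to heavier plug-in backbones.
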