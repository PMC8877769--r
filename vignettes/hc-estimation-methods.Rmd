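---
title: "Methods: segmentation-based and regression-based head-circumference estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: segmentation-based and regression-based head-circumference estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fetalhc)
```

## The problem

Fetal head circumference (HC) is a standard biometric measured from 2-D
ultrasound: a sonographer traces the skull and fits an ellipse, and the HC is
the length of that ellipse in millimetres. `fetalhc` implements and compares
the two automatic routes to this biomarker:

* **Segmentation route** — a network segments the head region, the mask is
  post-processed (Canny edge detection, then keeping the largest connected
  component), an ellipse is fitted to the surviving contour points, and the
  perimeter of the physical ellipse is computed.
* **Regression route** — a network maps the image directly to a single scalar,
  the normalized HC, with no intermediate mask.

Because clinical ultrasound data cannot ship with a package, everything is
developed and tested against a synthetic phantom generator whose ground truth
is known *analytically*, so that every stage of both routes can be validated
against exact values.

## Geometry

An ellipse is parameterized by center $(c_x, c_y)$, semi-axes $a \ge b > 0$,
and the major-axis orientation $\theta \in [0, 180)$ degrees measured from the
+x axis. Image coordinates are x right, y down, 0-based, with pixel centers at
integer coordinates; this convention is used everywhere, and $\theta = 0$ is
reported for circles by convention (comparisons on near-circular ellipses must
not assert $\theta$).

The perimeter is computed with the Ramanujan approximation
$$ h = \frac{(a-b)^2}{(a+b)^2}, \qquad
   P \approx \pi (a + b) \left( 1 + \frac{3h}{10 + \sqrt{4 - 3h}} \right), $$
whose relative error against the exact elliptic-integral perimeter
(`exact_perimeter()`, adaptive quadrature of
$4\int_0^{\pi/2}\sqrt{a^2\sin^2 t + b^2\cos^2 t}\,dt$) is below $10^{-6}$ for
axis ratios $b/a \ge 0.2$ — far below every other error source in the
pipeline. The phantom generator deliberately uses the *exact* perimeter as
ground truth so that the Ramanujan approximation error remains measurable
instead of cancelling out.

Ellipse fitting uses the direct least-squares conic fit with the
ellipse-specific constraint $4AC - B^2 = 1$ (Fitzgibbon's constraint in the
numerically stabilized Halir–Flusser formulation), preceded by centering and
isotropic scaling of the points. It is deterministic, closed-form, and exact
to $\sim 10^{-7}$ pixels on noiseless samples. Distinct error codes separate
too-few-points, degenerate (collinear/coincident) input, and non-elliptical
solutions.

Analysis-resolution masks are mapped back to the original grid by
`rescale_ellipse()`, which pushes the ellipse's quadratic form through the
exact diagonal map $\mathrm{diag}(f_x, f_y)$ rather than approximating the HC
by a mean scale factor; the same mechanism handles anisotropic pixel spacing
in `hc_mm()`.

## Post-processing

Raw segmentation maps are thresholded at 0.5 (the $\ge$ convention),
edge-detected with a Canny filter (Gaussian blur $\sigma = 1$ px, Sobel
gradients, non-maximum suppression, hysteresis at 100/200 on the 0–255
scale — on a binary mask any mid-range pair is equivalent; the pair is frozen
for reproducibility), and reduced to the largest 8-connected edge component
(ties broken by the smallest row-major pixel). Edges are detected *first* and
the component filter is applied to the edge map; interior hole edges then form
separate, smaller components and are discarded without any explicit hole
filling.

Retained edge pixels are localized to subpixel accuracy by parabolic
interpolation of the gradient magnitude along the gradient direction. This is
the one numerically load-bearing choice in the chain: integer edge
coordinates carry a half-pixel quantization plus a curvature-dependent inward
bias that grows as $\sigma^2 a / b^2$ at the major-axis ends, which for small
eccentric heads ($a \approx 20$ px) exceeds 1% of the HC. With subpixel
localization the full oracle pipeline (ground-truth mask in, HC out) recovers
the analytic HC to within 0.6% per image, which bounds the error floor the
segmentation network inherits.

## Evaluation metrics

Dice is computed on filled regions, $2|S \cap G| / (|S| + |G|)$ (1 when both
are empty); Hausdorff and average symmetric surface distance are computed on
contour point sets after scaling each coordinate axis by its pixel spacing,
so all distances are in mm. HC error is reported as MAE (mm) and PMAE, the
*per-case* percentage error averaged over cases. Choosing filled regions for
Dice and contours for the surface distances follows how these metrics are
conventionally reported for this task: near-99% Dice values are plausible
only for filled regions, while surface distances are defined between
contours.

## Agreement analysis

Differences are **predicted − reference**, so a negative bias means
underestimation. Bland–Altman limits use the conventional
$\text{bias} \pm 1.96\,s$ with the sample ($n-1$) standard deviation, and the
outlier count is the number of points strictly outside the limits. Agreement
regression is OLS of predictions on reference values with $r^2$ the squared
Pearson correlation. Two methods are compared by a two-sided paired Student
t-test on their error lists, with frozen degenerate conventions: all-zero
differences give $p = 1$; constant nonzero differences (infinite t) give
$p = 0$. The test's type-I error is verified by Monte-Carlo calibration in
the acceptance suite (10,000 null replicates, n = 30, rejection rate required
to lie in [0.03, 0.07] at $\alpha = 0.05$).

## Synthetic phantoms

Each phantom is an 8-bit grayscale image containing a bright elliptical
skull band (default full thickness 3 px along the minor axis) with

* uniform geometry: semi-major axis 0.16–0.30 of the frame size, axis ratio
  0.6–0.95, free orientation, jittered center, a 4 px margin guaranteed;
* missing angular segments (default 2 gaps totalling 15% of the parametric
  angle) emulating the fuzzy/missing borders of real skull contours;
* background clutter blobs and multiplicative speckle-like noise (smoothed
  Gaussian field, amplitude 0.25);
* a per-image isotropic pixel spacing in 0.05–0.3 mm/px.

Ground truth (filled mask, band mask, exact ellipse, spacing, analytic HC) is
independent of all corruption. Everything is deterministic per seed, and
generation never disturbs the caller's RNG stream.

**Spacing model.** If the pixel spacing were sampled independently of the
rendered geometry, the physical HC would be fundamentally unidentifiable from
the image alone and no regression network could work even in principle. In
clinical practice the sonographer adjusts the imaging depth to the fetal
head, which couples pixel size to head size. The generator emulates this:
spacing is placed log-uniformly across its range through a monotone link to
the phantom's pixel-domain perimeter, plus Gaussian jitter (sd 0.04 on the
unit interval) for operator variability. The jitter puts a floor of roughly
5–6% PMAE on any image-only HC predictor, which is deliberately far above the
segmentation route's 0.1–0.6% floor: the phantoms preserve the qualitative
ordering between the two routes that motivates the comparison.

**What the phantoms do not model:** beam physics, shadowing, anatomical
structure beyond the skull ellipse, operator framing variation, and real
annotation noise. Passing tests therefore validate the *pipeline* —
geometry, post-processing, metrics, optimization — not clinical performance;
numbers obtained on phantoms (especially the regression route's PMAE) do not
transfer to real ultrasound. With a 128 px frame and the fixed 0.05–0.3 mm/px
spacing range, phantom HC values span roughly 3–70 mm, smaller than the
clinical 60–350 mm range but spanning a comparable relative spread.

## Protocol

The canonical dataset protocol mirrors the challenge layout: 999 images with
an annotation CSV (filename, pixel size, HC), split 600/199/200 by a seeded
permutation. Training-set augmentation emits exactly three records per
original — identity, horizontal flip ($c_x \to W - 1 - c_x$,
$\theta \to 180 - \theta$), and a single +10° rotation about the image center
(exact ellipse transform; bilinear resampling for images, nearest for
masks) — so 600 becomes 1800. Both operations leave the reference HC exactly
unchanged. A rotation that pushes the band outside the frame clips the
content, fills with the border median, and warns. Cross-validation uses
seeded k-fold indices with larger folds first (999 cases in 5 folds give test
folds 200/200/200/200/199); the same fold object serves both routes.

## Models and training

No deep-learning framework is assumed: the package carries a compact,
fully-tested convolutional engine (im2col convolutions, 2×2 max-pooling,
nearest-neighbor upsampling, skip concatenation, global average pooling,
inverted dropout, Adam). Every layer's backward pass is verified against
numerical differentiation in the unit tests.

* `build_tiny_segnet()` — a U-shaped encoder–decoder (3×3 conv + ReLU +
  pool per level, bottleneck, upsample + skip-concat + conv per decoder
  level, 1×1 sigmoid head), trained with the smoothed soft-Dice loss
  (constant 1 in numerator and denominator).
* `build_tiny_regnet()` — a conv stack (3×3 conv + batch norm + ReLU + pool
  per level), global average pooling, dropout keeping `dropout_keep` of the
  feature units, and one linear output predicting HC normalized by the
  maximum training-split HC. The output bias starts at 0.5, the mid-range of
  the normalized target. Losses: MAE, MSE, or Huber
  ($e^2/2$ below $\delta$, $\delta(|e| - \delta/2)$ above, continuous at
  $|e| = \delta$; default $\delta = 1$). Batch normalization (per-channel,
  batch statistics at train time, running averages at prediction time) is
  what makes the few hundred gradient steps of a desk-scale run sufficient:
  without it the same network plateaus at a 2× higher validation error.

The reference protocol configuration is Adam at learning rate $10^{-4}$,
batch 16, 100 epochs, dropout keeping 30% of units. Desk-scale runs (tests,
the experiment runner) use learning rate $10^{-3}$–$2\times10^{-3}$, 15–30
epochs, and `dropout_keep = 0.9`: with only tens-to-hundreds of gradient
steps the protocol learning rate cannot move a freshly initialized network,
and aggressive dropout is counterproductive at this parameter count. The
trainer anneals the learning rate with a cosine schedule to zero over the
configured epochs, which stabilizes the final-epoch model at these small
step budgets. Training is bit-deterministic given the seed.

Two depths are used by default (`experiment_config()`): depth 3 for the
segmentation network and depth 5 for the regression network. The regression
task needs the deeper stack: predicting a global size requires final-layer
cells whose receptive field covers the whole head; at depth 3 the pooled
features remain essentially local band-area statistics and the network
plateaus at a 2–3× higher error. Input images are resized to 64×64 and
standardized per image (dataset-level statistics would leak across splits
and complicate single-image prediction).

Failed segmentations (post-processing yields fewer than 5 contour points, or
the fit is degenerate) are reported as failed predictions, excluded from
error aggregates, and counted in every report.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use: 999 phantoms for protocol
counts; 200 phantoms for oracle-route recovery; a 50×50 grid for formula
fidelity; 10,000 replicates for t-test calibration; 60 phantoms / 15 epochs
for the segmentation training check and 200 phantoms (160 train, augmented
×3, 40 validation) / 30 epochs for the regression training check; and an
80-image, 2-fold experiment for the route comparison. These sizes were chosen
so the whole suite runs on a single CPU in minutes while leaving each check
statistically meaningful.

Other frozen choices: binarization threshold 0.5 with the $\ge$ convention;
8-connectivity with the row-major tie-break; Canny $\sigma = 1$ with
hysteresis 100/200; quadrature tolerance $10^{-12}$; subpixel offsets clamped
to $\pm 1$ px; component labeling via an undirected pixel-adjacency graph.

## Known limitations

* The miniature networks are CPU-scale stand-ins: the pipeline API is
  backbone-agnostic, but no transfer learning or full-size architecture is
  included, and phantom results say nothing about clinical accuracy.
* The regression route's PMAE on phantoms carries the spacing-jitter floor
  (~5–6%) by construction.
* Surface metrics assume single closed contours; multi-object scenes are out
  of scope.
* Bland–Altman limits are reported without confidence intervals on the
  limits themselves.
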