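---
title: "Segmenting the exposed brain surface and fusing tissue probabilities: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Segmenting the exposed brain surface and fusing tissue probabilities: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(cortexfuse)
```

## The problem

Intraoperative hyperspectral (HSI) tissue classifiers for brain-tumor
surgery work pixel by pixel on 25-band near-infrared cubes and are trained
on sparse expert annotations. Their most damaging failure mode is
confusing non-healthy classes with one another -- typically calling
cortical blood vessels "tumor" or mixing dura mater into everything.
`cortexfuse` implements a two-part remedy:

1. a **weakly supervised segmentation network** that delineates the
   exposed brain surface (cortex) and its cortical vessels, trained
   almost entirely on automatically generated pseudo-labels, transferring
   from high-resolution RGB scenes to the HSI domain; and
2. a **probability fusion rule** that combines the cortex mask
   $P_{ctx}$, the vessel mask $P_{vsl}$ and the four-class output of any
   tissue classifier $P_{clf} = (P_h, P_t, P_v, P_d)$ into a refined
   four-class map, reducing the classifier's job to healthy vs.
   non-healthy:

$$Q_{clf} = \mathrm{softmax}([P_h,\ \max\{P_t, P_v, P_d\}])$$
$$P_{out} = [\,Q_{clf}\cdot(1 - P_{vsl})\cdot P_{ctx},\ \
P_{vsl}\cdot P_{ctx},\ \ 1 - P_{ctx}\,]$$

with output slots (healthy, tumor, vessel, background). The vessel
probability survives fusion untouched wherever the cortex is active
(slot 3 is exactly $P_{vsl} P_{ctx}$), anything outside the cortex
becomes background, and the four components sum to one by algebra. The
softmax is applied to probabilities, as defined -- this compresses the
healthy/non-healthy contrast relative to a logit softmax and slightly
miscalibrates $Q_{clf}$, which is accepted since only the ranking enters
the final argmax.

## Instrument model

The snapshot-mosaic camera tiles a 1085 x 2045 sensor with a repeating
5 x 5 filter pattern covering 25 bands between 665 and 960 nm;
demosaicking rearranges each frame into a 25 x 217 x 409 cube. The band
order within a tile is row-major with band 0 at the top left -- the
vendor does not publish the layout, so the package fixes this convention
and uses the same convention in the synthetic inverse, making
`demosaic()` and `mosaic_frame()` exact inverses. Reflectance is
`(raw - dark) / (white - dark)` against a white/dark reference pair
(divisor clamped at 1e-6, output clamped at 0 but *not* at 1; histogram
equalization and min-max normalization downstream are scale-free). The
vendor's spectral cross-talk correction matrix is an input and is applied
after white/dark calibration. Only three band centers are documented
(band 4 at 712.4 nm, band 20 at 913.7 nm, band 23 at 940.9 nm);
`snapshot_wavelengths()` interpolates the rest piecewise-linearly through
those anchors.

Pseudo-RGB reconstruction uses band 4 for red (the only band in visible
red) and approximates green and blue by second harmonics: half of
940.9 nm is 470.5 nm and half of 913.7 nm is 456.9 nm (rounding half-up
to 0.1 nm). `select_rgb_bands_by_harmonic()` implements the generic
rule -- first band at or past the red target, then the bands whose
harmonics fall nearest the green and blue ranges, assigned greedily
without reuse. On a monotone synthetic wavelength grid this rule cannot
single out the camera's documented green/blue choice (every long band's
harmonic lands in or near blue, so "nearest" degenerates); the
documented instrument assignment (bands 4, 23, 20) is therefore shipped
as the constant `camera_prgb_bands()` and used as the `reconstruct_prgb()`
default, while the rule remains available for arbitrary wavelength
tables.

## Synthetic scenes

No clinical data ship with the package; every pipeline stage is exercised
on synthetic craniotomy scenes (`generate_scene()`). Geometry is
analytic -- a polar-harmonic star-shaped cortex blob (area fraction drawn
from 12-22% of the frame), a dura ring around it, a tumor blob inside,
and quadratic Bezier vessel strokes with widths uniform in 1-8 HSI
pixels -- and is rasterized at both the RGB and HSI resolutions so the two
modalities share the exact same anatomy. Spectra are per-class 25-band
signatures modulated by a smooth illumination field plus Gaussian noise;
the vessel signature sits at least 0.15 below cortex in every band so
vessels stay darker than cortex by at least three noise standard
deviations (the generator rejects `noise_sd > 0.04` to preserve that
margin, the one assumption the vessel detector relies on). The raw
mosaic frame is the inverse-demosaicked synthetic radiance, so the
preprocessing chain round-trips bit-exactly.

What the scenes deliberately do not model: specular glare, blood pooling,
surgical instruments, depth parallax between the RGB and HSI viewpoints,
and photorealistic texture. Passing tests on these scenes therefore
validates the algorithms' mechanics and their interplay, not clinical
performance.

Sparse ground truth mimics the semi-automatic annotation tool by labeling
a few compact blobs per class (~30% of each class's area by default, with
zero label noise). Weak cortex annotations are square patches sampled
fully inside the cortex. A controllable flawed classifier
(`generate_flawed_probs()`) draws each pixel's predicted class from a
confusion-matrix row of its true class, which lets the fusion stage be
tested against precisely dosed vessel-to-tumor confusion.

## Pseudo-label generation

**Cortex refinement** (`refine_cortex_annotation()`). The image is
clustered by K-means in Lab color space (k = 12 by default, fit on a
20,000-pixel subsample, assignment of all pixels by nearest centroid).
Clusters present inside the patch annotation are the annotated tissue;
the darker of them are vessel-like. Growth absorbs 4-connected regions
of admissible clusters that touch the annotation *and contain vessel-like
pixels* -- vessels mediate the propagation, which also yields the right
degenerate behavior: on a uniform image nothing is vessel-like and the
refinement returns the closed patch mask. Admissibility ("cortex-like")
is a centroid distance below 3x the mean RMS color spread of the
annotated clusters; this spread-relative threshold proved far more
stable than a quantile of pairwise centroid distances, whose value
depends on how many clusters the large drape background happens to
consume. A bimodality guard 2-means each annotated cluster and rejects
the half that carries no annotation when the sub-centroids separate by
more than 3x the within-half spread (this catches rare merges of tumor
with dura when the background starves the clustering). Clustering runs
on a copy downscaled to a 512-px longest side; the result is restored to
full resolution, closed, hole-filled, and unioned with the closing of
the input mask so growth is monotone.

**Perimeter approximation** (`approximate_perimeter()`). Canny edges
(hysteresis thresholds at 0.66/1.33 of the median gradient magnitude,
edges shorter than 15 px dropped) are searched in the band between the
5%-eroded and 10%-dilated mask (fractions of the equivalent-circle
diameter). SLIC superpixels (~400, compactness 10) grow outward from
the eroded mask, stopping at superpixels that contain a retained edge or
leave the band; the contour is the retained in-band edges within 3 px of
the grown region. The tight adjacency radius matters: the dura ring's
outer rim produces a second, parallel edge inside the search band, and a
generous radius would sweep it in.

**Vessel pseudo-labels** (`detect_vessels()`). A bank of 2 x 12 oriented
line kernels (two sizes; 15-degree angular steps; zero-mean normalized
lines) is correlated with the inverted grayscale image; the per-pixel
response is the max over the bank, thresholded at the 0.90 response
quantile, small components removed. Defaults: kernels 7/15 px with a
40 px minimum component at RGB resolution, 5/11 px and 10 px at HSI
resolution (vessel widths are 1-8 px at HSI scale), grayscale source =
calibrated band 4 for HSI. An alternative response normalization
(dividing by the local intensity standard deviation) is available via
`response_type = "local_std"` since the upstream line-operator literature
is ambiguous on this point.

**Ground-truth densification and the adjusted GT.** Each sparse class is
closed with an 11 x 11 elliptical element; pixels claimed by two classes
revert to unlabeled and original labels are never removed. Background
complementation clusters the cube's band vectors (k = 12) and takes the 8
clusters most distant from the mean cortical-labeled spectrum as a
background mask. The three-way adjusted GT for fine-tuning is: *inner* =
filled concave hull of the cortical labels (healthy, tumor, vessel),
*outer* = dura and background minus inner, *unknown* = the rest.

**Concave hulls.** Computed by iterative edge digging on the convex
hull: an edge splits toward its nearest interior point when its length
exceeds `concavity` (= 2) times that distance. Boundary points are
subsampled to 150 and sub-8-px speckles are dropped before hulling --
hulls act as detached geometric targets, so this costs nothing in
gradient fidelity and keeps the shape losses fast on noisy
early-training masks.

## Network and losses

The segmentation network is a dual-input encoder-decoder ResNet.
RGB images enter a ResNet-C style stem (stride-2 3x3 convolution plus
two 3x3 convolutions); HSI cubes first pass a spectral stem of three
*valid* 3x3 convolutions tapering 25 -> 16 -> 8 -> 3 channels (batch norm +
leaky ReLU, slope 0.01), after reflect-padding the input by the 3-pixel
total margin so the stem output keeps the input resolution -- this
reconciles "valid" convolution arithmetic with the requirement that
outputs match the input size. The encoder stacks 14 ResNet-B residual
blocks in three stages (4/4/6 by default; the split is configurable
since only the total is documented) with ResNet-D downsampling
(stride-2 main path, average-pool + 1x1 shortcut) between stages. The
decoder upsamples x2 (nearest), adds a 1x1-projected skip from the
matching encoder stage, and applies two 3x3 conv+BN+leaky-ReLU blocks;
the head is two 1x1 convolutions with a BN between, ending in a sigmoid
over two channels (cortex, vessel -- not mutually exclusive). A
projection head (GAP, L2 norm, two 256-wide linear layers, L2 norm)
serves contrastive pre-training only. Arbitrary input sizes are handled
by local even-padding before each downsample and cropping after each
upsample.

No deep-learning framework is available to R in this environment, so the
package carries its own compact training core: a reverse-mode tape over
im2col convolutions (RcppArmadillo), batch norm with running statistics,
and AdamW with cosine learning-rate decay. Every operator's gradient is
verified against central differences in the test suite. Weight decay is
not applied to biases or normalization parameters.

The step-2 loss is the unweighted sum
$L = L_{ctx} + L_{SelfHull} + L_{Cont} + L_{vsl} + L_{CrossHull} + L_{Excess}$:

* $L_{ctx}$, $L_{vsl}$: (1 - soft Dice) + BCE against the refined
  annotation and the vessel pseudo-labels. Soft Dice uses smoothing 1 in
  numerator and denominator, so empty-vs-empty scores loss 0.
* $L_{Cont}$: BCE between the dilated Canny edges of the binarized
  cortex prediction and the contour pseudo-labels, on pseudo-contour
  pixels only. The hard edge map carries no gradient; the gradient
  surrogate drives the predicted probability toward 0.5 at the annotated
  boundary (a mask transition through a pixel leaves p near 0.5 there),
  which is bounded and stable, while the reported value stays the
  hard-edge BCE. The edge indicator is clamped to [0.01, 0.99] so a
  missed contour pixel costs -log(0.01), commensurate with the other
  terms.
* $L_{SelfHull}$: 1 - soft Dice between the cortex prediction and the
  filled concave hull of its own binarization (hull detached); empty
  predictions score 1.
* $L_{CrossHull}$: 1 - Dice between the filled hulls of the two
  predictions (value exactly as defined, on the detached hulls). The
  gradient flows only through the cortex prediction, pulled toward the
  vessel hull: the symmetric variant -- pulling the sparse vessel mask to
  fill the cortex hull -- directly fights $L_{vsl}$ and destabilized
  training in practice.
* $L_{Excess} = \frac1B\sum_b \log(\alpha\,\mathrm{DSC}(1 - Y_b, \hat
  Y_b) + 1)$ with natural log and $\alpha = 10$: penalizes vessel
  activation outside the refined annotation.

Step 1 pre-trains the encoder with the supervised contrastive loss
(temperature 0.1, sum over positives outside the log) on positive
(cortex patch) vs negative (surroundings) examples; batches are 1/3
positive (a batch of 128 splits 43/85). Negative patches are 217 px
squares sampled non-overlapping at a Chebyshev safety margin of
floor(217/2) = 108 px from the positive mask. Augmentation: flips, color
jitter, Gaussian blur at probability 1/2 each; random cropping is
omitted in this step, the patches already being crops. Step 3 fine-tunes
on HSI with masked BCEs against the adjusted GT (target 1 on inner, 0 on
outer, unknown excluded; vessel pseudo-labels only inside inner, any
outer activation penalized), the HSI stem at full rate and everything
else at 1/1000 of it -- weights barely move but batch-norm running
statistics adapt to the HS data. Augmentation in step 3 is flips only.
An optional equivariance regularizer (MSE between predictions of
transformed inputs and transformed predictions, flips and 180-degree
rotations) mirrors the consistency-constraint baseline. Model selection
evaluates every 10 epochs: step 2 keeps the best mean of cortex and
vessel DSC on validation pseudo-labels, step 3 the best mean of
inner/outer pixel accuracy ("ACC" read as pixel accuracy over the
labeled adjusted-GT region) and masked vessel DSC, combined by
arithmetic mean since the weighting is unspecified.

Full-scale defaults follow the documented training regime: 400 / 1000 /
700 epochs, batches 128 / 8 / 8, AdamW with cosine decay 1e-4 -> 1e-5,
min-max per-band normalization fitted on the training and validation
cubes (values outside the fitted range are not clipped). The desk-scale
profiles used by the demo and the tests reduce this to 4-12 scenes,
10-120 epochs, base width 8 and a 2/2/2 stage split, training windows of
109 x 205 or 55 x 103 pixels, and a faster 2e-3 -> 2e-4 schedule for the
overfit probes; these sizes are the package's own desk-scale choices and
are stated here so results are reproducible.

## Foreign cube sizes

`adapt_spatial()` brings any cube to the 217 x 409 network input:
rotate 90 degrees if taller than wide, downscale bilinearly if the
height still exceeds 217 (or by width if the scaled width would overflow,
with a warning), then zero-pad right/bottom. `restore_spatial()` inverts
the recipe (crop, nearest-neighbour upscale, rotate back); pad-only
recipes restore bit-exactly, which the 5-fold HELICoiD-style evaluation
path relies on to score masks at native resolution.

## Evaluation

DSC and ASSD (exact Euclidean distances between 4-connectivity
boundaries) assess the cortex against dense gold-standard masks; the
vessel mask is scored on the unmodified sparse GT by the vessel hit rate
(fraction of vessel-labeled pixels covered) and vessel error rate
(fraction of the mask falling on healthy/tumor labels). Tissue maps are
scored per class by F1 and rank-statistic AUC (midranks for ties) on
labeled pixels, aggregated per patient (classes absent from a patient are
excluded from that patient's mean only) and then across patients as
mean +/- sample standard deviation. Row-normalized confusion matrices
use true classes as rows; for fused maps dura ground truth maps to the
"outside" row. Qualitative exemplars are the images nearest the 5th /
50th / 95th percentiles (linear interpolation) of the model-averaged DSC.

## Numerical choices and degenerate inputs

* Probabilities are clamped to [1e-6, 1 - 1e-6] inside BCEs.
* Empty-mask conventions: DSC(empty, empty) = 100; ASSD errors on empty
  masks; VER of an empty mask warns and returns 0; self/cross-hull on
  empty predictions return 1.
* Argmax ties in fused maps break toward the lower class index (healthy
  first).
* K-means runs with 8 restarts; all stochastic steps funnel through
  explicit seeds and equal seeds reproduce results bit-identically.
* Constant image channels (pseudo-RGB) map to 0.5 with a warning;
  constant bands under min-max normalization map to 0 with a warning.

## Known limitations

The synthetic scenes are easy in ways real craniotomies are not: class
spectra are well separated, the cortex refinement typically reaches DSC
near 100 and the line operator sees high-contrast vessels, so pseudo-label
quality here is an upper bound. The cross-hull and contour terms use
gradient surrogates whose fixed points, not their trajectories, match
the defined values. The training core is single-threaded CPU code --
adequate for the desk-scale profiles it ships with, not for full-scale
training. The fusion rule can only relabel within the cortex: a
classifier that mislabels healthy tissue itself is explicitly outside
the method's reach, and vessel-mask false positives over tumor tissue
reappear as tumor false negatives after fusion.
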