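---
title: "Locating the endotracheal tube tip and Carina on portable chest radiographs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Locating the endotracheal tube tip and Carina on portable chest radiographs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

After endotracheal intubation in an ICU, the tube position must be checked on
a portable supine (AP) chest radiograph: a tip too close to the Carina risks
bronchial intubation, a tip too high risks accidental extubation. The working
criterion implemented here calls a position *suitable* when the ETT-tip to
Carina distance lies in the closed window **[20, 70] mm**, and *unsuitable*
otherwise. The package implements a fully automatic pipeline: an anchor-free
convolutional detector proposes boxes for four classes (ETT, ETT tip,
tracheal bifurcation, Carina), a Gaussian-prior post-process reduces them to
exactly one tip point and one Carina point per image, and an evaluation layer
turns pixel geometry into millimetre errors and a malposition classification.

## Ground-truth model

A radiograph is annotated with 13 landmark points: P1–P4 outline the distal
tube, P5–P13 outline the tracheal bifurcation, with P9 the Carina feature
point. Derived targets:

* **ETT box/polygon** — tight axis-aligned box and simple polygon of P1–P4;
* **bifurcation box/polygon** — the same for P5–P13;
* **feature boxes** — squares of a configured side (300 px at native
  ~2500-px radiograph width, scaled proportionally for smaller rasters)
  centered on the ETT tip (the midpoint of P2 and P3) and on the Carina (P9).

The annotation protocol does not fix a vertex order, so polygons are
re-sequenced by angular sort about the vertex centroid; for the star-shaped
point sets the protocol produces this always yields a simple polygon, which
we verify with a segment-intersection test. Coordinates are 0-based with
half-open boxes internally and COCO `xywh` on disk; feature boxes are stored
unclipped (center + side travel in the JSON record) so clipping at image
borders is an export-time concern only.

## Detector

The detector is a one-stage anchor-free network. Every location of a feature
pyramid is a point in image space that predicts a class score per category, a
centerness score, and its four distances $(l^*, t^*, r^*, b^*)$ to the sides
of the box it belongs to. A location is a positive sample for the
smallest-area ground-truth box that strictly contains it, provided
$\max(l^*,t^*,r^*,b^*)$ falls in the level's range ((0,64], (64,128],
(128,256], (256,512], (512,∞) on P3–P7 at full scale; halved for the desk
profile). Centerness is

$$\text{centerness}^* = \sqrt{\frac{\min(l^*,r^*)}{\max(l^*,r^*)}\cdot
\frac{\min(t^*,b^*)}{\max(t^*,b^*)}},$$

and at inference the classification score is multiplied by the predicted
centerness before class-wise NMS (IoU 0.6, score floor 0.05). Distances are
parameterized as $\exp(s_\ell \cdot x)\cdot\text{stride}_\ell$ with one
learned scalar $s_\ell$ per level, which keeps them positive and
scale-calibrated.

The backbone is a bottleneck residual network whose last down-sampling is
removed: stage 5 runs at stride 1 with dilation 2, so C5 keeps stride 16.
The pyramid therefore runs P2/4, P3/8, P4/16, P5/16, and P6/32, P7/64 from
strided 3×3 convolutions on P5. Heads are shared across levels
(convolution towers with group normalization; the classification head bias is
initialized to the focal prior $-\log(99)$).

### Coarse-to-fine attention

The deepest backbone map, reduced to the neck width by a 1×1 convolution, is
refined by a coarse-to-fine attention block before entering the pyramid:

* **Global-modelling attention (GA)** captures long-range context with two
  branches that keep C channels each: a *cross-region* branch (3×3 dilated
  convolution at rate 3, then a point-wise convolution) and an
  *adjacent-region* branch (point-wise convolution, then the dilated
  convolution). Their concatenation (2C channels) is reduced by a point-wise
  convolution and expanded by a 3×3 dilated convolution at rate 2. No
  terminal softmax is applied by default; `ga_softmax = TRUE` restores a
  per-channel spatial softmax for the ablation variant.
* **Scale attention (SA)** rescales the map by a single spatial weight
  field. Channel-group average and max pooling (8 contiguous groups each; a
  remainder joins the last group) give a 16-channel map $F_s$. Adaptive
  average and max pooling of $F_s$ to 16×3×3, a shared 3×3 convolution and
  two shared fully connected layers (squeeze ratio 4: 144→36→16) produce two
  excitation vectors whose sum rescales $F_s$ channel-wise; a $k\times k$
  convolution (k = 1 by default, 7 as an ablation) reduces it to one-channel
  logits, and a spatial softmax turns those into weights that sum to one
  over H×W and multiply the input across channels.
* **Fusion**: the default is GA → point-wise smoothing convolution → SA
  ("coarse to fine"). The reversed order, a parallel concatenation fusion,
  bare GA/SA, a two-SA stack, and the attention-free baseline are all
  constructible through `nn_attention()` for ablation work.

Because the spatial softmax makes weights sum to one, the attended map's
magnitude shrinks by a factor of H·W; `sa_rescale_by_hw` offers a
magnitude-preserving variant and is off by default, keeping the literal
softmax semantics.

### Segmentation branch

During training a mask branch regularizes the shared features: P3–P5 are
nearest-neighbour up-sampled to P2's grid and summed (`seg_fusion = FALSE`
restricts to P2 alone), four 3×3 convolutions process the fused map, and a
4× up-sampling followed by a final 3×3 convolution emits per-pixel logits
for {background, ETT, tracheal bifurcation}. Tip and Carina masks are
deliberately excluded from the default: their square boxes sit on top of the
tube/bifurcation polygons, and masking them would re-focus the branch on
exactly the regions the detection heads already handle.

## Training objective

$$L_\text{total} = L_\text{cls} + L_\text{reg} + L_\text{centerness} + L_\text{seg}$$

* $L_\text{cls}$: focal loss $-a_t (1-p_t)^\gamma \log p_t$ with
  $\gamma = 2$, $a = 0.25$, summed over all locations and classes and
  divided by the number of positive locations; probabilities are clamped to
  $[10^{-6}, 1-10^{-6}]$.
* $L_\text{reg}$: GIoU loss $1 - \text{GIoU}$ averaged over positive
  locations, with $\text{GIoU} = \text{IoU} - |C \setminus (A\cup B)|/|C|$
  and $C$ the smallest enclosing box.
* $L_\text{centerness}$: binary cross-entropy between predicted and target
  centerness over positive locations (0 when there are none).
* $L_\text{seg}$: soft Dice plus $\lambda$ × multi-class cross-entropy with
  $\lambda = 1$. Dice uses smoothing $10^{-5}$ in numerator and denominator
  and averages over the foreground classes *present in the ground truth*, so
  a class absent from an image neither rewards nor penalizes the prediction.

Training uses Adam (learning rate $10^{-4}$ at clinical scale), linear
warm-up over the first five epochs and cosine decay to zero, shorter-side-800
resize, colour jitter, rotation in [−10, 10]°, and random crops that are
skipped whenever they would cut off a landmark. Batches are realized by
gradient accumulation; all randomness (weight init, case order,
augmentation) flows from one configured seed, and the trainer aborts with a
per-term diagnostic if any loss turns non-finite.

## Post-processing

Raw detections can contain several tip/Carina candidates. The reduction is:

1. keep the highest-confidence ETT and bifurcation boxes (ties: smaller
   area, then earlier index);
2. re-score every tip (Carina) candidate by its final confidence times a
   Gaussian prior $\exp(-\lVert c-\mu\rVert^2 / 2\sigma^2)$ centered on the
   parent box center — or on the image center when no parent box exists —
   and keep the arg-max;
3. if the survivor's *raw* (unweighted) confidence is below the threshold
   **and** below its parent's, replace it: the tip becomes the midpoint of
   the ETT box's bottom edge; the Carina becomes the bifurcation box center.
   With no candidate and no parent the point is reported as absent.

σ defaults to one eighth of the image diagonal and the confidence threshold
to 0.5; both are configurable. The raw confidence (not the re-scored value)
is compared against the threshold: the prior should arbitrate *among*
candidates, not make a near-prior candidate immune to refinement. Mask-based
tip correction exists conceptually but is not used: bounding-box refinement
alone proved the more reliable signal, and the segmentation output is kept
as a training-time regularizer.

## Evaluation layer

* **Object error**: Euclidean distance between predicted and true point,
  times the pixel spacing (mm).
* **Distance error**: |true tip–Carina distance − predicted distance| in mm.
* **Detection counting**: a prediction within 10 mm is a true positive; a
  prediction farther away counts as a false positive *and* leaves its ground
  truth unmatched (a false negative); an absent prediction is a false
  negative. Hence recall = TP/(TP+FP+undetected), which also makes recall
  coincide with the ≤10 mm error-distribution entry.
* **Suitability**: the [20, 70] mm window applied to the predicted distance;
  images with an absent keypoint enter the confusion matrix as "undetected"
  and always count against accuracy.
* **Aggregation**: per-fold standard deviations use the population (n)
  divisor; 5-fold summaries are unweighted means of the per-fold values —
  including the means of the per-fold standard deviations, which is how the
  reference evaluation's Average rows reproduce. Relative changes against a
  reference method are $(ours - ref)/ref \times 100$, rounded to two
  decimals.

## Synthetic radiographs

The generator emulates exactly the statistical structure the detector needs:
a smooth dark tube curve entering from the top edge and ending at a tip
(with P1–P4 straddling the distal segment so the P2–P3 midpoint *is* the tip),
a brighter tracheal band ending in a Y of dark bronchi whose apex is P9,
Gaussian pixel noise, and bright linear occluders drawn after the tube so
some tips are partially hidden, mimicking monitoring wires. The tip–Carina
distance is drawn from a mixture: with the configured weight (default 0.5)
uniformly from the suitable [20, 70] mm window, otherwise from [0, 20) or
(70, 120] with probabilities proportional to their lengths. The physical
field of view is held at 256 mm, so the pixel spacing scales inversely with
the raster (0.5 mm/px at 512², 1 mm/px at 256²) and the full unsuitable
range stays representable at any size. Feature-box sides scale as
300 × width/2500 from the native protocol.

What the generator does **not** emulate: ribs, mediastinal anatomy, exposure
artefacts, detector heel effect, or inter-annotator variability. Passing
tests therefore demonstrate that the pipeline's geometry, losses,
optimization and reduction logic are correct and trainable — not that the
desk-scale model reaches clinical accuracy on real radiographs.

## Numerical and design choices

* **Normalization.** With gradient-accumulated batches of one or two images,
  batch statistics are meaningless, so every "batch norm" slot is realized
  as per-sample group normalization (instance-style in the attention convs,
  8-channel groups elsewhere); backbone norm affine parameters are frozen by
  default (`freeze_backbone_norm`). There are no running statistics, so
  train/eval forward passes are identical and deterministic.
* **Engine.** Networks run on a compact reverse-mode autodiff engine written
  for this package (dense R arrays, RcppArmadillo im2col convolutions with a
  point-wise fast path). Every structured operator's gradient is pinned
  against central finite differences in the test suite.
* **Desk profile.** The shipped CPU profile trains a width-reduced topology
  (stem 8, stages 8/16/32/64, neck 16, one-conv head towers) on 256² images
  for 200 single-image Adam iterations at learning rate 10⁻³ (scaled up for
  the narrow width), warm-up 10% of the schedule, no augmentation. Those
  sizes keep a full train/evaluate smoke run in a few minutes on one core
  while exercising the identical code path as the clinical-scale
  configuration.
* **Tie-breaks and degenerate inputs.** Ambiguous target locations take the
  smallest-area box; `best_box` ties resolve by area then index; zero-area
  annotation boxes are rejected at derivation; empty detection sets
  post-process to explicitly absent keypoints rather than erroring; Dice of
  an image with no foreground class is defined as 0.
* **Bit-exact round trips.** Assigned regression targets decode back to
  their ground-truth boxes exactly for integer-coordinate annotations (the
  native labelling case); for arbitrary real coordinates the identity holds
  to floating-point rounding.

## Limitations

The package reads PNG radiographs (plus pixel spacing carried in the
annotation JSON); DICOM ingestion is out of scope of this release. The
desk-scale smoke model demonstrates trainability, not clinical performance;
reproducing clinical accuracy requires GPU-scale training on real data. One
ETT per image is assumed throughout, and the post-process consequently never
reports more than one tip/Carina pair.
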