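---
title: "Landmark-anchored ROI classification: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-anchored ROI classification: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fundusroi)
```

## The problem and the method

Ultra-widefield fundus photography images most of the retina in one
shot, which makes it attractive for screening several ocular diseases at
once but also means most of each image is irrelevant for any single
diagnosis. The method implemented here exploits a clinical observation
about *where* the six target diseases manifest:

* diabetic retinopathy (DR), retinal break (RB) and retinal vein
  occlusion (RVO) produce lesions scattered across the whole retina;
* epiretinal membrane (ERM) and age-related macular degeneration (AMD)
  manifest around the macula;
* glaucoma-suspect (GS) findings concentrate on and around the optic
  disc (cup enlargement, peripapillary nerve-fiber changes).

The pipeline therefore (1) localizes the optic disc and macula, (2)
extracts two square regions of interest anchored to those landmarks,
and (3) routes each disease to the classifier branch that sees its
region: a binary optic-disc branch for GS, a two-label macula branch for
ERM and AMD, and a three-label whole-image branch for DR/RB/RVO. A
fourth configuration — a single whole-image six-label classifier — is
kept as the ablation baseline.

### ROI geometry

Both ROIs are squares whose edge is a multiple of `d`, the diagonal of
the detected optic-disc bounding box: `alpha * d` centered on the disc
center `O` (default `alpha = 3`) and `beta * d` centered on the macula
center `M` (default `beta = 6`). The optic disc is the anchor because
its detected extent is far more stable across images than the macula's,
so tying both ROI sizes to `d` keeps the physical area covered
consistent. Coordinates are continuous, 0-based,
min-inclusive/max-exclusive throughout; fractional edges round half up.

Two geometric choices were genuinely open and are resolved as follows:

* **Border handling.** Whether the original system clipped or padded
  ROIs at image borders is not stated. We pad with a constant fill
  (default black), because a fixed output shape is required for a
  fixed-size classifier input and padding keeps the ROI center aligned
  with the landmark. This is an interpretation, flagged as such.
* **Elimination order in proposal filtering.** Which of two overlapping
  detector proposals (IoU > 0.7) is dropped is unstated; we use greedy
  non-maximum suppression keeping the higher objectness score, the
  standard reading of "reducing redundancy". Score ties keep the
  earliest input, and this tie-break is tested.

### Detector

Training a two-stage object detector is out of scope here; the detector
sits behind a one-function interface (scene in, scored boxes out) and
the registered implementation is an *oracle* fed by the synthetic
ground truth, optionally corrupted with Gaussian corner jitter. The
proposal post-filtering contract (boundary-crossing proposals removed,
IoU > 0.7 suppression, a 256-proposal cap) and the top-1-per-class
selection rule are implemented and tested independently of any trained
model, because the method's substance is downstream of detection.

### Classifier branches

All branches share one training recipe: Adam, batch size 8, learning
rate halved every 10 epochs, 60 epochs by default, online augmentation
(horizontal flip with probability 0.5; rotation uniform on
[-180, 180] degrees, redrawn every batch), and model selection by the
epoch of highest mean validation AUC. The ROI branches start at
learning rate 1e-3 and the whole-image branches at 1e-4, following the
published schedule. The GS branch is trained with two-class softmax
cross-entropy and its disease probability is the softmax score of the
disease class (the output mapping is implied but unwritten in the
source method; we document it as our reading). The multi-label branches
use element-wise sigmoid binary cross-entropy.

**Backbones.** No deep-learning framework is available in this R
environment, so the registered backbones are small fully-connected
networks (a linear model and one-hidden-layer ReLU MLPs of width 32 and
64) trained by a hand-written, fully seeded Adam loop. The branch code
is backbone-agnostic via a registry, so convolutional backbones can be
slotted in where a framework exists. On the synthetic scenes this
matters little — the signal is purely spatial and the MLPs learn it —
but it is the main reason the package's absolute AUC values must not be
compared with published clinical numbers.

Input images are resized (bilinear) to `input_size` (default 48 px
here, chosen for desk-scale runtimes) and normalized with mean 0.5 /
sd 0.5; both constants are configurable and nothing downstream depends
on them.

### Splitting

The published protocol splits each class roughly 9:1. Multi-label
stratification is underdetermined by that statement; we use greedy
iterative stratification: repeatedly take the class with the fewest
unassigned positives and deal its images to the side whose remaining
demand for that class is larger, updating demands with the images' full
label vectors. Label-free (Normal) images are distributed last to
preserve the overall ratio. A class with exactly one positive cannot be
stratified and is rejected with an error rather than silently placed.

### Thresholds and evaluation

Per-disease cut-offs maximize sensitivity x specificity, searched over
every point where the confusion table can change (midpoints of
consecutive unique scores plus the endpoints 0 and 1), so the optimum of
the step function is exact rather than grid-approximate. Ties go to the
lower threshold, favouring sensitivity. An image is predicted positive
when its probability is *strictly* greater than the cut-off. Thresholds
are tuned on the validation split: the source text does not name the
tuning split, and tuning on evaluation data would leak.

AUC uses the rank (Mann-Whitney) formulation with ties counted 0.5.
Micro-averages pool confusion counts across the six diseases. The
derived Normal class is truly Normal when all six labels are zero and
predicted Normal when no probability exceeds its threshold — the
source's handling of its Normal row is unstated, and this all-negative
rule is our documented assumption. Repeated-run 95% confidence
intervals use the Student-t quantile (with five runs a normal quantile
would be anti-conservative). The significance test behind the published
p-values is unnamed; we use a Welch two-sample t-test on per-run AUCs,
computed in closed form so the degenerate zero-variance case returns
p = 1 instead of erroring. The single-label misclassification matrix
considers only images with at most one positive label; when several
diseases fire on one image every predicted cell is incremented (the
alternative — picking the max — is not what a multi-label system
outputs, and the source does not specify).

## The synthetic-scene generator

There is no public dataset for this task, so the package ships a
generator that emulates the *spatial statistics* the method exploits: a
circular retinal field with a radial intensity falloff, a bright optic
disc with a central cup, a darker macula temporal to the disc, additive
Gaussian pixel noise, and per-disease lesions:

* DR/RB/RVO-like: lesion centers uniform over the retinal field;
* ERM/AMD-like: truncated Gaussian around the macula center,
  concentration radius 2`d` by default;
* GS-like: a perturbation of the disc itself (enlarged, brighter cup
  plus a peripapillary ring) and small blobs within 1`d` of the disc
  center.

Lesions are small Gaussian-profile blobs, bright or dark per disease.
This is deliberate minimalism: the pipeline consumes only spatial
signal, so a photometrically realistic appearance model would add
nothing testable. Labels are independent Bernoulli draws per disease
(the source dataset's co-occurrence statistics are shown only as a
plot, so no numeric dependence structure is available to copy);
prevalence defaults to 0.3 per class, the value the scaled-down
acceptance experiments stipulate. Lesion count per active disease is
Poisson with mean 8 — enough for a clear spatial signature without
saturating a 128 px scene.

Because the GS signal is confined to the disc neighbourhood, a
whole-image learner sees it diluted by downsampling while the disc-ROI
learner sees it magnified: this is exactly the mechanism behind the
ROI-vs-whole-image gap the ablation reproduces qualitatively. A green
ROI-advantage test therefore establishes that the *pipeline* extracts
and exploits localized signal — it does not establish clinical
performance, image realism, or anything about lesion appearance.

What the generator does **not** model: vessel trees, eyelash/lid
artifacts, pseudo-color distortion, inter-eye laterality, correlated
labels, and realistic lesion morphology.

## Numerical and reproducibility choices

* All randomness flows through R's RNG; dataset generation, detector
  jitter, splitting and training each reseed from configuration fields,
  so a pipeline configuration determines every output byte (the
  determinism acceptance test compares report files byte-wise).
* Images are 8-bit grayscale PNGs written by a self-contained codec
  (the environment provides no image I/O package); encoding is
  deterministic and the suite cross-checks the codec against an
  independent reader.
* `round(edge)` uses round-half-up, stated once and asserted, because
  banker's rounding would make ROI sizes depend on parity.
* The smoke profile used by tests (48-96 px inputs, 2-10 epochs,
  hundreds of images) exists purely for runtime; the paper-faithful
  schedule (60 epochs) is the package default.

## Known limitations

* Fully-connected backbones cap achievable accuracy on complex scenes;
  absolute metric values on synthetic data are not comparable to
  published clinical results (which are also computed on a private
  dataset and are out of scope as reproduction targets).
* The oracle detector bypasses detection failure modes; jitter is the
  only detector-error model.
* Independent labels understate the difficulty of correlated
  multi-label prediction.
* The whole-image branch at the published 1e-4 learning rate learns
  slowly at smoke-profile epoch counts; its smoke AUCs for DR/RB/RVO
  are weak by construction, which is irrelevant to the ROI-advantage
  comparisons (those compare macula/disc branches against the baseline
  trained with the same whole-image schedule).
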