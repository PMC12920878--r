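---
title: "Auditing shortcut learning with ROI masking"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing shortcut learning with ROI masking}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(maskaudit)
```

## The problem

Image classifiers in medical imaging can reach impressive discrimination
scores while relying on features that are not causally related to disease:
implanted devices such as pacemakers, burnt-in scanner or camera text, or
the mere size of an anatomical structure. Such *shortcuts* survive internal
validation (the spurious correlation is present in the test split too) and
then fail, sometimes catastrophically, under distribution shift.

`maskaudit` operationalises a masking-based audit of this failure mode. The
clinically relevant structure — the lungs in a chest radiograph, the optic
disc in a fundus photograph — is described by a per-image binary ROI mask.
Five dataset variants are derived from each image:

| strategy      | keeps                                         |
|---------------|-----------------------------------------------|
| `FULL`        | everything                                    |
| `NO_ROI`      | everything except the precise ROI mask        |
| `NO_ROI_BB`   | everything outside the mask's bounding box    |
| `ONLY_ROI`    | only the precise ROI mask                     |
| `ONLY_ROI_BB` | only the mask's bounding box                  |

A model is trained per variant (5-fold cross-validation, so five models per
variant), and every model is evaluated on every variant of a held-out test
set, yielding a 5 × 5 grid of mean ± SD AUC. The diagnostic signal is simple:
**a model trained and evaluated on images whose ROI has been removed should
be at chance**. If it is significantly above a label-permuted null — by the
fold rule below — the data contain label-correlated signal outside the
region that should carry it, and every model trained on the full images had
the same shortcut available.

Three further probes refine the picture:

* **Dilation sweeps.** The mask is grown by morphological dilation with a
  Euclidean disk of radius *f* pixels before masking, and the AUC is traced
  as a function of *f*. Sweeping a `FULL`-trained model shows how much
  context around the ROI it needs; dilating the masks of *positives only*
  under an `ONLY_ROI` model exposes ROI-*size* confounds: if positives have
  systematically larger ROIs, enlarging their visible region drives the AUC
  to 1.0.
* **Embedding similarity.** Cosine similarity between the embedding of a
  full image and its masked variants, paired per image, under the
  `FULL`-trained model, plus a seeded 2-D stochastic neighbour projection.
  These are descriptive only; the package prints a standing caveat because
  similarity orderings can disagree with AUC orderings.
* **Superpixel Shapley attribution.** The image is partitioned into
  superpixels; the Shapley value of each superpixel under black-occlusion
  coalitions quantifies its contribution to the predicted probability. The
  in-ROI share of positive attribution mass summarises whether the model
  looks where a clinician would.

## Statistical machinery

The AUC is computed as the Mann–Whitney rank statistic with half credit for
ties (midranks), which equals exhaustive pair counting exactly. Two models
scored on the *same* samples are compared with the DeLong test: per-positive
and per-negative placement values give the 2 × 2 covariance of the two AUCs,
and \(z = (A_a - A_b)/\sqrt{\widehat{\mathrm{var}}(A_a - A_b)}\) is referred
to the standard normal, two-sided. Ties are handled through midrank
placements. With five fold models per variant, a difference is declared
significant when the p-value is below 0.05 in **at least three of the five
folds**; the same rule aggregates the per-fold label-permutation p-values
behind the shortcut-risk verdict. No multiple-testing correction is applied
across cells; the report notes this.

The Shapley estimator samples segment permutations in antithetic pairs and
caches coalition values; each permutation's marginal contributions sum to
\(f(x) - f(\emptyset)\) exactly, so efficiency holds exactly after
averaging. When the evaluation budget covers all \(2^M\) coalitions the
estimator switches to exhaustive enumeration with the combinatorial weights.
An independent oracle (`exact_shapley`) computes the same values through a
Möbius/Harsanyi-dividend transform and backs the estimator's tests.

## The synthetic test bed

Real audits of this kind need large clinical datasets and days of GPU time.
The package therefore ships a generator whose outputs have *known* ground
truth, so every claim the audit makes can be validated end to end at desk
scale. `generate_dataset()` emulates the structure of ROI-annotated medical
images:

* **Geometry.** `two_lungs`: two vertically elongated ellipses with a
  central gap on a body-shaped background; `disc`: one filled circle at a
  jittered position on an eye-shaped background. ROI size carries
  multiplicative jitter (SD 0.08) for anatomical variability.
* **Disease signal**, positives only, strictly inside the ROI: a localised
  *texture* change (extra high-frequency energy under a Gaussian window at a
  random in-ROI location) plus a mild intensity bump, with amplitude in
  units of the pixel-noise SD (default 2.5). The signal is texture-dominant
  by design: a brightness-dominant signal would be colinear with every
  area/brightness confound the audit is supposed to isolate, making the
  clean and confounded conditions indistinguishable to any
  brightness-sensitive model.
* **Planted shortcuts** (`shortcut_spec`): a pacemaker-like bright `token`
  with a lead-like line placed outside the ROI; `border_text`, a
  high-contrast glyph band in a corner strip, emulating burnt-in camera
  text; `global_offset`, an intensity offset of all non-ROI pixels. Presence
  matches the label with probability ρ: ρ = 1 is a perfect proxy, ρ = 0.5 is
  label-independent. Shortcut pixels never intersect the ROI.
* **ROI-size confound**: `roi_size_label_slope` enlarges positives' ROIs by
  a relative factor, emulating the situation where structure size correlates
  with the label without being the clinically correct criterion.
* **Metadata** (`sex`, `birth_year`, `projection`) derived from one latent
  whose separability is calibrated in the binormal model,
  \(d = \sqrt{2}\,\Phi^{-1}(\mathrm{AUC})\), so a logistic baseline on the
  metadata recovers the requested AUC.
* **Mask quality** mimics an automatic segmentation-quality score; a
  configurable fraction falls below the 0.7 filtering threshold, and
  `filter_records()` keeps only records strictly above it.

Intensities are floored at 0.02 so that exact black is reserved for padding
and masked-out pixels. All randomness flows from one seed through per-record
child streams: the same configuration and seed give byte-identical datasets,
and any subset of records is reproducible.

What the generator does **not** emulate: photorealistic anatomy, reader
disagreement, acquisition physics, multi-site batch structure, or
co-occurring pathologies. Passing the audit here shows the *pipeline* is
sound — that it flags planted confounds and stays quiet on clean data — not
that any particular clinical model is shortcut-free.

## The classifier stand-in

The audit's logic is backbone-agnostic, so the packaged classifier is a
deliberately small, fast stand-in for a large frozen CNN: a fixed
convolutional trunk — visibility (nonzero pixels), raw intensity, Gaussian
blur, difference of Gaussians, gradient magnitude, and local high-pass
energy — pooled over a 4 × 4 grid with mean, upper-quantile (q95) and max
statistics, plus per-cell visible-pixel-normalised intensity and texture
ratios (320 dimensions); on top of it, a trained head with one hidden ReLU
layer (32 units) and per-class logistic outputs. Only the head is trained,
mirroring frozen-backbone fine-tuning. The quantile statistic is pooled
alongside the max because the max grows with the number of visible pixels,
which would let occlusion and dilation masquerade as texture; the hidden
layer is needed because "artifact present in *any* cell" is an OR that a
linear head cannot express. Any model exposing embeddings and a
probabilistic head can stand behind the same `maskaudit_model` interface.

Training follows a fixed protocol: Adam (learning rate 1e-3) on mini-batches
of 32, up to 250 epochs, early stopping when the validation loss (the
held-out fold) fails to improve by 1e-3 for 10 consecutive epochs, with the
best-epoch weights restored. Augmentation expands the training set with
stochastic replicas: rotation ±45°, horizontal flip (p = 0.5), brightness
scaling 0.7–1.1, and random erasing (p = 0.5). Augmentation is applied to
the raw image *before* masking, so masked-out regions stay exactly black
rather than rotating the hole. Random erasing matters beyond regularisation:
it teaches the head that black patches mean absence of signal, which is what
makes black-occlusion Shapley probes in-distribution (without it the head's
response to heavily occluded images is arbitrary extrapolation).

Two protocol presets mirror the practice of tuning per dataset. The
chest-like default uses plain cross-entropy and no mask jitter. The
fundus-like protocol (used for ROI-size-confound analyses) uses weighted
cross-entropy, three replicas, and ROI-mask dilation jitter: each replica's
mask is dilated by a random radius covering the factor range of the planned
sweep. This models segmentation-boundary variability and is what makes the
sweep interpretable — a model that has never seen a dilated mask responds to
dilation as an arbitrary out-of-distribution perturbation, whereas a
boundary-jittered model responds only through signal that survives boundary
changes, such as a genuine size–label association. Mask-jitter replicas are
kept free of rotation and brightness changes so the learned invariance
transfers to unrotated evaluation images. Consequently, sweep factors should
stay within the jitter range used in training.

The learning rates quoted for full CNN fine-tuning (1e-5/1e-4) are specific
to pretrained backbones and are not meaningful for a two-layer head trained
from scratch; the head's default of 1e-3 was chosen once for stable
convergence within the epoch budget.

## Numerical and design choices

* Masked pixels take the value 0 ("black"), identical to padding, applied on
  the [0, 1] scale before any standardisation, so removed regions are
  indistinguishable from padding.
* Dilation uses an exact Euclidean distance transform; the "dilation factor"
  is the disk radius in pixels at the working resolution. Factors 0–40 at
  128 px correspond to roughly 0–160 at 512 px.
* Bounding boxes are 0-based with inclusive corners; degenerate (empty)
  masks raise an explicit error and the record is excluded with a logged
  count rather than silently producing an all-black or untouched image.
* Non-binary mask files are thresholded at >127 (8-bit) or >0.5 ([0, 1]).
* Undefined AUC cells (single-class evaluation subsets) are recorded as
  missing, never as 0.5.
* The permutation null for the verdict uses 200 label permutations per fold
  by default (p-values have resolution 1/201, sufficient for the 0.05 rule);
  the DeLong test is reserved for model-vs-model comparisons.
* `project_2d` is an exact O(n²) t-SNE with PCA initialisation (duplicates
  stay coincident), early exaggeration, and a stratified subsample cap of
  2000 points; perplexity defaults to 30 and shrinks automatically for small
  inputs.
* Superpixels default to a regular grid because it makes oracle tests
  deterministic; any integer label partition can be substituted.
* Shapley occlusion uses black as the baseline, matching the masking
  convention, with the budget fixed at 1000 model evaluations per image in
  the audit default.

## Problem sizes

The packaged analyses run on one CPU core at desk scale, chosen once: 600
training images (plus a 300-image test set) at 128 × 128 for the audit and
sweep experiments, 5-fold cross-validation throughout, 1000 replicates for
the DeLong null calibration, 1000 occlusion evaluations per attributed
image, and 10 attributed positives per condition. The test suite uses
smaller fixtures (64 px, 120–140 images) for module-level checks.

## Known limitations

* The trunk is not a learned representation; findings about *this*
  classifier's robustness do not transfer to any specific CNN. The audit
  surface (masking, evaluation, significance, attribution) is the reusable
  part.
* The shortcut amplitudes are free parameters of the generator; they are not
  calibrated to any real acquisition artifact.
* Embedding similarity and 2-D projections are descriptive; the package
  prints the corresponding caveat wherever they are reported.
* The fold rule controls neither family-wise error across the 25-cell grid
  nor correlation between folds; it is reproduced as specified and flagged
  in the report.
* `padchest_filter` implements the metadata-filtering pipeline for the
  chest-radiograph CSV dialect (lateral-view removal, null/excluded label
  strings, mask join, quality threshold); validating its survivor count
  against the real accession-controlled tables requires those tables.
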