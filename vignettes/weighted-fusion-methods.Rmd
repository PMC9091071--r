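---
title: "Weighted fusion of imaging and age evidence for spinal tumor diagnosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Weighted fusion of imaging and age evidence for spinal tumor diagnosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spinewff)
```

## The diagnostic problem

Differentiating benign from malignant spinal tumors on MRI is a
patient-level decision: a radiologist reviews several sagittal sequences
(T1-weighted, T2-weighted, fat-suppressed T2), each an ordered stack of
slices, and also weighs clinical context such as the patient's age.
`spinewff` implements a late-fusion framework that mirrors this workflow
with three separable evidence sources:

1. **Detection term `D`** — a per-image lesion detector proposes boxes with
   a tri-class score (background / benign / malignant); the top
   post-suppression detection of image `j` in sequence `i` yields a
   benign/malignant probability pair `D_i^j`.
2. **Sequence term `M`** — a classifier over an `N`-frame crop stack (the
   largest detected region, cropped from `N` consecutive slices and resized
   to `112 x 112`) yields one pair `M_i` per sequence.
3. **Age term `A`** — a per-age-bin probability table fitted on training
   metadata yields one pair `A` per patient.

Per image, the sources are combined by a weighted sum,

$$P_i^{j} = \lambda_1 D_i^{j} + \lambda_2 M_i + \lambda_3 A,$$

normalized by the sum of the weights of the terms actually present. Each
image votes with the argmax of its fused pair; the majority elects the
sequence category; the majority over sequences elects the patient category.
Exact ties at either level go to *malignant* — a deterministic,
sensitivity-favoring rule chosen because the clinical cost of a missed
malignancy exceeds that of a false alarm. The continuous patient score used
for ROC analysis (never for the categorical decision) is the mean over
sequences of the mean fused malignant probability; the categorical decision
path and the score path are deliberately kept separate because majority
voting is not a monotone function of any single scalar score.

### Handling absent evidence

The weighted sum is defined over *present* terms only. Images on which the
detector found nothing contribute no vote rather than an imputed one; a
sequence whose images all abstain falls back to the remaining terms
(`lambda_2 M + lambda_3 A`, renormalized), and if those carry zero weight
too, to an equal-weight combination of whatever evidence exists. This keeps
every decision total and deterministic without letting absent evidence
masquerade as neutral evidence. Renormalization by the active weight sum
also makes decisions invariant to positive rescaling of
`(lambda_1, lambda_2, lambda_3)`, so weight triples that do not sum to 1
(e.g. the detection + age setting `(0.45, 0, 0.1)`) are handled exactly
rather than approximately.

## Reference implementations behind the contracts

Deep backbones are intentionally out of scope. Both image models are
lightweight, fully deterministic reference implementations standing behind
narrow contracts (a detection table and a per-sequence probability table in
documented CSV formats), so externally produced detections or sequence
predictions can be fused and evaluated by swapping files at those
boundaries.

**Detector.** Proposals are connected components of the thresholded
*anomaly map*: the positive part of the image minus a background estimate.
The background is the elementwise maximum of an `8 x 8` low-pass field
(block resampling up and down by separable bilinear interpolation) and a
per-column median profile; the latter absorbs the bright vertebral band so
lesions overlapping the spine still stand out. The proposal mask is
morphologically closed (dilate radius 3, fill holes, erode back) so a
detected lesion rim becomes a tight full-lesion box. The anomaly threshold
is trained by scanning candidate quantiles of outside-annotation anomaly
values and keeping the one that maximizes ground-truth box recall at
IoU >= 0.5. Each proposal is scored by multinomial logistic regression on
five appearance features (mean, variance, gradient energy, log area, aspect
ratio); boxes whose argmax is background are not emitted; greedy
class-agnostic NMS (IoU threshold 0.5, confidence ties broken by lower
`x0`, then `y0`) selects the final set.

**Sequence classifier.** Each 112 x 112 frame is summarized by mean,
variance, gradient energy and an 8-bin intensity histogram; the 11-vector
is averaged over the `N` frames and fed to a ridge-regularized logistic
model (penalty `1e-2`, chosen mild since the feature space is tiny and the
training draws are numerous). Training draws sequences class-balanced
(inverse-frequency weights), and windows with a 50/50 mixture of
tumor-centered and acquisition-order centers. Because the stack feature is
a mean of per-frame features, the trainer caches per-position frame
features and averages cached columns — numerically identical to extracting
the stack (asserted in the test suite) while rendering each slice once.

### Crop-stack window rules

`N = 16` frames by default (larger stacks outperformed 4- and 8-frame
stacks in the source experiments). The window around center position `c`
starts at `c - floor(N/2)`, is shifted to fit at sequence ends, and when
the sequence is shorter than `N` the positions cycle `0, 1, ..., L-1, 0,
1, ...` until `N` frames are taken — so extraction is total for every
`L >= 1` (property-tested exhaustively for `L` up to 40 and `N` up to 32).
Bilinear interpolation performs the 112 x 112 resize. A sequence with no
detections at all is classified from a centered fallback box of half the
image dimensions at the middle slice, with a logged notice.

## The age model

Ages are binned into decades (left-closed), and each bin's malignancy
probability is the additively smoothed fraction
`(n_m + alpha) / (n_b + n_m + 2 alpha)` with `alpha = 1`. Smoothing keeps
sparse bins away from 0/1 certainty, so a single age bin can never veto
image evidence inside the weighted sum; empty bins receive the global
prior. The age term is served as a probability pair rather than a hard
class, consistent with the additive fusion.

## Fusion weights

The default triple is `(0.45, 0.45, 0.1)` — image evidence dominates and
age acts as a mild prior. `crossval_select_weights()` searches the unit
simplex (step 0.05) by patient-stratified k-fold cross-validation (k = 4),
maximizing mean held-out accuracy with ties broken by mean AUC, then lower
age weight, then lexicographic order. Ablations zero components of the base
triple (detection-only, detection+age, sequence-only, ...), relying on
active-weight renormalization for comparability.

## The synthetic cohort generator

The generator defines the study conditions for every test: patients with
four sequences (modalities cycling T1, T2, FS-T2), 12-24 slices per
sequence at 256 x 256 pixels, and a lesion visible on a contiguous 7-11
slice sub-range whose in-plane footprint drifts by at most ~1.5 px/slice.
The background is a smooth noise field (base 0.35, amplitude 0.08) with a
vertical column of brighter vertebral bodies separated by darker disc
gaps. Lesions are filled ellipses (semi-minor axis 8-30 px, aspect ratio
1.2-2): benign lesions are near-homogeneous (speckle sd 0.02) with a
smooth boundary; malignant lesions carry strong speckle (sd 0.12) and a
radially perturbed boundary (relative amplitude 0.25). Class is drawn from
the logistic age law `1 / (1 + exp(-(age - 40) / 8))` — probability 0.5 at
age 40 and ~0.99 at age 80 — with ages uniform on 4-82 years; uniform
rather than bell-shaped ages were chosen so every decade bin is populated
for age-table testing.

Modality enters twice: lesion/background contrast (T1 0.18, T2 0.30,
FS-T2 0.35) and texture-signal strength (T1 scaled to 0.4). The class
signal is therefore present in all modalities but weaker on T1, so
T2-weighted sequences are genuinely more informative — the mechanism behind
the expected modality-ablation ordering. Contrasts were fixed so that
lesions remain brighter than vertebral bodies in all modalities; an early
design in which T1 lesions were darker than bone made on-spine T1 lesions
physically undetectable to any brightness-based detector, which confounds
the modality comparison with a detectability artifact.

What the generator does *not* emulate: anatomical shape variation, partial
volume and bias fields, k-space noise, multi-focal disease, and the
histological diversity of real spinal tumors. Passing tests therefore
demonstrate the correctness and internal consistency of the pipeline and
the qualitative behavior of fusion (image + sequence + age beats single
sources; T2 beats T1), not clinical performance.

## Numerical choices and degenerate inputs

* Boxes are 0-based half-open pixel rectangles; IoU is exact rational
  arithmetic on that convention, validated against pixel-set counting.
* AUC is the rank-based Mann-Whitney statistic with tie half-credit,
  validated against O(PN) pair counting to 1e-12.
* Metrics with zero denominators are reported as `NA`, never as 0; report
  tables round to 3 decimals.
* All randomness flows through explicit seeds; per-slice render seeds are
  derived arithmetically from the cohort seed so lazily rendered pixels are
  bit-reproducible regardless of evaluation order. Two pipeline runs with
  one seed produce byte-identical decision files.
* Problem sizes used in the shipped checks — 120-patient cohorts for
  end-to-end evaluation, 2000 metadata-only patients for age-law recovery,
  50-patient cohorts for detector recall — were chosen as the smallest
  cohorts at which the binomial noise of the measured rates is comfortably
  below the margins being asserted.

## Known limitations

* The reference detector is brightness-based; lesions isointense to their
  surroundings would require the pluggable deep detector the contract
  anticipates.
* The age table is a frequency table, not a calibrated model; with very
  small training sets the global-prior fallback dominates.
* Fused probabilities are renormalized but not calibrated; they support
  ranking (AUC) and argmax decisions, not absolute risk statements.
* Majority voting weighs every sequence equally; no attempt is made to
  down-weight sequences with poor detection coverage.
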