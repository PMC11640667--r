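---
title: "Multi-view individual identification: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view individual identification: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(caprid)
```

## The identification task

A herd of N visually similar animals is observed by up to five cameras:
left face (L), front face (F), right face (R), top-down back body (B) and
side body (S). Each view has its own classifier that maps a cropped,
resized appearance image to a softmax confidence vector of length N. The
package's job is everything around those classifiers: thinning raw video
frames into a diverse image set, building balanced train/validation/test
splits, fusing per-view confidences into one decision, scoring the
result, and deciding at runtime how many images or views to spend per
animal.

## Decision-level fusion

For confidence vectors $v_i$ from $n$ distinct views with weights $w_i$,

$$v_\mathrm{avg} = \frac{\sum_{i=1}^{n} w_i\, v_i}{\sum_{i=1}^{n} w_i},$$

with $w_i$ the top-1 accuracy of view $i$'s single-view model. The fused
identity is $\arg\max v_\mathrm{avg}$, ties broken to the lowest index
(ties have measure zero for real-valued confidences; the rule only
matters for degenerate inputs). Because $v_\mathrm{avg}$ is a convex
combination of simplex points it is itself a probability vector, and
scaling all weights by a positive constant changes nothing — both are
tested invariants. The formula is applied verbatim to any subset of 2–5
views; weights are used as-is, with no per-subset renormalisation beyond
the denominator.

Two weight sources are supported: validation accuracy (the default — it
keeps the test set out of the weights) and test accuracy, selectable via
`weights_from` in `run_config()`. Published work on this design has used
test-set accuracies as weights, which leaks a small amount of test
information into fused test evaluation; we flag the issue and default to
the clean choice rather than resolve it.

For multi-view evaluation from per-view confidence dumps, test images of
the same identity must be paired across views. The pairing rule is not
canonical; `fuse_dumps()` pairs by per-identity sample rank by default
and offers a seeded random pairing as the alternative. Rank pairing is
deterministic and truncates to the smallest per-view count.

## Frame thinning

Consecutive video stills are near-duplicates. Two sequential filters
remove them, each comparing a candidate against the *most recently
retained* frame (an anchor, rather than the immediate predecessor, so a
slow drift cannot chain-delete a whole sequence; "adjacent frame"
filtering in field practice is ambiguous between the two, and the anchor
variant is the conservative reading):

* **dHash**: grayscale, bilinear resize to 9×8, bit per horizontal
  intensity drop, 64 bits row-major; drop a frame when the Hamming
  distance to the anchor is strictly below 5. This is the canonical
  difference-hash definition; a constant image hashes to all zeros
  because the comparison is strict.
* **SSIM**: 11×11 Gaussian window, σ = 1.5, K1 = 0.01, K2 = 0.03,
  dynamic range 255, population window moments, averaged over interior
  windows; drop when SSIM ≥ 0.7 (high similarity means delete — the
  deletion direction is stated nowhere canonical, but deleting *similar*
  frames is the only reading under which retained sets grow with the
  threshold). The window configuration is a free choice; the Gaussian
  11×11 window is the reference configuration in the original SSIM
  literature, and a uniform window of any size (including the whole
  image) is available for verification against single-window statistics.

Manual curation of blurred or empty frames is replaced by an optional
variance-of-Laplacian sharpness score with a user cutoff, disabled by
default, since the original step was human judgement.

## Dataset construction

Order is a hard constraint: per-class **test extraction first** (default
20 images per (identity, view) class), then balancing, then the 8:2
train/validation split. Augmented images inherit nothing from test —
test rows are excluded both as balancing output and as augmentation
sources, so no augmented descendant of a test image can contaminate
training.

Balancing brings every class to exactly `target_per_class` (default 450)
images: deficits are filled by augmentations of uniformly sampled
originals with uniformly sampled operations; surpluses are reduced by
seeded subsampling without replacement (field data maxing out at 448
never triggers this branch, but the operation must be total).
Augmentation magnitudes are not published anywhere authoritative; we use
rotation ±15°, translation up to 10% of each dimension with edge
reflection, and brightness ×1.25 / ×0.75 with clipping — mild transforms
consistent with visual examples of this preprocessing. The 8:2 split is
stratified per class (plain "random division" would slowly unbalance the
classes the augmentation just balanced).

## The reference classifier

Deep backbones (the published comparisons use MobileNetV3, MobileViT,
ResNet18 and VGG16 at 224×224 with ImageNet pretraining) need GPUs and a
real image corpus; neither belongs in a desk-scale test suite. The
package therefore defines a classifier *contract* — train on a manifest,
predict a valid confidence vector, evaluate to a dump — and provides a
reference backend: multinomial softmax regression on flattened 16×16,
[0,1]-scaled pixels, trained by seeded mini-batch gradient descent on the
cross-entropy from zero initialisation (default 400 epochs, learning rate
1, batch 32; 200 epochs demonstrably underfits the weakest synthetic
views). It is deterministic given its seed, trains in seconds, and its
predictions agree with an independent multinomial fit (`nnet::multinom`)
on separable data — a test, not an implementation dependency. Parameter
counting is exact enumeration of the weight array, `(features + 1) × N`.

The fusion, metrics and policy layers never see anything but confidence
vectors, so swapping in a convolutional backend changes nothing
downstream.

## The synthetic herd

`make_identity_bank()` gives each individual a signature: four sinusoidal
texture components (amplitude, two frequencies, phase) plus an elliptical
body blob (centre, radius). A view renders
`informativeness × (40·texture + 30·blob)` on a mid-gray background and
adds nuisance drawn independently of identity: global lighting offset,
pose translation, a smooth random field, per-pixel noise, and (for B
only) a bright exposure blob emulating the top-down view's uneven natural
lighting. Because nuisance depends only on `(view, frame_seed)`, setting
informativeness to zero makes two individuals render pixel-identically —
the zero-signal limit used in tests.

The default profile fixes informativeness at 1 / 0.85 / 0.72 / 0.55 /
0.55 for S / B / F / L / R with monotonically growing nuisance, chosen
once so that the reference classifier on a 20-identity herd (25 training
and 10 held-out images per class) lands at roughly 1.0 / 0.97 / 0.93 /
0.93 / 0.93 held-out accuracy: above the 0.9 floor that makes the herd a
usable fusion testbed, and ordered S ≥ B ≥ F ≥ {L, R}. No quantitative
separation between real views' informativeness is published — only the
ordering — so these levels reproduce the ordering, not any particular
accuracy table. Two same-specification views (L and R) realise
accuracies up to ~0.04 apart at this herd size, which is the sampling
spread the ordering tests tolerate.

`generate_frame_sequence()` emulates video: each frame after the first
is, with probability `dup_rate`, its predecessor plus sub-threshold
sensor noise (σ = 0.6 intensity levels), and otherwise a fresh render
whose pose/lighting/field/noise nuisance is scaled up by
`scene_strength` (default 4). The multiplier models the fact that
captures seconds apart differ by posture shifts far larger than
within-capture jitter; it is calibrated so planted duplicates and
genuine frames are cleanly separable by both filters (worst-case margins
across views and seeds: unique-frame dHash distance ≥ 7 against the <5
rule, unique-frame SSIM ≤ 0.56 against the 0.7 rule), which is what lets
the dedup tests demand *exact* ground-truth recovery rather than
approximate.

The generator does **not** model: photorealistic animal appearance,
breed differences, occlusion, multi-animal frames, detector errors
(boxes are assumed given), or correlated errors between views. Passing
tests therefore demonstrate the pipeline's correctness and the fusion
arithmetic's behaviour under controlled signal/noise, not field accuracy
on real herds.

## The confidence simulator

`simulate_confidence_vectors()` emulates a trained classifier of known
accuracy $a_v$ without training: the predicted label is the true one
with probability $a_v$, otherwise uniform over the wrong labels (no
confusion structure is published to calibrate against); the predicted
label receives mass $m = 1/N + (1 - 1/N)\,\mathrm{Beta}(c, 1)$ — always
above $1/N$, so the argmax is the predicted label and the empirical
accuracy is exactly $a_v$ in expectation — and the rest is uniform.

The shape $c$ is `concentration` (default 40) for correct predictions
and `concentration/10` for wrong ones. The asymmetry matters: real
softmax classifiers are much less confident when wrong (thresholding
their confidence visibly raises accuracy, and barely 2% of a
well-trained model's predictions fall below 0.9 confidence — the regime
the default reproduces). A correctness-blind simulator would make
confidence thresholds useless and the cascade policy pointless; with the
asymmetry, accepted decisions are enriched for correct ones and the
cascade beats its best single view, as the policy tests verify on 10,000
episodes.

## Runtime policies

Single camera: accept at top-1 confidence ≥ `tau_accept` (0.9); pool
predictions in `[tau_reject, tau_accept)` and accept a label once it
holds a strict majority of at least `min_votes` = 2 pooled entries
(the minimum pool size for "majority of the images" is not canonical;
two concordant votes is the smallest decisive pool and is configurable);
discard below `tau_reject` (0.7). A hard cap (`max_images`, default 5)
bounds the episode — an uncapped reshoot loop is unusable — and an
exhausted episode returns the modal pooled label (ties to the higher
mean confidence) or the highest-confidence prediction seen, flagged
rather than silent, because downstream systems need a total function. A
confident image arriving mid-vote short-circuits the pool: the 0.9 rule
declares it trustworthy on its own.

Multi camera: views are added in `view_order` (S, B, F, then L, R — the
face views' relative order is a free choice), re-fusing all collected
vectors through the weighted fusion after each addition and accepting as
soon as the fused confidence reaches `tau_accept`. Missing views are
skipped and logged. Episode cost is images consumed × per-image
classifier cost, which is the right proportionality because fusion
arithmetic is negligible next to a forward pass.

## Numerical choices

* Bilinear resampling maps output pixel centres by
  `src = (i + 0.5)·scale − 0.5` with border clamping; identity-size
  resizes are pixel-exact, which the ROI-crop tests rely on.
* Grayscale conversion uses ITU-R BT.601 luminance.
* Table aggregation rounds half *up* to two decimals
  (`round_half_up()`), matching how two-decimal accuracy tables are
  conventionally printed; base R's round-half-to-even would disagree on
  exact .005 cases (e.g. 99.955 → 99.96, not 99.95).
* Per-class zero-division in precision/recall scores 0 for that class —
  conservative, and rare on balanced test sets.
* Thresholded accuracy removes sub-threshold samples from numerator and
  denominator both; at threshold 0 it is exactly plain top-1 accuracy.
* All randomness flows from explicit seeds through `seed_from()`, which
  hashes a stage/class/episode key into a decorrelated 31-bit sub-seed;
  every generator, split, training run and episode log is reproducible
  from one master seed.

## Problem sizes used in the shipped checks

The test suite and the acceptance script run at: 20 identities × 5 views
(700 images per view) for classifier ordering; 54 identities × 5 views
at manifest level (no pixels) for dataset geometry, which reproduces the
published 5,400-image test set and 121,500-image balanced training set
exactly; 10,000 draws for simulator calibration, three-view fusion and
cascade episodes; 40–50-frame sequences across all five views for
deduplication; and 1,000 randomized cases for the fusion oracle. These
sizes were chosen so the whole suite completes in well under a minute on
one CPU while keeping binomial confidence intervals tight enough for the
claims being tested.

## Known limitations

* The reference classifier is linear in pixels; it calibrates the fusion
  testbed but says nothing about deep-backbone accuracy on real imagery.
* Simulated wrong predictions are uniform over wrong labels; real
  confusion is structured (similar animals confuse each other), which
  would make voting slightly more error-prone than simulated here.
* View confidences are simulated independently per view; real multi-view
  errors correlate (e.g. poor lighting degrades several cameras at
  once), so real cascades will gain less from added views than the
  independent model suggests.
* The detector stage (locating the animal in the raw frame) is out of
  scope; the package consumes pre-cropped regions or externally supplied
  boxes.
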