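---
title: "ccfocus: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ccfocus: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The diagnostic problem

Complete agenesis of the corpus callosum (CC) is among the more consequential
fetal CNS malformations detectable by prenatal ultrasound. The CC appears in
the midsagittal plane as a slender hypoechoic (dark) band under the bright
falx; it occupies only a few percent of the cranial field, and its absence is
often read indirectly — through the upward displacement of the third
ventricle, dilation of the lateral ventricles, and distortion of the cavum
septi pellucidi. Reading these signs is operator-dependent, and the two
informative planes (midsagittal and transventricular/axial) are rarely
equally interpretable in a given fetal position.

`ccfocus` implements a two-stage framework for this problem: (1) a
region-of-interest (ROI) stage that localizes the CC and its neighbouring
landmarks and crops an expanded patch around them, and (2) an anatomy-aware
dual-stream classifier (ADFNet) that consumes the paired sagittal/axial ROI
patches, exchanges information between the two streams mid-network, and
fuses the pooled features with a learned per-case view weighting before a
softmax head. Because clinical data cannot ship with a package, every stage
is exercised end-to-end on a synthetic speckle phantom whose anatomy encodes
exactly the signs above.

## The phantom generator

The generator is first-class, tested code, not a fixture. Each case renders
the same latent anatomy into two planes:

* a bright elliptical skull outline (intensity 235) with a 6 px ring;
* parenchyma at mean 90;
* in the sagittal plane, a bright falx/pericallosal arc (200) and — in
  normal cases only — the hypoechoic CC band (intensity 40) drawn as an
  annulus arc of thickness 6 px beneath it;
* a cavum septi pellucidi and a third ventricle (dark, midline);
* lateral ventricles with bright walls; in the axial plane these are the
  paired anterior horns flanking a straight midline echo.

Agenesis cases omit the band, displace the third ventricle upward by 25 px
(into the region the cavum/CC complex normally occupies), and dilate the
ventricle axes by a factor 1.6 — the indirect signs the classifier is meant
to exploit. Speckle is multiplicative gamma noise with shape equal to the
number of looks (default 12, giving a coefficient of variation of about
0.29 on flat tissue), the standard fully developed B-mode statistic. A
per-case random similarity pose (rotation up to 10 degrees, translation up
to 10 px) is applied analytically: pixels are inverse-mapped into the
canonical frame and the anatomy predicates evaluated there, so images and
ground-truth masks are exact rather than resampled, and tight ground-truth
boxes come directly from the rendered masks.

Default study conditions, used by the tests and the acceptance script: 300
cases at 20% agenesis prevalence. The prevalence is deliberately higher than
clinical reality (roughly 1 in 4,000 live births) so that a desk-scale
cohort contains enough positive cases to train on; the class-weighted loss
is still exercised because the imbalance is 4:1.

What the phantom does *not* emulate: attenuation and shadowing, probe-angle
anisotropy, gestational-age-dependent anatomy, partial agenesis, and real
speckle correlation lengths. Passing the end-to-end bars therefore
demonstrates that the pipeline is wired correctly and learnable, not that
clinical performance transfers.

## Preprocessing

**Canonicalization.** The two planes are aligned to a shared frame
convention per view: the skull outline is detected by intensity threshold
(default 190), the outermost bright band kept, and an ellipse fitted by
algebraic least squares with one trimming refinement. The similarity
transform maps the fitted center to the image center, the major axis to the
horizontal, and the semi-major axis to a fixed canonical length (0.3984 of
the image width). On phantoms this recovers a known pose within about one
degree and one pixel. Cross-view "alignment" of two orthogonal planes has no
literal geometric meaning, so per-view canonicalization to a shared
convention is the implemented reading.

**Homomorphic filtering.** Speckle is multiplicative, so the filter operates
in the log domain: a Gaussian transfer function attenuates the
high-frequency speckle band (gain 1.0 at DC falling to 0.5 above the
cutoff) and the result is exponentiated and min-max rescaled to [0, 255],
which strictly reduces the coefficient of variation on flat speckle. Two
parameter choices matter and were settled by measurement on phantoms. The
cutoff (0.25 of Nyquist) must sit above the spectral band of the thin
callosal structures — a 6 px band lives near 0.17 of Nyquist, and a 0.1
cutoff despeckles beautifully but erases exactly the anatomy the
classifier needs (end-to-end accuracy collapsed when we tried it). The DC
gain is held at 1.0 because a log-domain DC boost is a gamma expansion:
with the bright skull echo setting the maximum, a gain of 1.5 compressed
all soft-tissue contrast into the bottom of the rescaled range. The
adaptivity consists of applying the filter after canonicalization, which
fixes the anatomical scale the cutoff refers to. All parameters are
exposed.

**Resize.** Aspect-preserving letterbox to 256 x 256 with symmetric zero
padding, bilinear interpolation throughout (border value 0, rotation about
the image center).

**Augmentation.** Training draws, in a fixed order: rotation uniform in
±15 degrees, multiplicative brightness uniform in ±10% with clipping, and an
elastic warp whose displacement field is uniform noise smoothed by a
Gaussian of sigma 8 px and scaled by alpha 32. The order
(rotation, brightness, elastic) is a package choice; the strengths are the
reference settings. Test-time augmentation generates exactly five variants
with the *same* strengths as training (the equal-strength reading of the
protocol) and aggregates softmax vectors by arithmetic mean; the two views
of a variant share one random draw so the pair stays spatially consistent.

## ROI extraction

Boxes are 0-based and half-open, so pixel areas are plain coordinate
differences; IoU is computed on those areas and verified in the tests
against brute-force rasterized counting. The dynamic boundary expansion
moves each box side outward 3–5 px: a fixed value, or "auto" =
`clamp(round(0.05 * max(width, height)), 3, 5)`, which operationalizes
"according to the expected anatomical dimensions" — larger structures get
the larger margin.

The detector is a pluggable interface; any function mapping an image to
detections can stand behind it, and externally produced boxes can be
supplied through the JSON manifest. The shipped baseline is a matched
filter: noise-free canonical-anatomy templates (the dark band, the cavum,
the ventricle horns) scored by zero-mean normalized cross-correlation over a
±20 px search window in the canonicalized, despeckled image. On phantoms the
cc template separates cleanly — normal-case correlations fall above about
0.87 and agenesis-case correlations below about 0.64 — so the cc confidence
threshold is 0.75, the midpoint of the gap; the always-present landmarks use
a permissive 0.3. A missing cc
detection is the expected, diagnostic outcome on agenesis cases, and the
classifier ROI then falls back to the canonical cc location ("where the band
should be"). In both cases the sagittal ROI is the union of the cc box with
the detected cavum and ventricle boxes, mirroring the design intent that the
crop include the indirect landmarks; the axial ROI is the landmark union.
Missing detections score IoU 0 in evaluation.

## The dual-stream classifier

Each view has its own residual CNN stream. The `tiny` backbone used at desk
scale is a 7x7 stride-2 stem plus 3x3 stride-2 max-pool, followed by two
residual stages (widths 16 and 32, one block each, no batch normalization —
plain conv+ReLU blocks train stably at this size under Adam); `resnet18`
instantiates the standard four-stage layout. There is no external
deep-learning dependency: convolution (im2col + GEMM), pooling and all
gradients are implemented in RcppArmadillo, and the backward pass is
verified against central finite differences to 1e-8 relative error.

**Cross-view interaction (CVFIM).** After the penultimate stage (stage 3 of
4 for resnet18, stage 1 of 2 for tiny), each stream is gated by the other:

    F'_sag = F_sag + sigmoid(phi_s(F_cor)) ⊙ F_sag
    F'_cor = F_cor + sigmoid(phi_c(F_sag)) ⊙ F_cor

with independent learned 1x1 convolutions phi_s, phi_c. The update is
applied symmetrically to both streams — the interaction is described as
mutual — and both gates read the pre-exchange maps. The gating equation is
taken as authoritative; the cross-view covariance mentioned alongside it in
prose does not appear in the equation and is not part of the computation.
Zero-initialized phi makes the untrained module an exact x1.5 rescaling
(sigmoid(0) = 0.5), which doubles as the ablation hook: `cvfimMode = "off"`
removes the module, `"fixed"` pins the gates at 0.5.

**Fusion.** Global average pooling per stream, then a learned scalar
per-case coefficient alpha = sigmoid(w·[v_sag; v_cor] + b) forms the convex
combination `alpha * v_sag + (1 - alpha) * v_cor`. Alpha is scalar, not
per-channel: the quantity is summarized clinically as a single per-case
number, and the elementwise product in the fusion equation is read as scalar
broadcast. (The alternative prose reading — concatenate then pool — is not
implemented; the equation pools per view first.) Alpha is logged per case.
On phantoms the trained gate typically settles below 0.5, i.e. the axial
stream dominates: the dilation and displacement signs survive ROI cropping
in the axial plane most robustly.

**Input normalization.** ROI patches are per-image standardized (zero
mean, unit variance) before entering the streams. The crops are mostly dark
tissue, and with a fixed 1/255 scaling their low mean and variance leave
first-layer activations — and hence early gradients — small, which at the
fixed reference learning rate stretches the initial training plateau past a
desk-scale epoch budget on some initializations. Standardization makes the
activation scale independent of crop brightness; the fixed 1/255 scaling
remains available as a configuration option.

**Head and loss.** A 512-unit ReLU layer with dropout 0.5 (train mode only)
and a 2-unit softmax output. The loss is class-weighted cross-entropy with
w_normal = 1 and w_agenesis = N_normal / N_agenesis (about 8.64 at the
reference 311/36 training counts); batches normalize by the summed weights
of the labels present, so all-ones weights reduce exactly to mean
cross-entropy. Optimization is Adam (lr 1e-3, betas 0.9/0.999, batch 32)
with early stopping on a stratified 10% validation split of the training
set (patience 5 by default; the monitored quantity is validation loss).
Training splits are patient-level and stratified, with per-class quotas by
largest-remainder apportionment so a 496-case cohort at 70% yields exactly
347 = 311 + 36 training cases.

## Interpretability

Grad-CAM++ is computed per view per class at each stream's final
convolutional stage (pre-pooling, post-exchange), using the standard
first/second/third-order combination under exponential-score smoothing:
alpha = g² / (2g² + sum(A)·g³), channel weight w_k = sum(alpha · relu(g)),
map = relu(sum_k w_k A_k), bilinearly upsampled and min-max normalized to
[0, 255]. An identically zero rectified map is returned as all zeros, not an
error. On a hand-built model whose class score is the spatial mean of one
activation channel, the map reduces to a positive rescaling of that channel
(the closed-form test). Heatmap values are banded on the 0–255 signal
scale: decisive above 220, high in (200, 220], perceptible in [100, 200],
background below 80; the unassigned gap [80, 100) maps to a distinct "low"
band rather than being forced into a neighbour.

When the pipeline computes maps on letterboxed ROI patches it passes the
content region to the attribution call: the zero padding carries no image
signal, and convolution responses at the content/padding boundary would
otherwise dominate the normalized map (we observed exactly that — a hot
band sitting in the padding). Attribution is therefore reported over the
image content only.

The phantom localization check asks that at least half of the top-decile
heatmap mass on agenesis cases fall inside the informative ground-truth
regions (displaced third ventricle and ventricle walls, dilated by 5 px),
averaged over both views' maps per case — both planes carry the indirect
signs, and the per-view maps are the unit of interpretation. On trained
phantom models the axial map concentrates almost entirely inside those
regions; the sagittal map splits its mass between them and the
superior-arc region where the band is missing — a direct sign that
region union does not include.

## Evaluation and collaboration

Agenesis is the positive class. Confusion-derived metrics flag (rather than
propagate) zero denominators; balanced accuracy is exactly the mean of
class-wise sensitivity and specificity. AUC uses the tie-aware Mann-Whitney
formulation — identical to trapezoidal integration for distinct scores and
well-defined under ties — and is cross-checked in the tests against
exhaustive pair counting and against pROC. The decision threshold is 0.5,
boundary inclusive toward agenesis (the safer screening direction).

Clinician-AI fusion maps a reading (diagnosis, confidence in [0, 1]) to an
agenesis probability — confidence if the diagnosis is agenesis, otherwise
1 − confidence, the sign convention the fusion formula needs but does not
state — and combines it with the AI probability at 0.7/0.3 (AI-dominant,
junior readers) or 0.5/0.5 (balanced, senior readers). The reader study
itself cannot be reproduced without clinicians; a simulation harness draws
independent correct/incorrect outcomes at stated accuracies with calibrated
confidences (uniform in [0.7, 1] for the asserted class) and compares
AI-alone, clinician-alone and fused accuracy.

## Problem sizes and numerical choices

The end-to-end study in the tests and the acceptance script uses 300
phantom pairs, the tiny backbone at 256 x 256 input, and at most 10 epochs
with patience 3 — sizes chosen so a complete run finishes in minutes on a
single CPU while leaving a comfortable margin over the learnability bars
(held-out accuracy at least 0.90, AUC at least 0.95). Reproducibility is
strict: every stochastic operation takes an explicit seed derived from one
master seed via an integer hash, RNG state is restored after each seeded
operation, and identical (config, seed) pairs produce bitwise-identical
reports. Probabilities are clamped at 1e-12 inside the loss; softmax
subtracts the max logit; Grad-CAM++ guards its denominator at 1e-12;
min-max rescales return the input unchanged when the range is below 1e-9.

## Known limitations

* The phantom is a geometric emulation; none of the acceptance bars speak
  to clinical data.
* The matched-filter baseline detector assumes canonicalization succeeded
  and structures near their canonical locations; it does not handle the
  dilated-ventricle template mismatch beyond a lower IoU, and it is not a
  substitute detector interface consumer would use on real images — a
  trained detector's boxes can be plugged in via the manifest.
* `resnet18` from-scratch training at desk scale is supported but slow in
  pure-R + BLAS terms; the `pretrained` hook accepts a parameter file but no
  weights are shipped or downloaded.
* Elastic deformation and rotation use bilinear interpolation with zero
  borders; repeated augmentation slightly erodes image borders, which is
  irrelevant for centered cranial content.
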