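# ccfocus

Two-stage detection of fetal corpus callosum (CC) agenesis from paired-plane
cranial ultrasound, exercised end-to-end on a synthetic speckle phantom.

The corpus callosum appears in the midsagittal plane as a thin hypoechoic
band under the bright falx; complete agenesis is read both from the band's
absence and from indirect signs — an upwardly displaced third ventricle and
dilated lateral ventricles — that are often clearer in the axial plane.
`ccfocus` is aimed at researchers in automated prenatal imaging who need a
fully reproducible, dependency-light reference implementation of this
detection-then-classification paradigm:

1. **ROI extraction** — the skull outline is fitted and each view
   canonicalized to a shared frame, speckle is suppressed by homomorphic
   filtering, anatomical structures are localized (a pluggable detector
   interface with a matched-filter baseline), and the detected boxes are
   enlarged by a *dynamic boundary expansion* of 3–5 px so the crop includes
   the cavum septi pellucidi margins and ventricular walls.
2. **ADFNet classification** — an anatomy-aware dual-stream residual CNN.
   After the penultimate stage the streams exchange information through a
   sigmoid-gated residual module,

       F'_sag = F_sag + σ(φ_s(F_cor)) ⊙ F_sag,
       F'_cor = F_cor + σ(φ_c(F_sag)) ⊙ F_cor,

   with independent 1×1 convolutions φ. Globally pooled features are fused
   by a learned per-case coefficient α ∈ (0,1),

       F_fused = α · GAP(F_sag) + (1 − α) · GAP(F_cor),

   and classified by a 512-unit MLP with softmax. Training uses
   class-weighted cross-entropy (w_agenesis = N_normal / N_agenesis ≈ 8.64
   at the reference 311/36 cohort counts), Adam (lr 1e-3, batch 32),
   patient-level stratified 70/30 splitting, and five-variant test-time
   augmentation (±15° rotation, ±10% brightness, elastic σ=8 α=32).

Interpretability comes from per-view Grad-CAM++ heatmaps banded on the
0–255 signal scale (decisive >220, perceptible 100–200, background <80),
and a clinician–AI collaboration module fuses AI probabilities with reader
confidences at 0.7/0.3 (junior) or 0.5/0.5 (senior) weights.

The entire CNN engine (im2col convolution, backprop, Adam, Grad-CAM++) is
implemented in R/RcppArmadillo — no Python, GPU, or external deep-learning
framework — and every stochastic step is seeded, so runs are
bitwise-reproducible.

## Worked example

```r
library(ccfocus)

# one phantom case per class
cfg  <- phantomConfig()                       # 256x256, 12-look speckle
case <- generateCase(cfg, "agenesis", seed = 7)
case
#> CasePair case_seed7 [agenesis], 256x256, structures:
#>   sag{lateral_ventricle_anterior_horn,cavum_septi_pellucidi,third_ventricle}
#>   ax{lateral_ventricle_anterior_horn,cavum_septi_pellucidi,third_ventricle}
# (normal cases additionally carry the sagittal "cc" box)

# detect structures in the canonicalized, despeckled sagittal view
det <- matchedFilterDetector("sagittal", cfg)
pv  <- preprocessView(generateCase(cfg, "normal", seed = 11)@sagittal, det)
pv$detections[[1]]
#> Detection cc conf=0.883 BoundingBox [84,173) x [86,120), area 3026 px

# the IoU of that detection against the generator's ground truth
bb <- mapBoxThroughAffine(pv$detections[[1]]@box, pv$transform,
                          c(256, 256), inverse = TRUE)
iou(bb, gtBoxes(generateCase(cfg, "normal", seed = 11), "sagittal")$cc)
#> [1] 0.8385093

# class weights at the reference cohort counts
computeClassWeights(311, 36)$w_agenesis
#> [1] 8.638889

# a complete scaled-down study: 300 phantom pairs at 20% prevalence,
# tiny backbone, at most 10 epochs (about 10 minutes on one CPU)
rep <- runPipeline(runConfig(
  nCases  = 300,
  phantom = phantomConfig(prevalence = 0.2),
  network = networkConfig("tiny"),
  train   = trainConfig(maxEpochs = 10, earlyStopPatience = 3, seed = 1),
  seed    = 7), outDir = "run")
rep$metrics[c("accuracy", "auc", "balanced_accuracy")]
#>   accuracy auc balanced_accuracy
#> 1        1   1                 1
```

The held-out accuracy/AUC say the phantom task is cleanly learnable by the
dual-stream architecture; `rep$detection` reports per-structure mean IoU of
the baseline detector (cc ≈ 0.87), and `rep$explain$localization` the
fraction of top-decile Grad-CAM++ mass falling inside the informative
(third-ventricle / ventricle-wall) ground-truth regions on agenesis cases.

A thin command-line wrapper over the same functions lives at
`inst/scripts/ccfocus.R`:

```sh
Rscript inst/scripts/ccfocus.R simulate --n 50 --prevalence 0.2 --seed 1 --out phantoms
Rscript inst/scripts/ccfocus.R train    --in phantoms --out run --epochs 5
Rscript inst/scripts/ccfocus.R predict  --checkpoint run/checkpoint.json --in phantoms --out preds.csv
Rscript inst/scripts/ccfocus.R evaluate --preds preds.csv --out report.json
```

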