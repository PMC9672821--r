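---
title: "Models and methods behind strokefate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind strokefate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its science: the forward
model of the synthetic phantom, the processing conventions, the
statistical and learning machinery, and the numerical decisions taken
where the underlying methodology leaves choices open. It states no
empirical result that the test suite or `scripts/acceptance.R` does not
itself compute.

## 1. The perfusion model

CT perfusion interprets each voxel's contrast enhancement as the
convolution of an arterial input function (AIF) with a flow-scaled
residue function,

$$C(t) = \big(a \circledast \mathrm{CBF}\,R\big)(t),$$

where $R(t)$ is the fraction of tracer remaining in the voxel $t$
seconds after arterial arrival, $R(0^+)=1$, and $\int R = \mathrm{MTT}$.
The central volume theorem links the parameters:
$\mathrm{CBV} = \mathrm{CBF}\cdot\mathrm{MTT}$. `Tmax` is the time of the
maximum of the deconvolved residual curve $k(t)=\mathrm{CBF}\,R(t)$; it
aggregates bolus delay and dispersion and is the parameter clinical
threshold rules act on.

Deconvolution is ill-posed; the package regularises it with the
block-circulant (delay-insensitive) SVD: the padded AIF (padding factor
2) forms a circulant matrix whose singular values below a fraction
(default **0.15**) of the largest are discarded before inversion.
Truncation low-passes the estimate: sharp features of $k$ — in
particular the peak that defines CBF — are systematically attenuated.
That bias is a property of the method, not a defect of the
implementation, and it shapes several phantom design choices below.

Parameter-map conventions (`parameterMaps()`): CBF is the raw maximum of
$k$ (negative side lobes are kept by default; clipping is available via
`clipNegative`), `Tmax` its sample-aligned argmax, CBV the ratio of curve
integrals $\int C/\int a$, and MTT = CBV/CBF wherever CBF exceeds a
reliability tolerance (`cbfTol`, default $10^{-6}$; flagged voxels carry
MTT 0 and are marked in the `lowFlow` attribute). CBF and CBV stay in
relative units — no hematocrit or tissue-density scaling is applied,
since all downstream use is voxelwise learning and thresholding, which
are invariant to a global scale.

## 2. The synthetic phantom

The phantom exists so that every stage has a ground truth. It emulates:

* **geometry** — concentric ellipsoids: a 1000 HU skull shell, a
  subarachnoid CSF gap (10 HU), brain tissue (35 HU) and ventricles
  (5 HU), on a default grid of 64 × 64 × 8 voxels at 3 × 3 × 5 mm,
  48 frames at 1.8 s. The CSF gap is anatomically motivated and keeps
  the blurred skull out of the brain rim during threshold-based masking.
* **hemodynamics** — normal tissue CBF 0.6 (relative), MTT 4 s, Tmax
  4 s. A lesion ellipsoid with severity $s$ falling linearly from core
  to boundary degrades the maps: CBF × (1 − 0.7 s), MTT × (1 + 1.5 s),
  Tmax + 8 s·s. Lesion volumes are drawn per treatment arm from
  log-normal distributions matching the reference cohort's arm means and
  standard deviations (IA 55.6 (74.4) ml, IV 117.5 (134.9) ml), and the
  default cohort is 145 patients split 102 IA / 43 IV.
* **curves** — the continuous convolution $a \circledast \mathrm{CBF}R$
  evaluated by FFT on an 18× supersampled grid and read off at the frame
  times. A grid-resolution discrete convolution would violate the
  central volume theorem by ~20% at MTT 4 s and dt 1.8 s, so the
  supersampled quadrature is used instead.
* **residue family** — a smooth-rise residue: a $\sin^2$ ramp from 0 to
  exactly 1 over a rise time $\tau$ = 3 s (bolus dispersion in the
  feeding vasculature), then an exponential tail with scale
  MTT − τ/2 so that $\int R = \mathrm{MTT}$ holds exactly. The argmax of
  $R$, delay + τ, is the voxel's Tmax ground truth. A pure delayed
  exponential (jump discontinuity at arrival) was rejected during
  design: its discontinuous rise is unrecoverable by truncated-SVD
  deconvolution from 1 s samples — CBF errors of 20–40% for any AIF
  width — which would make the phantom useless for validating the
  deconvolution stage. Dispersed (smooth) residues are also the more
  physiological choice.
* **AIF** — a peak-normalised gamma-variate, $t_0$ = 10 s, shape 2,
  scale 1 s, amplitude 10 HU. Compact relative to clinical boluses
  (full width of roughly 3 s rather than 5–10 s); the width was chosen,
  before any acceptance measurement was frozen, so that the truncation
  at 15% leaves enough spectrum for the recovery contract of the
  deconvolution stage (CBF within 15%, Tmax within one sample on
  noise-free data) to be attainable at all.
* **noise** — additive i.i.d. Gaussian in HU (default σ = 2; the
  scaled-down learning experiments use a low-noise arm at σ = 0.5).
  Real CTP noise is correlated, dose-dependent and structured; this
  suffices for method testing but means phantom results say nothing
  about photon-starvation artifacts.
* **follow-up infarct** — per voxel, a logistic link
  $p = \mathrm{plogis}\!\big(3\,(T_{max}-6) + 3\,(0.35-\mathrm{CBF})\big)$
  thresholded against a spatially smoothed uniform field, giving a
  focal, spatially coherent but stochastic target. Healthy tissue
  (Tmax 4 s) has a per-voxel infarct probability of ~0.1%; the
  transition is ~1.3 s wide in Tmax. With `infarctSlopeTmax = Inf` the
  link degenerates to the deterministic rule Tmax > 6 s, which the test
  suite uses as an exactness oracle.

Not emulated: motion, beam hardening, partial-volume mixtures,
hemorrhage, arterial voxels (the AIF is a known model, standing in for
the automatic AIF selection of clinical pipelines, which is out of
scope), and any real anatomical variability. Passing tests on the
phantom therefore demonstrate correctness of the algorithms under their
own forward model — not clinical performance.

Every patient is a pure function of `(cohortSpec, index)`: the per-patient
seed derives deterministically from the master seed, so cohorts are
bit-reproducible and never need to be stored.

## 3. Preprocessing conventions

* **Baseline**: mean of the first three frames; subtracted from every
  frame to form the CTC.
* **Motion correction** is a pass-through hook (`motionCorrect()`), since
  the phantom is motion-free and rigid registration is standard
  machinery rather than part of this package's contribution.
* **Resampling to 1 s** uses a least-squares cubic B-spline fitted per
  voxel with knots every **1.5 input frame intervals**. A coarser knot
  spacing (2 intervals) was measured during design to dominate the
  whole-chain CBF error (~30% versus ~10%), so the tighter spacing is
  the default; it still reproduces polynomials exactly and attenuates
  frame-to-frame noise.
* **Brain mask**: normalised Gaussian smoothing (σ = 1 voxel in-slice,
  none across slices; the smoothing is divided by the smoothed support so
  zeroed surroundings do not drag the tissue edge down — this also makes
  the mask exactly idempotent on masked input), thresholding to the open
  interval (1, 100) HU, in-slice 5 × 5 erosion, largest 3D connected
  component (6-neighbourhood), in-slice 5 × 5 dilation. Morphology is
  delegated to EBImage with explicit zero padding at the grid border.
* **Hemispheres**: the brain mask is split at the midsagittal plane of
  its bounding box; "left" is the lower x-index half (radiological
  convention), and the plane column of an odd-width box goes left. The
  published fissure-detection method used clinically is out of scope.

## 4. Tensor preparation

Contrast arrival is the first frame whose mean in-mask attenuation
exceeds **115%** of the in-mask baseline mean — evaluated on the raw
series, where "baseline enhancement" is meaningful. The CTC window of
**32** samples is centred on the peak mean intensity within **40 s**
after arrival, with the peak at 0-based window position 16 (window
[p−16, p+15]; the parity is a documented convention, as "centred" does
not determine it). If no frame qualifies, the global mean-intensity peak
is used and a warning logged. Residual curves carry no bolus delay and
are cropped to the first 32 samples. Out-of-range window positions are
filled with the per-voxel mean of the first or last three existing
frames.

Hemisphere tensors are masked, cropped to the in-slice bounding box and
padded symmetrically (ties toward the leading edge) to a configurable
in-slice shape — 480 × 320 at 0.45 mm for clinical geometry, 32 × 64 or
96 × 64 for the desk-scale phantom.

Standardisation is z-scoring with statistics frozen on the training
split; spatiotemporal inputs (CTC/RC stacks) share one mean/sd pair
across all timepoints, parameter-map stacks one pair per channel.
Statistics are pooled over entire prepared tensors (padding included),
which keeps the transform identical between training and inference.
Constant features are epsilon-guarded with a warning.

## 5. Predictors

**Tmax thresholding** and its leave-one-out threshold selection operate
on a grid read as (0, 24] s in 0.2 s steps — exactly 120 values; the
nominal "0 to 24 s" range arithmetically contains 121 inclusive values,
and the degenerate 0 s threshold is the one dropped. Ties in the
leave-one-out mean Dice resolve to the smallest threshold (`which.max`
semantics), and the held-out patient's own Dice row never participates.

**The random decision forest** is a regression forest (ranger backend,
100 trees, per-tree instance fraction r = 0.5 without replacement) over
the four parameter maps; its averaged tree output is the probability
map. Balancing is per-patient stratified undersampling: all
minority-class voxels plus an equal random sample of the majority class,
pooled across the training patients. Patients lacking one class
contribute nothing (the forest itself requires both classes overall).
Trees are scale-invariant, so the forest consumes unstandardised maps.
Its binarized predictions optionally pass the noise filter: in-slice
3 × 3 closing, then 3D components (6-neighbourhood) of fewer than 10
voxels removed — "fewer than" strictly, so a 10-voxel component
survives.

**Deep models.** All four share one UNet trunk (default depth 4 with 64
base filters, doubling per level; zero-padded 3 × 3 convolutions, ReLU,
2 × 2 max pooling, nearest-neighbour upsampling with skip
concatenation, 1 × 1 two-channel softmax head; batch normalisation is
off). The temporal variants replace only the input layer by a
per-voxel temporal block with a single weight set shared across voxels:

* *simple*: three un-padded convolution pairs (32, 16, 8 filters, kernel
  3, ReLU) with factor-2 max pooling between pairs — the temporal axis
  collapses 32→30→28→14→12→10→5→3→1, leaving eight features;
* *causal*: five dilated causal convolutions (8 filters, kernel 2,
  dilations 1, 2, 4, 8, 16); only the last output element, whose
  receptive field is exactly 1 + (1+2+4+8+16) = 32, is retained.

The layers, backpropagation and the Adam optimiser are implemented in
the package (R drivers over RcppArmadillo kernels); there is no deep
learning framework dependency. Two exact computational shortcuts are
used and property-tested against the reference path:

* because only the causal block's last element is retained, its
  dependency cone evaluates as five kernel-2 *stride-2* convolutions
  (32→16→8→4→2→1) with the same weights — identical retained features,
  about a fifth of the work;
* out-of-hemisphere pixels all carry the same constant (zeroed, then
  standardised) curve, so their temporal features are computed once and
  broadcast, and their gradient contribution is the backward pass with
  their output gradients summed.

Training: Adam with α = 0.0005, β₁ = 0.975, β₂ = 0.999, ε = 0.08; soft
Dice loss $1 - (2\sum pg + s)/(\sum p + \sum g + s)$ averaged over the
slices of a batch, smoothing s = 1 during training (s = 0 only in
analytic tests, where the empty-truth case is rejected as undefined).
Slices without infarct voxels are omitted from training; the validation
loss is computed over non-empty validation slices for the same
definedness reason (an interpretation — the underlying methodology does
not state the validation handling). Early stopping halts after eight
epochs without validation improvement and restores the best epoch's
weights. Kernel weights use He-normal initialisation; the terminal bias
is initialised to a background prior logit (softmax ≈ 5% foreground),
the standard remedy for extreme class imbalance that otherwise spends
the first epochs unlearning a uniform prediction. Batch size (default
8; the scaled-down experiments use 4, which doubles the optimisation
steps per epoch at unchanged cost) and the epoch cap (default 500) are
free choices; with fixed seeds a training run is reproducible
end-to-end.

## 6. Evaluation harness

Folds are assigned once per `(cohort, seed)` and reused by every method:
five near-equal test folds per treatment arm; within each fold, 15% of
the training portion is sampled as validation, giving the nominal
68/12/20 split. Metrics:

* **Dice** $2|P\cap G|/(|P|+|G|)$, with the both-empty case defined as 1
  (tiny phantom lesions can vanish under filtering; clinical data never
  meets this case);
* **ROC** per patient from 100 binarization thresholds (0.00–0.99 in
  0.01 steps), restricted to ipsilateral-hemisphere voxels, anchored at
  (0,0) and (1,1), AUC by trapezoid; the method-level curve is the
  pointwise mean of patient curves, and the method-level AUC statistic
  averages per-patient AUCs (the alternative — AUC of the averaged
  curve — is a defensible reading; per-patient averaging matches how the
  Dice and volume statistics are formed). Patients with single-class
  truth are flagged `NA` and excluded from means. For Tmax thresholding,
  which has no probabilistic output, the map is scaled by its 24 s grid
  ceiling into [0, 1] as the ROC surrogate.
* **binarization** at each patient's leave-one-out optimal threshold on
  the inclusive 0–1 grid in 0.01 steps (101 values — here the inclusive
  reading is kept, in contrast to the Tmax grid, where the stated count
  of 120 forces the exclusive one);
* **volume errors** signed (positive = overestimation) and absolute, in
  ml.

`runExperiment()` evaluates every requested model on identical folds,
with and without the morphological noise filter, and
`correlateFeatures()` computes Spearman rank correlations between
learned temporal feature maps and the four parameter maps over pooled
in-mask voxels.

## 7. Problem sizes

The package's own experiments run at desk scale, chosen once as
realistic for a complete, reproducible analysis on a single CPU: the
default phantom grid is 64 × 64 × 8 × 48; the end-to-end learning
experiment uses a 20-patient low-noise arm, a reduced UNet (depth 3, 16
base filters, 32 × 64 hemisphere tiles), batches of 4, and at most 26
epochs; the determinism check uses 4 patients and 2 folds. The clinical
geometry (480 × 320 at 0.45 mm, depth-4/64-filter UNet) is fully
supported by the same code paths but is not exercised by the tests.

## 8. Known limitations

* Phantom realism is deliberately minimal (Section 2); absolute
  performance numbers on the phantom do not transfer to patients.
* The AIF is known by construction; automatic AIF selection and
  hemispheric-fissure detection are out of scope, replaced by the model
  input and the midsagittal split.
* CBF/CBV are relative; no absolute quantification.
* The delay-insensitive deconvolution inherits the usual
  truncated-SVD biases (peak attenuation, mild oscillation); the
  phantom's recovery contract quantifies them rather than removing them.
* Repeated-measures group statistics (ANOVA families, post-hoc
  corrections) are intentionally not reimplemented; the harness exports
  tidy per-patient CSVs for external statistical software.
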