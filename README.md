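# strokefate

Voxelwise prediction of the follow-up infarct lesion in acute ischemic
stroke from baseline 4D CT perfusion (CTP) imaging — the full chain from
the raw spatiotemporal series to evaluated lesion predictions, plus a
synthetic digital CTP phantom with known hemodynamic ground truth so that
every stage is testable without clinical data.

## What it does

CTP acquires a time-resolved CT series while an iodinated contrast bolus
passes through the brain. Each voxel's **concentration-time curve (CTC)**
`C(t)` is modelled as the convolution of an **arterial input function
(AIF)** `a(t)` with the flow-scaled **residue function**

```
C(t) = (a ⊛ k)(t),   k(t) = CBF · R(t),
```

where `R(t)` is the fraction of tracer still inside the voxel `t` seconds
after arrival. Deconvolving `C` by `a` with a block-circulant SVD
(singular values below 15% of the largest are truncated) yields the
residual curve `k`, from which the standard perfusion parameters follow:

```
CBF  = max_t k(t)            Tmax = argmax_t k(t)
CBV  = ∫C / ∫a               MTT  = CBV / CBF
```

On top of the perfusion pipeline, five tissue-outcome predictors map
acute imaging to the voxelwise probability of infarction on follow-up:

* **Tmax thresholding** — `Tmax > θ`, with `θ` chosen per patient by
  leave-one-out maximisation of the mean Dice over the other patients of
  the same treatment arm (120 candidate thresholds, (0, 24] s at 0.2 s);
* **random decision forest** — 100 regression trees over the four
  parameter maps, per-patient stratified undersampling for class balance,
  optional in-slice 3×3 closing with removal of components under 10
  voxels;
* **Param-UNet** — a 2D UNet over the four parameter maps with zero-padded
  convolutions, weak L2 kernel regularisation (0.5e-4) and a two-channel
  softmax head;
* **RC-Simple / RC-Causal / CTC-Causal** — the same UNet fed by a
  trainable temporal block that reduces each voxel's 32-timepoint curve
  (deconvolved residual curves, or raw CTCs) to eight learned features:
  either three pairs of un-padded 1D convolutions (32/16/8 filters,
  kernel 3) with factor-2 max pooling, or five dilated causal
  convolutions (8 filters, kernel 2, dilations 1, 2, 4, 8, 16) whose final
  output element — receptive field exactly 32 — is retained.

Training uses Adam (α = 0.0005, β₁ = 0.975, β₂ = 0.999, ε = 0.08) with the
soft Dice loss, omission of slices without infarct voxels, and early
stopping after eight epochs without validation improvement. Evaluation is
a patient-level fivefold cross-validation per treatment arm (nominal
68% / 12% / 20% train/validation/test), leave-one-out optimal
binarization (thresholds 0–1 at 0.01), Dice, empirical ROC-AUC from 100
binarization thresholds, and signed/absolute lesion volume errors in ml.

The audience is researchers working on stroke tissue-outcome prediction
who want a self-contained, dependency-light reference implementation with
a fully synthetic test bed.

## Worked example

```r
library(strokefate)

# one synthetic patient: raw HU series + ground truth + follow-up infarct
spec <- cohortSpec(nTotal = 5, nIA = 5, nIV = 0, seed = 1, noiseSigma = 0)
p <- genPatient(spec, 1)

bavg  <- baselineAverage(p$series)
brain <- brainMask(bavg)
ctc   <- temporalResample(baselineSubtract(p$series, bavg))  # 1 s grid
aif   <- genAif(p$truth@aif, seq(0, by = 1, length.out = dim(ctc@values)[4]))
maps  <- parameterMaps(bcsvdDeconvolve(ctc, aif), ctc, aif, mask = brain)

sel <- p$truth@cbf > 0 & brain
median(abs(parameterMap(maps, "cbf")[sel] - p$truth@cbf[sel]) / p$truth@cbf[sel])
#> [1] 0.1009339
median(abs(parameterMap(maps, "tmax")[sel] - p$truth@tmax[sel]))
#> [1] 0
```

So on a noise-free phantom the deconvolution chain recovers CBF with a
median relative error of about 10% (the residue peak is low-pass limited
by the 15% singular-value truncation and the 1 s resampling) and the
per-voxel Tmax exactly at the 1 s sampling resolution.

A scaled-down end-to-end experiment (20 synthetic patients, reduced UNet)
runs the whole comparison:

```r
spec <- cohortSpec(nTotal = 20, nIA = 20, nIV = 0, seed = 5, noiseSigma = 0.5)
res <- runExperiment(spec, models = c("tmax", "param_unet", "ctc_causal"),
                     arms = "IA", padShape = c(32, 64), unetDepth = 3,
                     baseFilters = 16,
                     trainCfg = trainConfig(maxEpochs = 30, batchSize = 4))
res$summary
```

`res$metrics` holds one row per patient × model × filtering variant with
Dice, ROC-AUC, threshold and volume errors; `res$summary` the per-model
means and standard deviations.

## Command line

A thin CLI wraps the exported functions:

```sh
Rscript inst/cli/strokefate.R simulate --config cohort.yaml --out DIR --seed 1
Rscript inst/cli/strokefate.R preprocess --in ctp.nii.gz --out DIR
Rscript inst/cli/strokefate.R perfusion --ctc ctc.nii.gz --aif aif.csv --out DIR
Rscript inst/cli/strokefate.R evaluate --config experiment.yaml --out DIR
```

All volumes are NIfTI-1 (`.nii.gz`, voxel spacing in `pixdim[1:3]`, frame
spacing in `pixdim[4]`), manifests and metrics are CSV, configurations
are YAML.

## The methods vignette

`vignettes/strokefate-methods.Rmd` documents the forward model of the
phantom, every processing convention and tunable parameter, the numerical
design of the deconvolution and the network training, and what the
synthetic experiments do and do not demonstrate about clinical data.
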