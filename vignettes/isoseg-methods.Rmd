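---
title: "IsoSeg: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{IsoSeg: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Around six months of age the T1/T2 intensity distributions of gray matter
(GM) and white matter (WM) in infant brain MRI converge — the *isointense*
stage — so voxelwise contrast alone cannot separate the two tissues, and
spatial context has to carry the classification. IsoSeg implements a full
pipeline for four-class segmentation (background, CSF, GM, WM) of
co-registered T1/T2 volumes at this stage:

1. percentile-landmark intensity standardization across records,
2. a four-level U-Net whose 3-D convolutions are factorized into
   in-plane (1×3×3) and across-slice (3×1×1) stages — (2+1)D convolution,
3. a hybrid sparse-cross-entropy + soft-Dice training cost with ADAM and
   best-model checkpointing,
4. leave-one-out cross-validation with a
   sensitivity/precision/Dice/accuracy metric suite and cohort
   aggregation,
5. a synthetic two-modality phantom generator so every stage is testable
   without access-restricted clinical data.

The reference operating point is a cohort of ten records of up to 112
transversal slices of 144×192 pixels at 1 mm³ (the iSeg-2017 training-set
geometry); volumes are processed whole, as a batch of one.

## Intensity standardization

MRI intensities have no absolute scale: acquisition differences show up
as per-record global scale/offset changes. Standardization follows the
percentile-landmark (Nyúl-style) scheme. For each record and modality,
`computeLandmarks()` extracts the 25th/50th/75th percentiles of the
*foreground* distribution (intensities > 0; air excluded), bracketed by
robust outer anchors at the 1st/99th percentiles. All quantiles use
linear interpolation between order statistics (R type 7) — the same
convention validated against the published cohort summary tables by the
acceptance tests. `buildStandardScale()` averages the anchors across the
(training) records; `standardizeIntensity()` applies the piecewise-linear
map sending each record's anchors onto the reference anchors, linear
between anchors, clamped beyond the outer anchors.

Design points worth knowing:

* **Foreground-only mapping.** The map is applied to foreground voxels
  only; exact-zero air stays zero. Mapping background too would move it
  onto the low reference anchor, silently redefining the foreground and
  de-aligning the cohort's landmarks. With foreground preserved, every
  mapped anchor lands exactly on the reference anchor, and the map is
  monotone non-decreasing, so intensity order is never violated.
* **Robust outer anchors and idempotence.** With outer anchors at the
  1st/99th percentiles, the ≤ 2% tail mass outside them is clamped;
  re-standardizing an already-standardized record is therefore the exact
  identity *within* the outer-anchor range, while clamped tail voxels can
  move slightly. Choosing `outer = c(0, 100)` (min/max) makes
  re-standardization the exact identity everywhere, at the cost of
  outlier sensitivity. The default favours robustness.
* **Re-computed landmarks.** Re-estimating landmarks on a standardized
  record reproduces the reference anchors to float-level *relative*
  precision (~1e-6); the residual is quantile-interpolation error across
  the map's breakpoints, not misalignment.
* **No test-set leakage.** Inside cross-validation the standard scale is
  rebuilt per fold from the training records only; the held-out record is
  mapped with its own landmarks onto that training scale.
* **Void filling.** Sporadic missing voxels (validity mask `FALSE`) are
  filled before landmark extraction by `fillMissing()`: each void takes
  the median of the valid voxels in its 3×3×3 neighborhood, iterated
  until no voids remain. The fill is deterministic, local, and
  median-based, so the global histogram is essentially preserved. The
  per-record void fraction is expected to be well under the 20% cap the
  phantom spec allows.
* **Bias-field correction is out of scope**: the target data show little
  intensity inhomogeneity, and no inhomogeneity model is included.

## The (2+1)D U-Net

`archConfig()` describes the network declaratively; `buildModel()` turns
it into an execution plan plus seeded Glorot-uniform weights, so two
builds from the same config and seed are bitwise identical.

The full-scale layout (`archConfig()` defaults):

* **Input** 112×192×144×6 — the two modalities each replicated three
  times (`stackModalities(replication = 3)`), the image-as-RGB convention
  under which two modalities become six channels. `replication = 1`
  (2 channels) is the economical variant used by the reduced profile.
* **Encoder**, four blocks with 65/32/16/8 filters: each block is
  pair → BN → dropout(0.2) → pair → BN → skip tap → 2×2×2 max-pool,
  where *pair* is the (2+1)D factorized unit — a 1×3×3 convolution then a
  3×1×1 convolution, each with its own ELU (α = 1), stride 1, "same"
  zero padding, and the block's full filter count (no intermediate
  channel bottleneck). Feature maps shrink 112×192×144 → 56×96×72 →
  28×48×36 → 14×24×18 → bridge input 7×12×9.
* **Bridge**: two full pairs at 4 filters — pair → BN → dropout → pair →
  BN.
* **Decoder**, four blocks mirroring the encoder (8/16/32/65): 2×2×2
  stride-2 transpose convolution with ELU, concatenation with the skip
  features of the same level, then pair → BN → dropout → pair → BN.
* **Head**: 1×1×1 convolution to 4 channels with softmax; segmentation is
  the per-voxel argmax, ties broken deterministically toward the lowest
  class index.

The slice axis plays the role of the "temporal" axis of the video-style
(2+1)D factorization; the 65-filter top level (not 64) is reproduced
as published.

Because no deep-learning framework is part of the package's dependency
set, the forward pass, backward pass, and ADAM optimizer are implemented
in the package itself, with the dense compute (3-D convolution and its
gradients, the 2×2×2 transpose convolution, max pooling) in C++ via Rcpp
and the elementwise/bookkeeping parts in R. The backward pass is verified
against central-difference numerical gradients to ~1e-9 relative error in
the test suite — an end-to-end guarantee a framework implementation would
not give you for free.

**Batch normalization with a batch of one.** Volumes are processed whole,
so a "batch" is a single volume and batch statistics are per-volume
(instance) statistics. Running-average inference statistics are a poor
fit here: with one optimization step per record they chase
weight-dependent statistics they can never track. IsoSeg therefore
normalizes by the current volume's own per-channel statistics in both
training and inference. Inference stays deterministic (the input defines
its statistics), restored checkpoints reproduce their recorded cost
exactly, and this matches the common choice in batch-of-one medical
segmentation. Epsilon is 1e-3; gains/shifts are trainable.

**Input scaling.** Standardized intensities live on the cohort scale
(hundreds of scanner units). `recordInput(intensityScale = ...)` divides
each modality by the standard scale's high anchor so the network sees
order-one inputs; `runLOOCV()` does this automatically.

**Non-divisible extents.** Four pooling levels require extents divisible
by 16. By default other extents are an error; `predict(padInput = TRUE)`
symmetrically zero-pads to the next multiple and crops the output back.

## Training cost and protocol

The cost is
`0.5 * CE + 0.5 * (1 - mean_c softDice_c)`:
sparse categorical cross entropy (per-voxel −log of the probability of
the true class, clipped below at 1e-7) plus the Dice cost obtained by
subtracting from 1 the soft Dice averaged over all four classes,
including background. Soft Dice for class *c* is
`(2·Σ p_c y_c + s) / (Σ p_c + Σ y_c + s)` with smoothing `s = 1e-6`, so
classes absent from both prediction and truth score ~1. The *reported*
tissue-average F1 instead averages over CSF/GM/WM only
(`tissueAverageF1()`); both conventions are explicit.

Training (`trainModel()`) takes one volume per ADAM step
(learning rate 1e-3 by default; β₁ = 0.9, β₂ = 0.999, ε = 1e-7). At the
end of each epoch the mean training cost is evaluated in inference mode
(dropout off), and the parameters of the lowest-cost epoch are the
returned checkpoint, so re-evaluating a restored checkpoint reproduces
its recorded cost to machine precision. The full-scale protocol is 1000
epochs; there is no data augmentation, no learning-rate schedule and no
early stopping. A `holdoutFraction` option can switch checkpoint
selection to held-out records but is off by default, matching the
training-cost selection rule. In deterministic mode every stochastic
element (initialization, dropout streams) derives from the configured
seed, and fold *k* of cross-validation initializes with `seed + k`, so
results are a function of the seed and the data alone.

`runLOOCV()` runs one fold per record: standardize on the training
records, train a freshly initialized model, evaluate on the held-out
record, and aggregate the per-fold reports.

## Metrics and aggregation

`tissueConfusion()` tallies actual-by-predicted voxel counts. From the
confusion matrix, per tissue τ: sensitivity `TPR = TP/rowSum`, precision
`PPV = TP/colSum`, Dice `DSC = 2TP/(rowSum+colSum)` (the harmonic mean of
TPR and PPV), and overall accuracy `ACC = trace/total` across all classes
including background. Metrics with empty denominators are `NA`, never 0 —
silently zeroing empty classes would bias cohort means. Cohort
aggregation (`aggregateReports()`/`summaryStats()`) reports mean, sample
(n−1) standard deviation, min, linear-interpolation quartiles and max;
those conventions reproduce the published cohort distribution table from
the published per-record values to the printed six decimals, which is how
they were fixed. The published cohort table's own printed mean accuracy
(0.9225) differs from the arithmetic mean of its printed per-record
column in the fifth decimal; IsoSeg computes the true mean and leaves the
discrepancy to the source.

## The phantom generator

`generatePhantom()` builds records that exercise the statistical
structure the method assumes, not anatomical realism:

* **Geometry**: nested background → CSF shell → GM ribbon → WM core from
  a perturbed ellipsoid level set; a low-order harmonic perturbation with
  seeded coefficients makes each record's anatomy unique. The GM/WM
  boundary radius is `3^(1/3)` times the WM radius, so the GM ribbon
  holds about twice as many voxels as the WM core, matching the roughly
  2:1 GM:WM voxel ratio of real records.
* **Intensities**: per-tissue Gaussians on both modalities, with
  CSF/parenchyma contrast inverted between T1 and T2. `gmWmSeparation`
  sets the GM–WM mean gap in units of the within-tissue SD: the default
  0.4 keeps the distributions strongly overlapping (the isointense
  regime, where CSF is easy and GM/WM are hard), while large values
  (e.g. 6) give the well-separated "easy" regime used by the learning
  check. Tissue means default to plausible scanner units
  (T1: CSF 250, parenchyma 610; T2: CSF 850, parenchyma 470; SD 50) and
  are configurable; they are synthetic choices, not estimates from data.
* **Record jitter**: one global affine intensity change (scale 0.8–1.25,
  offset 0–60) per record and modality, the effect standardization must
  undo.
* **Voids**: a small fraction (default 0.5%) of in-brain voxels flagged
  invalid and zeroed, exercising the fill step.

Everything is a deterministic function of the seed; `generateCohort(n)`
uses seeds `seed + 0..n-1`. What the phantom does *not* model: cortical
folding, partial-volume mixtures, Rician noise, bias fields, and
registration error. Passing the pipeline on phantoms therefore
demonstrates mechanical and statistical correctness of the
implementation, not clinical-grade accuracy on real infant MRI.

## Problem sizes used by the shipped checks

The test suite keeps everything desk-scale on one CPU: gradient checks on
4×8×8 grids with 2–3 filters; learning and cross-validation checks on
32×48×32 and 16×32×16 phantoms with the reduced 16/8/4/2 (or 8/4/2/2)
filter profile and two input channels; the architecture audit builds the
full 65/32/16/8 model (weights only) and runs one real forward pass at
reduced filters on a zero-filled 112×192×144×6 input. The learning check
trains 60 epochs on an easy-regime phantom and requires mean tissue
Dice ≥ 0.90 on its training phantom. Full-scale training (1000 epochs,
ten records, 65-filter network) is expressed by the same code paths with
`archConfig()` + `trainConfig()` defaults but is a GPU-scale undertaking
and is not part of the shipped checks, and the published full-scale
accuracy numbers are correspondingly not reproduced here.

## Known limitations

* The hand-rolled convolution kernels are cache-friendly but unblocked
  and single-threaded; full-scale training is out of reach on one CPU.
* Best-model selection on training cost (the published protocol) can
  prefer late epochs on easy problems and overfit quietly on hard ones;
  the holdout option exists but changes the protocol.
* The void filler is a deterministic stand-in for the under-specified
  "histogram-based interpolation" of missing data; any local
  histogram-preserving fill would serve.
* Analyze 7.5 output stores no orientation beyond geometry; NIfTI is the
  preferred interchange format.
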