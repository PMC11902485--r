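# IsoSeg

Four-class tissue segmentation (background, CSF, gray matter, white
matter) of infant brain MRI at the *isointense* stage — the age around
six months when the T1/T2 intensity distributions of gray and white
matter converge and voxelwise contrast alone cannot separate them. The
package is aimed at researchers who need the full method as runnable,
testable code on one CPU: the preprocessing, the network, the training
protocol, the evaluation suite, and a synthetic cohort generator that
replaces the access-restricted clinical data.

## What is inside

* **Percentile-landmark intensity standardization.** Per record and
  modality, the 25th/50th/75th foreground percentiles (bracketed by
  robust 1st/99th anchors) are mapped piecewise-linearly onto the
  cohort-mean anchors (Nyúl-style histogram alignment), after a
  deterministic 3×3×3 neighborhood-median fill of void voxels.
* **A (2+1)D U-Net.** Four encoder levels (65/32/16/8 filters), a
  4-filter bridge, a mirrored decoder and a 1×1×1 softmax head. Every
  3-D convolution is factorized into an in-plane 1×3×3 stage followed by
  an across-slice 3×1×1 stage, each with its own ELU:

      y = ELU(W_t *  ELU(W_s * x + b_s) + b_t),   W_s: 1×3×3,  W_t: 3×1×1

  A 112×192×144×6 input (T1/T2 each replicated ×3) descends through
  56×96×72, 28×48×36, 14×24×18 to a 7×12×9 bridge and returns to a
  112×192×144×4 probability map. Forward, backward and ADAM are
  implemented in the package (Rcpp kernels for the convolutions); the
  backward pass is verified against numerical gradients in the tests.
* **Hybrid training cost.** `0.5·CE + 0.5·(1 − mean soft Dice over the
  four classes)`, one whole volume per optimization step, best-model
  checkpointing at the lowest evaluated training cost, 1000-epoch
  full-scale profile.
* **Evaluation.** Actual×predicted confusion matrices; per-tissue
  sensitivity (TPR), precision (PPV) and Dice (DSC); overall accuracy
  (ACC); cohort aggregation with mean, sample SD and interpolated
  quartiles; leave-one-out cross-validation with per-fold standard-scale
  rebuilding.
* **Phantom cohorts.** Seeded two-modality nested-ellipsoid phantoms with
  a controllable GM–WM intensity separation (isointense by default),
  per-record global intensity jitter, and sporadic voids.

NIfTI-1 and Analyze 7.5 volumes are read/written via RNifti/oro.nifti;
in-memory voxel order is `(slice, row, col)`.

## Worked example

Train the reduced CPU profile (16/8/4/2 filters, two channels) on an
easy-regime 32×48×32 phantom and evaluate it on its training record:

```r
library(IsoSeg)

rec <- generatePhantom(phantomSpec(gmWmSeparation = 6, seed = 101))
std <- standardizeCohort(list(rec))
iscale <- c(max(anchors(std$scales$t1)), max(anchors(std$scales$t2)))
x <- recordInput(std$records[[1]], 1, intensityScale = iscale)

model <- buildModel(scaledArchConfig(2), seed = 1)
tr <- trainModel(model, list(list(x = x, y = std$records[[1]]$labels)),
                 trainConfig(epochs = 40, seed = 5))

pred <- predict(tr$model, x)
evaluateSegmentation(pred$labels, rec$labels)$metrics
```

```
MetricsReport [record record]
       CSF     GM     WM
TPR 0.9499 0.9922 0.9744
PPV 0.8562 0.9665 0.9982
DSC 0.9006 0.9792 0.9861
  ACC (all classes): 0.9860
```

All three tissues exceed 0.90 Dice after 40 epochs (~3 min on one CPU);
98.6% of voxels are labeled correctly. CSF precision is the weakest
number — the thin outer shell borders both air and gray matter — which
mirrors where boundary errors concentrate in real data. The encoder
geometry of the full-scale network can be audited directly:

```r
shapeTrace(archConfig(), c(112, 192, 144))
```

```
         stage slices rows cols
1        input    112  192  144
2  after_pool1     56   96   72
3  after_pool2     28   48   36
4  after_pool3     14   24   18
5 bridge_input      7   12    9
```

The cohort-aggregation conventions (mean, n−1 SD, linear-interpolation
quartiles) reproduce the published distribution table of the method's
per-record benchmarks to the printed six decimals:

```r
tab <- read.csv(system.file("extdata", "iseg2017_reported_metrics.csv",
                            package = "IsoSeg"))
round(aggregateReports(tab[, c("precision", "recall", "f1")]), 6)
```

```
    precision   recall       f1
avg  0.922774 0.922005 0.922052
std  0.007010 0.007890 0.007732
min  0.910571 0.906693 0.907219
Q1   0.918156 0.918036 0.918025
Q2   0.923274 0.922091 0.922208
Q3   0.928504 0.928412 0.928328
max  0.932538 0.932624 0.932568
```

A thin command-line surface over the same functions lives at
`inst/cli/isoseg.R` (`phantom`, `standardize`, `train`, `segment`,
`evaluate`, `crossval` subcommands).

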