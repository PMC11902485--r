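#' @import methods
NULL

# Tissue classes, in label-code order. Code 0 = background.
ISOSEG_CLASSES <- c("BG", "CSF", "GM", "WM")
ISOSEG_TISSUES <- c("CSF", "GM", "WM")

#' IntensityVolume: a single-modality 3-D intensity grid
#'
#' Stores one co-registered MRI modality as a numeric array indexed
#' `(slice, row, col)`, together with voxel spacing (mm per axis), a world
#' origin, and an optional validity mask flagging void voxels (`FALSE` =
#' missing measurement). The slice axis is the axis treated as "temporal"
#' by the (2+1)D convolutions downstream.
#'
#' @slot values numeric 3-D array, `(slice, row, col)`.
#' @slot spacing numeric length-3, mm per axis, strictly positive.
#' @slot origin numeric length-3, mm.
#' @slot mask logical 3-D array of the same extents, or `NULL` when every
#'   voxel is valid.
#' @export
setClass("IntensityVolume",
  representation(values = "array", spacing = "numeric", origin = "numeric",
                 mask = "ANY"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0), mask = NULL))

setValidity("IntensityVolume", function(object) {
  d <- dim(object@values)
  if (length(d) != 3L) return("values must be a 3-D array")
  if (any(d < 1L)) return("all three extents must be >= 1")
  if (length(object@spacing) != 3L || any(!is.finite(object@spacing)) ||
      any(object@spacing <= 0))
    return("spacing must be 3 strictly positive finite values")
  if (length(object@origin) != 3L) return("origin must have length 3")
  if (!is.null(object@mask)) {
    if (!is.logical(object@mask) || !identical(dim(object@mask), d))
      return("mask must be a logical array with the same extents as values")
  }
  TRUE
})

#' MultiModalVolume: channel-stacked network input
#'
#' A 4-D array `(slice, row, col, channel)` holding the replicated T1 and T2
#' channels that feed the segmentation network, plus one label per channel.
#'
#' @slot channels numeric 4-D array, `(slice, row, col, channel)`.
#' @slot channelLabels character, one tag per channel.
#' @slot spacing,origin shared spatial geometry of all channels.
#' @export
setClass("MultiModalVolume",
  representation(channels = "array", channelLabels = "character",
                 spacing = "numeric", origin = "numeric"),
  prototype(spacing = c(1, 1, 1), origin = c(0, 0, 0)))

setValidity("MultiModalVolume", function(object) {
  d <- dim(object@channels)
  if (length(d) != 4L) return("channels must be a 4-D array")
  if (d[4] != length(object@channelLabels))
    return("channel count must equal length(channelLabels)")
  if (length(object@spacing) != 3L || any(object@spacing <= 0))
    return("spacing must be 3 strictly positive values")
  TRUE
})

#' LabelVolume: integer tissue map
#'
#' Voxelwise class codes: 0 background, 1 CSF, 2 GM, 3 WM by default.
#' Used both for ground truth and for predicted segmentations.
#'
#' @slot labels integer 3-D array, values in `0:(nClasses-1)`.
#' @slot classNames ordered class names, first entry = code 0.
#' @slot spacing,origin spatial geometry.
#' @export
setClass("LabelVolume",
  representation(labels = "array", classNames = "character",
                 spacing = "numeric", origin = "numeric"),
  prototype(classNames = ISOSEG_CLASSES, spacing = c(1, 1, 1),
            origin = c(0, 0, 0)))

setValidity("LabelVolume", function(object) {
  d <- dim(object@labels)
  if (length(d) != 3L) return("labels must be a 3-D array")
  if (length(object@classNames) < 2L) return("need at least 2 classes")
  lab <- object@labels
  if (any(lab != round(lab))) return("labels must be integer-valued")
  if (min(lab) < 0 || max(lab) > length(object@classNames) - 1L)
    return("every voxel must lie in {0, ..., nClasses-1}")
  TRUE
})

#' LandmarkSet: per-record intensity landmarks
#'
#' Percentile landmarks of the foreground-intensity distribution of one
#' record/modality: `(low anchor, p25, p50, p75, high anchor)` by default.
#'
#' @slot modality modality tag ("T1", "T2", ...).
#' @slot anchors non-decreasing intensity values at the anchor percentiles.
#' @slot percentiles the percentile list the anchors were computed at,
#'   including the outer anchors (default 1, 25, 50, 75, 99).
#' @export
setClass("LandmarkSet",
  representation(modality = "character", anchors = "numeric",
                 percentiles = "numeric"))

setValidity("LandmarkSet", function(object) {
  if (length(object@anchors) != length(object@percentiles))
    return("anchors and percentiles must have equal length")
  if (length(object@anchors) < 2L) return("need at least 2 anchors")
  if (is.unsorted(object@anchors)) return("anchors must be non-decreasing")
  if (is.unsorted(object@percentiles, strictly = TRUE))
    return("percentiles must be strictly increasing")
  TRUE
})

#' StandardScale: cohort reference intensity scale
#'
#' The cohort-mean anchor intensities a record's landmarks are mapped onto.
#' Strictly increasing by construction; degenerate cohorts are rejected.
#'
#' @slot modality modality tag.
#' @slot referenceAnchors strictly increasing reference intensities.
#' @slot percentiles matching percentile list.
#' @export
setClass("StandardScale",
  representation(modality = "character", referenceAnchors = "numeric",
                 percentiles = "numeric"))

setValidity("StandardScale", function(object) {
  if (length(object@referenceAnchors) != length(object@percentiles))
    return("referenceAnchors and percentiles must have equal length")
  if (is.unsorted(object@referenceAnchors, strictly = TRUE))
    return("referenceAnchors must be strictly increasing")
  TRUE
})

#' ArchitectureConfig: declarative (2+1)D U-Net description
#'
#' @slot levels encoder depth.
#' @slot filtersPerLevel filters per encoder level, top to bottom; the
#'   decoder mirrors them bottom-up.
#' @slot bridgeFilters filters in the bridge block.
#' @slot inChannels,nClasses input channels and output classes.
#' @slot spatialKernel,sliceKernel the two factorized kernel extents.
#' @slot pool pooling extents per level.
#' @slot dropoutRate dropout fraction used after the first conv pair of
#'   every block.
#' @slot activation hidden-layer activation tag.
#' @slot paddingMode "same" (zero padding keeps spatial extents).
#' @export
setClass("ArchitectureConfig",
  representation(levels = "integer", filtersPerLevel = "integer",
                 bridgeFilters = "integer", inChannels = "integer",
                 nClasses = "integer", spatialKernel = "integer",
                 sliceKernel = "integer", pool = "integer",
                 dropoutRate = "numeric", activation = "character",
                 paddingMode = "character"))

setValidity("ArchitectureConfig", function(object) {
  if (length(object@filtersPerLevel) != object@levels)
    return("length(filtersPerLevel) must equal levels")
  if (any(c(object@filtersPerLevel, object@bridgeFilters, object@inChannels,
            object@nClasses) < 1L))
    return("all channel/filter counts must be positive")
  if (object@dropoutRate < 0 || object@dropoutRate >= 1)
    return("dropoutRate must lie in [0, 1)")
  if (length(object@spatialKernel) != 3L || length(object@sliceKernel) != 3L ||
      length(object@pool) != 3L)
    return("kernel and pool extents must have length 3")
  TRUE
})

#' SegModel: a built (2+1)D U-Net
#'
#' Holds the architecture config, the ordered op list the forward/backward
#' passes execute, and the parameter collection (weights, biases,
#' batch-norm statistics).
#'
#' @slot config the [ArchitectureConfig-class] the model was built from.
#' @slot ops ordered list of op descriptors (internal execution plan).
#' @slot params named list of per-layer parameter lists.
#' @slot mode "training" or "inference" (controls dropout and which
#'   batch-norm statistics are used).
#' @slot seed the seed the initial weights were drawn with.
#' @export
setClass("SegModel",
  representation(config = "ArchitectureConfig", ops = "list",
                 params = "list", mode = "character", seed = "integer"))

setValidity("SegModel", function(object) {
  if (!object@mode %in% c("training", "inference"))
    return("mode must be 'training' or 'inference'")
  TRUE
})

#' ProbabilityVolume: voxelwise class probabilities
#'
#' @slot probs numeric 4-D array `(slice, row, col, class)`; per voxel the
#'   class probabilities sum to 1.
#' @slot classNames ordered class names.
#' @export
setClass("ProbabilityVolume",
  representation(probs = "array", classNames = "character"),
  prototype(classNames = ISOSEG_CLASSES))

setValidity("ProbabilityVolume", function(object) {
  d <- dim(object@probs)
  if (length(d) != 4L) return("probs must be a 4-D array")
  if (d[4] != length(object@classNames))
    return("4th extent must equal the number of classes")
  if (min(object@probs) < -1e-6 || max(object@probs) > 1 + 1e-6)
    return("probabilities must lie in [0, 1]")
  s <- range(rowSums(matrix(object@probs, ncol = d[4])))
  if (s[1] < 1 - 1e-5 || s[2] > 1 + 1e-5)
    return("per-voxel class probabilities must sum to 1 (tol 1e-5)")
  TRUE
})

#' TissueConfusion: per-record voxel confusion matrix
#'
#' Rows are actual classes, columns predicted classes, mirroring the
#' actual-by-predicted layout used for cohort confusion statistics.
#'
#' @slot counts nClasses x nClasses matrix of voxel counts.
#' @slot recordId record tag.
#' @export
setClass("TissueConfusion",
  representation(counts = "matrix", recordId = "character"))

setValidity("TissueConfusion", function(object) {
  cm <- object@counts
  if (nrow(cm) != ncol(cm)) return("counts must be square")
  if (any(cm < 0) || any(cm != round(cm))) return("counts must be non-negative integers")
  TRUE
})

#' MetricsReport: per-record segmentation metrics
#'
#' Sensitivity (TPR), precision (PPV) and Dice score (DSC) for each tissue
#' class (CSF, GM, WM), plus overall accuracy (ACC) across all classes
#' including background. Metrics with an empty denominator are `NA`, never
#' silently 0.
#'
#' @slot tpr,ppv,dsc named numeric vectors over the tissue classes.
#' @slot acc overall fraction of correctly labeled voxels.
#' @slot recordId record tag.
#' @export
setClass("MetricsReport",
  representation(tpr = "numeric", ppv = "numeric", dsc = "numeric",
                 acc = "numeric", recordId = "character"))

setValidity("MetricsReport", function(object) {
  ok <- function(x) all(is.na(x) | (x >= 0 & x <= 1))
  if (!ok(object@tpr) || !ok(object@ppv) || !ok(object@dsc) || !ok(object@acc))
    return("every metric must lie in [0, 1] or be NA")
  TRUE
})

#' TrainConfig: optimization settings
#'
#' @slot epochs number of training epochs (the full-scale protocol uses
#'   1000; tests use far fewer).
#' @slot optimizer optimizer tag (only "adam").
#' @slot learningRate ADAM step size.
#' @slot seed base RNG seed.
#' @slot checkpointRule "lowest-cost": the returned model carries the
#'   parameters of the epoch with the lowest mean training cost.
#' @slot deterministicMode when TRUE, all stochastic parts (dropout order,
#'   init) are derived from `seed`, making runs bitwise reproducible.
#' @slot holdoutFraction optional fraction of training records held out for
#'   checkpoint selection; 0 selects on training cost (the default
#'   protocol).
#' @export
setClass("TrainConfig",
  representation(epochs = "integer", optimizer = "character",
                 learningRate = "numeric", seed = "integer",
                 checkpointRule = "character", deterministicMode = "logical",
                 holdoutFraction = "numeric"))

setValidity("TrainConfig", function(object) {
  if (object@epochs < 1L) return("epochs must be >= 1")
  if (object@learningRate < 0) return("learningRate must be >= 0")
  if (!object@optimizer %in% "adam") return("only the adam optimizer is supported")
  if (object@holdoutFraction < 0 || object@holdoutFraction >= 1)
    return("holdoutFraction must lie in [0, 1)")
  TRUE
})

#' FoldResult: one leave-one-out fold
#'
#' @slot testRecordId the held-out record.
#' @slot metrics [MetricsReport-class] on the held-out record.
#' @slot confusion [TissueConfusion-class] on the held-out record.
#' @slot history per-epoch mean training cost.
#' @slot bestEpoch epoch whose parameters were checkpointed (argmin of
#'   history).
#' @export
setClass("FoldResult",
  representation(testRecordId = "character", metrics = "MetricsReport",
                 confusion = "TissueConfusion", history = "numeric",
                 bestEpoch = "integer"))

setValidity("FoldResult", function(object) {
  if (length(object@history) >= 1L &&
      abs(object@history[object@bestEpoch] - min(object@history)) > 1e-12)
    return("bestEpoch must attain the minimum of history")
  TRUE
})
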