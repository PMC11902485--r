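#' @include AllGenerics.R
NULL

#' @describeIn volDims extents of an intensity volume
#' @export
setMethod("volDims", "IntensityVolume", function(x) dim(x@values))

#' @describeIn volDims spatial extents of a multi-modal volume
#' @export
setMethod("volDims", "MultiModalVolume", function(x) dim(x@channels)[1:3])

#' @describeIn volDims extents of a label volume
#' @export
setMethod("volDims", "LabelVolume", function(x) dim(x@labels))

#' @describeIn volDims spatial extents of a probability volume
#' @export
setMethod("volDims", "ProbabilityVolume", function(x) dim(x@probs)[1:3])

#' @describeIn volSpacing spacing of an intensity volume
#' @export
setMethod("volSpacing", "IntensityVolume", function(x) x@spacing)

#' @describeIn volSpacing spacing of a multi-modal volume
#' @export
setMethod("volSpacing", "MultiModalVolume", function(x) x@spacing)

#' @describeIn volSpacing spacing of a label volume
#' @export
setMethod("volSpacing", "LabelVolume", function(x) x@spacing)

#' @describeIn volValues intensity grid
#' @export
setMethod("volValues", "IntensityVolume", function(x) x@values)

#' @describeIn volValues 4-D channel grid
#' @export
setMethod("volValues", "MultiModalVolume", function(x) x@channels)

#' @describeIn volValues integer label grid
#' @export
setMethod("volValues", "LabelVolume", function(x) x@labels)

#' @describeIn volValues 4-D probability grid
#' @export
setMethod("volValues", "ProbabilityVolume", function(x) x@probs)

#' @describeIn volMask validity mask (or NULL)
#' @export
setMethod("volMask", "IntensityVolume", function(x) x@mask)

#' @describeIn classNames of a label volume
#' @export
setMethod("classNames", "LabelVolume", function(x) x@classNames)

#' @describeIn classNames of a probability volume
#' @export
setMethod("classNames", "ProbabilityVolume", function(x) x@classNames)

#' @describeIn nClasses of a label volume
#' @export
setMethod("nClasses", "LabelVolume", function(x) length(x@classNames))

#' @describeIn nClasses of a probability volume
#' @export
setMethod("nClasses", "ProbabilityVolume", function(x) length(x@classNames))

#' @describeIn anchors per-record landmark anchors
#' @export
setMethod("anchors", "LandmarkSet", function(x) x@anchors)

#' @describeIn anchors cohort reference anchors
#' @export
setMethod("anchors", "StandardScale", function(x) x@referenceAnchors)

#' @describeIn modality of a landmark set
#' @export
setMethod("modality", "LandmarkSet", function(x) x@modality)

#' @describeIn modality of a standard scale
#' @export
setMethod("modality", "StandardScale", function(x) x@modality)

#' @describeIn confusionCounts actual-by-predicted counts
#' @export
setMethod("confusionCounts", "TissueConfusion", function(x) x@counts)

setMethod("show", "IntensityVolume", function(object) {
  d <- dim(object@values)
  nv <- if (is.null(object@mask)) 0L else sum(!object@mask)
  cat(sprintf("IntensityVolume %dx%dx%d (slice x row x col), spacing %s mm\n",
              d[1], d[2], d[3], paste(format(object@spacing), collapse = "x")))
  cat(sprintf("  intensity range [%.4g, %.4g], %d void voxel(s)\n",
              min(object@values), max(object@values), nv))
})

setMethod("show", "MultiModalVolume", function(object) {
  d <- dim(object@channels)
  cat(sprintf("MultiModalVolume %dx%dx%dx%d, channels: %s\n",
              d[1], d[2], d[3], d[4],
              paste(object@channelLabels, collapse = ", ")))
})

setMethod("show", "LabelVolume", function(object) {
  d <- dim(object@labels)
  tab <- tabulate(as.integer(object@labels) + 1L,
                  nbins = length(object@classNames))
  cat(sprintf("LabelVolume %dx%dx%d, classes: %s\n", d[1], d[2], d[3],
              paste(sprintf("%s=%d", object@classNames, tab), collapse = ", ")))
})

setMethod("show", "LandmarkSet", function(object) {
  cat(sprintf("LandmarkSet [%s] p(%s) -> (%s)\n", object@modality,
              paste(object@percentiles, collapse = ", "),
              paste(format(object@anchors, digits = 5), collapse = ", ")))
})

setMethod("show", "StandardScale", function(object) {
  cat(sprintf("StandardScale [%s] p(%s) -> (%s)\n", object@modality,
              paste(object@percentiles, collapse = ", "),
              paste(format(object@referenceAnchors, digits = 5), collapse = ", ")))
})

setMethod("show", "TissueConfusion", function(object) {
  cat(sprintf("TissueConfusion [record %s], actual rows x predicted columns:\n",
              object@recordId))
  print(object@counts)
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport [record %s]\n", object@recordId))
  m <- rbind(TPR = object@tpr, PPV = object@ppv, DSC = object@dsc)
  print(round(m, 4))
  cat(sprintf("  ACC (all classes): %.4f\n", object@acc))
})

setMethod("show", "ArchitectureConfig", function(object) {
  cat(sprintf(paste0("ArchitectureConfig: %d levels, filters (%s), bridge %d, ",
                     "in %d ch, %d classes\n"),
              object@levels, paste(object@filtersPerLevel, collapse = ", "),
              object@bridgeFilters, object@inChannels, object@nClasses))
  cat(sprintf("  kernels %s / %s, pool %s, dropout %.2f, %s, padding %s\n",
              paste(object@spatialKernel, collapse = "x"),
              paste(object@sliceKernel, collapse = "x"),
              paste(object@pool, collapse = "x"),
              object@dropoutRate, object@activation, object@paddingMode))
})

setMethod("show", "SegModel", function(object) {
  cat(sprintf("SegModel ((2+1)D U-Net), %s mode, seed %d\n",
              object@mode, object@seed))
  show(object@config)
  cat(sprintf("  %d layers, %d trainable parameters\n",
              nrow(layerTable(object)), parameterCount(object)))
})

setMethod("show", "FoldResult", function(object) {
  cat(sprintf("FoldResult [test record %s]: best epoch %d/%d, cost %.5f\n",
              object@testRecordId, object@bestEpoch, length(object@history),
              min(object@history)))
  show(object@metrics)
})
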