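#' @include AllClasses.R
NULL

#' Spatial extents of a volumetric object
#'
#' Returns the `(slice, row, col)` extents in voxels.
#'
#' @param x a volume-like object.
#' @return integer vector of length 3.
#' @export
setGeneric("volDims", function(x) standardGeneric("volDims"))

#' Voxel spacing in millimetres
#'
#' @param x a volume-like object.
#' @return numeric vector of length 3 (mm per axis).
#' @export
setGeneric("volSpacing", function(x) standardGeneric("volSpacing"))

#' Underlying numeric/integer grid of a volume
#'
#' @param x a volume-like object.
#' @return the 3-D (or 4-D, for multi-channel objects) array.
#' @export
setGeneric("volValues", function(x) standardGeneric("volValues"))

#' Validity mask of a volume
#'
#' `TRUE` marks measured voxels, `FALSE` void voxels; `NULL` means every
#' voxel is valid.
#'
#' @param x an [IntensityVolume-class].
#' @return logical 3-D array or `NULL`.
#' @export
setGeneric("volMask", function(x) standardGeneric("volMask"))

#' Class names of a labelled object
#'
#' @param x a label/probability/metrics object.
#' @return character vector, in class-code order.
#' @export
setGeneric("classNames", function(x) standardGeneric("classNames"))

#' Number of classes
#'
#' @param x a label/probability object.
#' @return integer.
#' @export
setGeneric("nClasses", function(x) standardGeneric("nClasses"))

#' Landmark/reference anchors
#'
#' @param x a [LandmarkSet-class] or [StandardScale-class].
#' @return numeric vector of anchor intensities.
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))

#' Modality tag
#'
#' @param x a [LandmarkSet-class] or [StandardScale-class].
#' @return character scalar.
#' @export
setGeneric("modality", function(x) standardGeneric("modality"))

#' Confusion counts matrix
#'
#' Actual classes in rows, predicted classes in columns.
#'
#' @param x a [TissueConfusion-class].
#' @return integer matrix.
#' @export
setGeneric("confusionCounts", function(x) standardGeneric("confusionCounts"))

#' Total number of trainable parameters
#'
#' @param x a [SegModel-class].
#' @return integer count of trainable scalars (convolution weights and
#'   biases, batch-norm gains and shifts).
#' @export
setGeneric("parameterCount", function(x) standardGeneric("parameterCount"))
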