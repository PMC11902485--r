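#' @include AllClasses.R
NULL

#' Construct an IntensityVolume
#'
#' @param values numeric 3-D array indexed `(slice, row, col)`.
#' @param spacing voxel edge lengths in mm, length 3.
#' @param origin world origin in mm, length 3.
#' @param mask optional logical array of identical extents; `FALSE` marks
#'   void voxels.
#' @return an [IntensityVolume-class].
#' @export
intensityVolume <- function(values, spacing = c(1, 1, 1), origin = c(0, 0, 0),
                            mask = NULL) {
  new("IntensityVolume", values = values, spacing = as.numeric(spacing),
      origin = as.numeric(origin), mask = mask)
}

#' Construct a LabelVolume
#'
#' @param labels integer 3-D array with voxel codes `0:(length(classNames)-1)`.
#' @param classNames ordered class names; code 0 is the first entry.
#' @param spacing,origin spatial geometry.
#' @param remap optional integer vector of raw on-disk codes in class order
#'   (e.g. `c(0, 10, 150, 250)` for iSeg-2017 conventions); when given,
#'   `labels` is translated to the canonical codes `0:(n-1)` first.
#' @return a [LabelVolume-class].
#' @export
labelVolume <- function(labels, classNames = ISOSEG_CLASSES,
                        spacing = c(1, 1, 1), origin = c(0, 0, 0),
                        remap = NULL) {
  lab <- labels
  if (!is.null(remap)) {
    if (length(remap) != length(classNames))
      stop("remap must list one raw code per class")
    idx <- match(as.integer(lab), as.integer(remap))
    if (anyNA(idx))
      stop("labels contain codes absent from the remap table")
    lab <- array(idx - 1L, dim = dim(labels))
  }
  storage.mode(lab) <- "integer"
  new("LabelVolume", labels = lab, classNames = classNames,
      spacing = as.numeric(spacing), origin = as.numeric(origin))
}

# Normalize an on-disk (x=col, y=row, z=slice) array to in-memory
# (slice, row, col) order. The permutation is its own inverse.
.toSliceRowCol <- function(arr) aperm(arr, c(3L, 2L, 1L))

.isAnalyzePath <- function(path) grepl("\\.(hdr|img)(\\.gz)?$", path)

#' Read a volumetric image
#'
#' Reads a NIfTI-1 (`.nii`, `.nii.gz`) or Analyze 7.5 (`.hdr` + `.img`)
#' file and normalizes the voxel order to `(slice, row, col)`, so that a
#' header declaring 112 slices of 144x192 pixels yields extents
#' `(112, 192, 144)`.
#'
#' @param path file path.
#' @param formatHint optional `"nifti"` or `"analyze"`; by default the
#'   format is inferred from the extension.
#' @return an [IntensityVolume-class].
#' @export
readVolume <- function(path, formatHint = NULL) {
  if (!file.exists(path) && !file.exists(paste0(path, ".gz")))
    stop("file not found: ", path)
  if (identical(formatHint, "analyze") && !.isAnalyzePath(path))
    stop("analyze format requires an .hdr/.img path")
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e) stop("unreadable volume '", path,
                                           "': ", conditionMessage(e)))
  arr <- as.array(img)
  if (length(dim(arr)) == 4L && dim(arr)[4] == 1L)
    arr <- array(arr, dim = dim(arr)[1:3])
  if (length(dim(arr)) != 3L)
    stop("expected a 3-D volume, got extents ",
         paste(dim(arr), collapse = "x"))
  pd <- RNifti::pixdim(img)[1:3]
  intensityVolume(.toSliceRowCol(arr), spacing = rev(pd))
}

#' Read a label map
#'
#' Convenience wrapper around [readVolume()] that converts the voxel codes
#' to a [LabelVolume-class], optionally translating a raw code table.
#'
#' @inheritParams readVolume
#' @inheritParams labelVolume
#' @return a [LabelVolume-class].
#' @export
readLabels <- function(path, classNames = ISOSEG_CLASSES, remap = NULL,
                       formatHint = NULL) {
  v <- readVolume(path, formatHint)
  labelVolume(round(v@values), classNames = classNames,
              spacing = v@spacing, origin = v@origin, remap = remap)
}

#' Write a volumetric image
#'
#' Writes an [IntensityVolume-class] (stored as float64, so the read-back is
#' bit-exact) or a [LabelVolume-class] (stored as unsigned 8-bit) to NIfTI-1
#' or Analyze 7.5, chosen by extension (`.nii`/`.nii.gz` vs `.hdr`/`.img`).
#'
#' @param volume the volume to write.
#' @param path output path; the parent directory must exist.
#' @return `invisible(path)`.
#' @export
writeVolume <- function(volume, path) {
  if (!dir.exists(dirname(path)))
    stop("directory does not exist: ", dirname(path))
  isLabel <- is(volume, "LabelVolume")
  arr <- .toSliceRowCol(if (isLabel) volume@labels else volume@values)
  sp <- rev(volume@spacing)
  if (.isAnalyzePath(path)) {
    dt <- if (isLabel) 2L else 64L   # uint8 / float64
    aim <- oro.nifti::anlz(arr, datatype = dt,
                           bitpix = if (isLabel) 8L else 64L)
    aim@pixdim[2:4] <- sp
    stem <- sub("\\.(hdr|img)(\\.gz)?$", "", path)
    oro.nifti::writeANALYZE(aim, stem, gzipped = grepl("\\.gz$", path))
  } else {
    img <- RNifti::asNifti(arr)
    RNifti::pixdim(img) <- sp
    RNifti::writeNifti(img, path,
                       datatype = if (isLabel) "uint8" else "double")
  }
  invisible(path)
}

#' Stack two modalities into a network input
#'
#' Concatenates the T1 and T2 volumes along a trailing channel axis, each
#' replicated `replication` times, in the order
#' `[T1 x replication, T2 x replication]`. The default replication of 3
#' mirrors the image-as-RGB convention under which two modalities become
#' six input channels.
#'
#' @param t1,t2 co-registered [IntensityVolume-class] objects sharing
#'   extents and spacing.
#' @param replication positive integer; each modality is repeated this many
#'   times.
#' @return a [MultiModalVolume-class] with `2 * replication` channels.
#' @export
stackModalities <- function(t1, t2, replication = 3L) {
  replication <- as.integer(replication)
  if (replication < 1L) stop("replication must be a positive integer")
  d1 <- dim(t1@values); d2 <- dim(t2@values)
  if (!identical(d1, d2))
    stop("t1 and t2 extents differ: ", paste(d1, collapse = "x"), " vs ",
         paste(d2, collapse = "x"))
  if (max(abs(t1@spacing - t2@spacing)) > 1e-9)
    stop("t1 and t2 spacing differ")
  ch <- array(c(rep(t1@values, replication), rep(t2@values, replication)),
              dim = c(d1, 2L * replication))
  labs <- c(rep("T1", replication), rep("T2", replication))
  new("MultiModalVolume", channels = ch, channelLabels = labs,
      spacing = t1@spacing, origin = t1@origin)
}
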