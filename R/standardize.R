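#' @include AllClasses.R
NULL

# Default anchor percentiles: outer robust anchors at 1/99 plus the
# quartile landmarks the alignment is anchored on.
DEFAULT_PERCENTILES <- c(1, 25, 50, 75, 99)

.foregroundValues <- function(volume, foregroundRule = "positive") {
  v <- volume@values
  keep <- switch(foregroundRule,
    positive = v > 0,
    all = rep(TRUE, length(v)),
    stop("unknown foregroundRule: ", foregroundRule))
  if (!is.null(volume@mask)) keep <- keep & volume@mask
  v[keep]
}

#' Compute percentile landmarks of one record
#'
#' Extracts the anchor intensities of the foreground-voxel distribution,
#' using linear-interpolation quantiles. The interior landmarks default to
#' the 25th, 50th and 75th percentiles; the outer anchors to the robust
#' 1st/99th percentiles.
#'
#' @param volume an [IntensityVolume-class].
#' @param percentiles interior landmark percentiles (default `c(25, 50, 75)`).
#' @param outer outer anchor percentiles, `c(low, high)` (default `c(1, 99)`).
#' @param foregroundRule `"positive"` (intensity > 0; air excluded) or
#'   `"all"`. Void voxels (mask `FALSE`) are always excluded.
#' @param modality modality tag stored with the landmarks.
#' @return a [LandmarkSet-class].
#' @export
computeLandmarks <- function(volume, percentiles = c(25, 50, 75),
                             outer = c(1, 99), foregroundRule = "positive",
                             modality = "T1") {
  fg <- .foregroundValues(volume, foregroundRule)
  if (length(fg) == 0L)
    stop("no foreground voxels under rule '", foregroundRule, "'")
  p <- c(outer[1], percentiles, outer[2])
  if (is.unsorted(p, strictly = TRUE))
    stop("percentiles must be strictly increasing within the outer anchors")
  a <- unname(stats::quantile(fg, probs = p / 100, type = 7, names = FALSE))
  new("LandmarkSet", modality = modality, anchors = a, percentiles = p)
}

#' Build the cohort standard intensity scale
#'
#' The reference anchors are the arithmetic mean of each anchor across the
#' supplied per-record landmark sets. Inside cross-validation the scale is
#' built from training records only.
#'
#' @param landmarkSets list of [LandmarkSet-class], all of the same modality
#'   and percentile specification.
#' @return a [StandardScale-class]; errors if the mean anchors are not
#'   strictly increasing (degenerate cohort).
#' @export
buildStandardScale <- function(landmarkSets) {
  if (length(landmarkSets) < 1L) stop("need at least one landmark set")
  mods <- vapply(landmarkSets, function(l) l@modality, character(1))
  if (length(unique(mods)) != 1L)
    stop("all landmark sets must share one modality; got: ",
         paste(unique(mods), collapse = ", "))
  pcts <- lapply(landmarkSets, function(l) l@percentiles)
  if (!all(vapply(pcts, identical, logical(1), y = pcts[[1]])))
    stop("all landmark sets must share one percentile specification")
  A <- do.call(rbind, lapply(landmarkSets, function(l) l@anchors))
  ref <- colMeans(A)
  if (is.unsorted(ref, strictly = TRUE))
    stop("degenerate cohort: mean anchors are not strictly increasing")
  new("StandardScale", modality = mods[1], referenceAnchors = ref,
      percentiles = pcts[[1]])
}

#' Map one record onto the standard intensity scale
#'
#' Applies the piecewise-linear map sending the record's anchor intensities
#' onto the cohort reference anchors: exact at every anchor, linear between
#' consecutive anchors, and clamped to the outer reference anchors beyond
#' the record's outer anchors. The map is monotone non-decreasing, so voxel
#' intensity order is preserved.
#'
#' The map is applied to foreground voxels only (by default, intensities
#' greater than zero): air background stays at exactly zero, so foreground
#' membership — and with it every landmark — is invariant under
#' standardization, which is what keeps the cohort's landmarks aligned
#' after mapping.
#'
#' @param volume the [IntensityVolume-class] to standardize.
#' @param landmarks the record's own [LandmarkSet-class].
#' @param scale the cohort [StandardScale-class].
#' @param foregroundRule `"positive"` (map intensities > 0, leave the rest)
#'   or `"all"` (map every voxel); must match the rule the landmarks were
#'   computed with.
#' @return a standardized [IntensityVolume-class] (mask carried over).
#' @export
standardizeIntensity <- function(volume, landmarks, scale,
                                 foregroundRule = "positive") {
  a <- landmarks@anchors
  r <- scale@referenceAnchors
  if (length(a) != length(r))
    stop("landmark and scale anchor arities differ (", length(a), " vs ",
         length(r), ")")
  # Collapse ties in the record anchors (constant stretches map to the
  # midpoint of the corresponding reference anchors); approx() needs
  # strictly increasing x.
  ux <- unique(a)
  uy <- vapply(ux, function(x) mean(r[a == x]), numeric(1))
  v <- volume@values
  sel <- switch(foregroundRule,
    positive = v > 0,
    all = array(TRUE, dim = dim(v)),
    stop("unknown foregroundRule: ", foregroundRule))
  mapped <- v
  if (length(ux) == 1L) {
    mapped[sel] <- uy
  } else {
    mapped[sel] <- stats::approx(ux, uy, xout = v[sel],
                                 method = "linear", rule = 2)$y
  }
  intensityVolume(mapped, spacing = volume@spacing, origin = volume@origin,
                  mask = volume@mask)
}

#' Fill void voxels by iterated neighborhood medians
#'
#' Replaces every void voxel (mask `FALSE`) by the median of the valid
#' voxels in its 3x3x3 neighborhood, iterating until no voids remain.
#' Valid voxels are never modified, and the fill is deterministic and
#' local, so the global intensity histogram is essentially preserved.
#'
#' @param volume an [IntensityVolume-class] with a validity mask.
#' @param maxIterations safety cap on the number of sweeps.
#' @return an [IntensityVolume-class] with all voxels valid.
#' @export
fillMissing <- function(volume, maxIterations = 100L) {
  if (is.null(volume@mask))
    stop("fillMissing requires a validity mask")
  v <- volume@values
  valid <- volume@mask
  if (!any(valid)) stop("volume has no valid voxels to interpolate from")
  d <- dim(v)
  offs <- as.matrix(expand.grid(ds = -1:1, dr = -1:1, dc = -1:1))
  offs <- offs[rowSums(abs(offs)) > 0, , drop = FALSE]
  iter <- 0L
  while (any(!valid)) {
    iter <- iter + 1L
    if (iter > maxIterations)
      stop("voids remain after ", maxIterations, " fill iterations")
    voids <- which(!valid, arr.ind = TRUE)
    newVals <- rep(NA_real_, nrow(voids))
    for (i in seq_len(nrow(voids))) {
      nb <- sweep(offs, 2, voids[i, ], "+")
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] & nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      vv <- valid[nb]
      if (any(vv)) newVals[i] <- stats::median(v[nb[vv, , drop = FALSE]])
    }
    filled <- !is.na(newVals)
    if (!any(filled))
      stop("isolated void region cannot be filled")  # unreachable if any valid
    v[voids[filled, , drop = FALSE]] <- newVals[filled]
    valid[voids[filled, , drop = FALSE]] <- TRUE
  }
  intensityVolume(v, spacing = volume@spacing, origin = volume@origin,
                  mask = array(TRUE, dim = d))
}

#' Standardize a two-modality cohort
#'
#' Convenience pipeline: fills voids, computes per-record landmarks, builds
#' per-modality standard scales from the records listed in `trainIdx`
#' (defaults to all records), and maps every record onto those scales.
#'
#' @param records list of records, each a list with elements `t1` and `t2`
#'   ([IntensityVolume-class]) and optionally `labels`.
#' @param trainIdx indices of records contributing to the standard scale.
#' @param percentiles,outer,foregroundRule passed to [computeLandmarks()].
#' @return list with elements `records` (standardized copies) and `scales`
#'   (per-modality [StandardScale-class]).
#' @export
standardizeCohort <- function(records, trainIdx = seq_along(records),
                              percentiles = c(25, 50, 75), outer = c(1, 99),
                              foregroundRule = "positive") {
  prep <- lapply(records, function(rec) {
    for (m in c("t1", "t2"))
      if (!is.null(rec[[m]]@mask) && !all(rec[[m]]@mask))
        rec[[m]] <- fillMissing(rec[[m]])
    rec
  })
  lms <- lapply(prep, function(rec)
    list(t1 = computeLandmarks(rec$t1, percentiles, outer, foregroundRule, "T1"),
         t2 = computeLandmarks(rec$t2, percentiles, outer, foregroundRule, "T2")))
  scales <- list(
    t1 = buildStandardScale(lapply(lms[trainIdx], `[[`, "t1")),
    t2 = buildStandardScale(lapply(lms[trainIdx], `[[`, "t2")))
  std <- mapply(function(rec, lm) {
    rec$t1 <- standardizeIntensity(rec$t1, lm$t1, scales$t1, foregroundRule)
    rec$t2 <- standardizeIntensity(rec$t2, lm$t2, scales$t2, foregroundRule)
    rec
  }, prep, lms, SIMPLIFY = FALSE)
  list(records = std, scales = scales)
}

#' Serialize landmarks or a standard scale to JSON
#'
#' @param x a [LandmarkSet-class] or [StandardScale-class].
#' @param path output JSON path.
#' @return `invisible(path)`.
#' @export
writeLandmarksJSON <- function(x, path) {
  obj <- if (is(x, "LandmarkSet")) {
    list(kind = "landmarks", modality = x@modality,
         percentiles = x@percentiles, anchors = x@anchors)
  } else {
    list(kind = "standard_scale", modality = x@modality,
         percentiles = x@percentiles, anchors = x@referenceAnchors)
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Read landmarks or a standard scale from JSON
#'
#' @param path JSON path written by [writeLandmarksJSON()].
#' @return a [LandmarkSet-class] or [StandardScale-class].
#' @export
readLandmarksJSON <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$kind, "landmarks"))
    new("LandmarkSet", modality = obj$modality, anchors = obj$anchors,
        percentiles = obj$percentiles)
  else
    new("StandardScale", modality = obj$modality,
        referenceAnchors = obj$anchors, percentiles = obj$percentiles)
}
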