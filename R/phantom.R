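#' @include AllClasses.R
NULL

#' Synthetic phantom cohort specification
#'
#' Parameter bundle for the built-in two-modality infant-brain phantom:
#' nested background / CSF shell / GM ribbon / WM core geometry from
#' smoothly perturbed ellipsoid level sets, per-tissue Gaussian intensity
#' models on both modalities, per-record global intensity jitter, and
#' sporadic void voxels. The defaults emulate the isointense regime: the
#' GM and WM means sit 0.4 pooled standard deviations apart while CSF sits
#' several standard deviations away, and the GM ribbon holds roughly twice
#' as many voxels as the WM core.
#'
#' @param extents spatial extents `(slice, row, col)`; each must be
#'   divisible by 16 (four pooling levels) unless input padding is used
#'   downstream.
#' @param brainRadiusFrac outer (CSF) ellipsoid radius as a fraction of the
#'   half-extents.
#' @param wmRadiusFrac WM-core radius as a fraction of the brain radius;
#'   the GM/CSF boundary sits at `wmRadiusFrac * 3^(1/3)` so the GM:WM
#'   voxel ratio is ~2.
#' @param perturbAmplitude amplitude of the low-order harmonic boundary
#'   perturbation (0 gives exact ellipsoids).
#' @param t1CsfMean,t1ParenchymaMean,t2CsfMean,t2ParenchymaMean per-modality
#'   intensity means (arbitrary scanner units); CSF/parenchyma contrast is
#'   inverted between T1 and T2.
#' @param tissueSd within-tissue intensity standard deviation.
#' @param gmWmSeparation GM-WM mean gap in units of `tissueSd`; the default
#'   0.4 keeps the two distributions strongly overlapping (isointense),
#'   large values (e.g. 6) give an easy, well-separated regime.
#' @param scaleRange,offsetRange per-record global affine intensity jitter:
#'   each record/modality draws one multiplicative scale and one additive
#'   offset from these ranges (applied to brain voxels; air stays 0).
#' @param voidFraction fraction of in-brain voxels masked invalid, in
#'   `[0, 0.2]`.
#' @param seed integer seed; the phantom is fully determined by it.
#' @return a list of class `"PhantomSpec"`.
#' @export
phantomSpec <- function(extents = c(32L, 48L, 32L),
                        brainRadiusFrac = 0.80, wmRadiusFrac = 0.64,
                        perturbAmplitude = 0.05,
                        t1CsfMean = 250, t1ParenchymaMean = 610,
                        t2CsfMean = 850, t2ParenchymaMean = 470,
                        tissueSd = 50, gmWmSeparation = 0.4,
                        scaleRange = c(0.8, 1.25), offsetRange = c(0, 60),
                        voidFraction = 0.005, seed = 1L) {
  spec <- list(extents = as.integer(extents),
               brainRadiusFrac = brainRadiusFrac,
               wmRadiusFrac = wmRadiusFrac,
               gmRadiusFrac = wmRadiusFrac * 3^(1 / 3),
               perturbAmplitude = perturbAmplitude,
               t1CsfMean = t1CsfMean, t1ParenchymaMean = t1ParenchymaMean,
               t2CsfMean = t2CsfMean, t2ParenchymaMean = t2ParenchymaMean,
               tissueSd = tissueSd, gmWmSeparation = gmWmSeparation,
               scaleRange = scaleRange, offsetRange = offsetRange,
               voidFraction = voidFraction, seed = as.integer(seed))
  if (length(spec$extents) != 3L || any(spec$extents < 16L))
    stop("extents must be three values >= 16")
  if (spec$voidFraction < 0 || spec$voidFraction > 0.2)
    stop("voidFraction must lie in [0, 0.2]")
  if (spec$tissueSd <= 0) stop("tissueSd must be positive")
  if (spec$gmRadiusFrac >= 1)
    stop("wmRadiusFrac too large: GM boundary exceeds the brain radius")
  class(spec) <- "PhantomSpec"
  spec
}

# Per-tissue means for one modality. Tissue order: CSF, GM, WM.
.tissueMeans <- function(spec, modalityTag) {
  gap <- spec$gmWmSeparation * spec$tissueSd
  if (modalityTag == "T1") {
    # infant T1: GM lighter than WM
    c(spec$t1CsfMean, spec$t1ParenchymaMean + gap / 2,
      spec$t1ParenchymaMean - gap / 2)
  } else {
    c(spec$t2CsfMean, spec$t2ParenchymaMean - gap / 2,
      spec$t2ParenchymaMean + gap / 2)
  }
}

.modalityVolume <- function(spec, lab, modalityTag) {
  n <- length(lab)
  means <- .tissueMeans(spec, modalityTag)
  v <- numeric(n)
  brain <- lab > 0L
  v[brain] <- means[lab[brain]] +
    stats::rnorm(sum(brain), 0, spec$tissueSd)
  v[brain] <- pmax(v[brain], 1e-3)  # keep brain voxels in the foreground
  # one global affine intensity change per record/modality
  sc <- stats::runif(1, spec$scaleRange[1], spec$scaleRange[2])
  off <- stats::runif(1, spec$offsetRange[1], spec$offsetRange[2])
  v[brain] <- v[brain] * sc + off
  mask <- rep(TRUE, n)
  nVoid <- round(spec$voidFraction * sum(brain))
  if (nVoid > 0) {
    voidIdx <- sample(which(brain), nVoid)
    mask[voidIdx] <- FALSE
    v[voidIdx] <- 0
  }
  d <- spec$extents
  intensityVolume(array(v, dim = d), mask = array(mask, dim = d))
}

#' Generate one synthetic phantom record
#'
#' Builds the tissue geometry from a smoothly perturbed nested-ellipsoid
#' level set, draws per-tissue Gaussian intensities on both modalities
#' (CSF/parenchyma contrast inverted between T1 and T2), applies one
#' global affine intensity jitter per modality, and masks a sporadic
#' fraction of brain voxels as voids. Fully determined by `spec$seed`.
#'
#' @param spec a [phantomSpec()].
#' @param recordId record tag.
#' @return list with elements `t1`, `t2` ([IntensityVolume-class]),
#'   `labels` ([LabelVolume-class]) and `id`.
#' @export
generatePhantom <- function(spec = phantomSpec(), recordId = "phantom01") {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(spec$seed)
  d <- spec$extents
  # normalized coordinates in [-1, 1] per axis
  u1 <- (seq_len(d[1]) - (d[1] + 1) / 2) / (d[1] / 2)
  u2 <- (seq_len(d[2]) - (d[2] + 1) / 2) / (d[2] / 2)
  u3 <- (seq_len(d[3]) - (d[3] + 1) / 2) / (d[3] / 2)
  U1 <- array(rep(u1, times = d[2] * d[3]), dim = d)
  U2 <- array(rep(rep(u2, each = d[1]), times = d[3]), dim = d)
  U3 <- array(rep(u3, each = d[1] * d[2]), dim = d)
  r <- sqrt(U1^2 + U2^2 + U3^2)
  rho <- r / spec$brainRadiusFrac
  # low-order harmonic boundary perturbation (seeded coefficients)
  cf <- stats::runif(3, -1, 1)
  theta <- acos(ifelse(r > 0, U1 / pmax(r, 1e-12), 1))
  phi <- atan2(U3, U2)
  p <- cf[1] * sin(2 * phi) * sin(theta) +
       cf[2] * cos(phi) * sin(2 * theta) +
       cf[3] * cos(2 * theta)
  rhoEff <- rho / (1 + spec$perturbAmplitude * p)
  lab <- array(0L, dim = d)
  lab[rhoEff <= 1] <- 1L                       # CSF shell
  lab[rhoEff <= spec$gmRadiusFrac] <- 2L       # GM ribbon
  lab[rhoEff <= spec$wmRadiusFrac] <- 3L       # WM core
  counts <- tabulate(lab + 1L, nbins = 4L)
  if (any(counts[2:4] == 0L))
    stop("degenerate phantom spec: tissue class with zero voxels (counts ",
         paste(counts, collapse = ", "), ")")
  t1 <- .modalityVolume(spec, lab, "T1")
  t2 <- .modalityVolume(spec, lab, "T2")
  list(t1 = t1, t2 = t2,
       labels = labelVolume(lab), id = recordId)
}

#' Generate a phantom cohort
#'
#' `n` records drawn from seeds `spec$seed + 0 .. n-1`, each with its own
#' geometry perturbation and global intensity jitter. Optionally writes
#' the volumes as NIfTI plus a JSON manifest listing per-record paths.
#'
#' @param n number of records.
#' @param spec a [phantomSpec()]; per-record specs differ only in seed.
#' @param outDir optional output directory for NIfTI volumes and
#'   `manifest.json`.
#' @return list of records as returned by [generatePhantom()].
#' @export
generateCohort <- function(n, spec = phantomSpec(), outDir = NULL) {
  if (n < 1L) stop("n must be >= 1")
  records <- lapply(seq_len(n) - 1L, function(k) {
    sp <- spec
    sp$seed <- spec$seed + k
    generatePhantom(sp, recordId = sprintf("rec%02d", k + 1L))
  })
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    manifest <- lapply(records, function(rec) {
      paths <- list(t1 = file.path(outDir, paste0(rec$id, "_t1.nii.gz")),
                    t2 = file.path(outDir, paste0(rec$id, "_t2.nii.gz")),
                    labels = file.path(outDir, paste0(rec$id, "_labels.nii.gz")))
      writeVolume(rec$t1, paths$t1)
      writeVolume(rec$t2, paths$t2)
      writeVolume(rec$labels, paths$labels)
      c(list(id = rec$id), paths)
    })
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE)
  }
  records
}

#' Read a cohort manifest written by [generateCohort()]
#'
#' @param path path to `manifest.json`.
#' @return list of records with elements `t1`, `t2`, `labels`, `id`.
#' @export
readCohortManifest <- function(path) {
  manifest <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(manifest, function(m)
    list(t1 = readVolume(m$t1), t2 = readVolume(m$t2),
         labels = readLabels(m$labels), id = m$id))
}

#' Assemble the network input of a phantom/cohort record
#'
#' Stacks the two modalities into channels and optionally rescales the
#' intensities to order one, which keeps the network's first-layer
#' pre-activations in a well-conditioned range.
#'
#' @param record a record (list with `t1`, `t2`).
#' @param replication channel replication per modality (see
#'   [stackModalities()]).
#' @param intensityScale `NULL` (no rescaling) or a length-2 numeric
#'   `(t1, t2)`: each modality's intensities are divided by its entry.
#'   [runLOOCV()] uses the standard scale's high anchors here.
#' @return a [MultiModalVolume-class].
#' @export
recordInput <- function(record, replication = 1L, intensityScale = NULL) {
  t1 <- record$t1
  t2 <- record$t2
  if (!is.null(intensityScale)) {
    t1 <- intensityVolume(t1@values / intensityScale[1], t1@spacing,
                          t1@origin, t1@mask)
    t2 <- intensityVolume(t2@values / intensityScale[2], t2@spacing,
                          t2@origin, t2@mask)
  }
  stackModalities(t1, t2, replication)
}
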