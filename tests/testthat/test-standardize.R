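test_that("landmarks match an independent sort-and-interpolate oracle", {
  v <- intensityVolume(array(c(1:100, rep(0, 25)), dim = c(5, 5, 5)))
  lm <- computeLandmarks(v)   # zeros excluded by the foreground rule
  expect_identical(lm@percentiles, c(1, 25, 50, 75, 99))
  fg <- 1:100
  for (i in seq_along(lm@percentiles))
    expect_equal(anchors(lm)[i], oracleQuantile(fg, lm@percentiles[i] / 100))

  # random volumes too
  for (s in 1:5) {
    set.seed(s)
    vals <- rlnorm(500, 5, 1)
    rv <- intensityVolume(array(c(vals, rep(0, 100)), dim = c(10, 10, 6)))
    lmr <- computeLandmarks(rv)
    expect_equal(anchors(lmr),
                 vapply(lmr@percentiles / 100, oracleQuantile, numeric(1),
                        x = vals))
  }
})

test_that("constant foreground collapses all anchors and empty foreground errors", {
  v <- intensityVolume(array(7, dim = c(4, 4, 4)))
  expect_true(all(anchors(computeLandmarks(v)) == 7))
  zero <- intensityVolume(array(0, dim = c(4, 4, 4)))
  expect_error(computeLandmarks(zero), "foreground")
})

test_that("standard scale is the anchorwise mean and rejects degenerate cohorts", {
  a <- new("LandmarkSet", modality = "T1", anchors = c(1, 2, 3, 4, 5),
           percentiles = c(1, 25, 50, 75, 99))
  b <- new("LandmarkSet", modality = "T1", anchors = c(3, 4, 5, 6, 7),
           percentiles = c(1, 25, 50, 75, 99))
  expect_equal(anchors(buildStandardScale(list(a))), anchors(a))
  expect_equal(anchors(buildStandardScale(list(a, b))), (anchors(a) + anchors(b)) / 2)

  mixed <- new("LandmarkSet", modality = "T2", anchors = anchors(b),
               percentiles = b@percentiles)
  expect_error(buildStandardScale(list(a, mixed)), "modality")

  flat1 <- new("LandmarkSet", modality = "T1", anchors = c(1, 2, 2, 4, 5),
               percentiles = c(1, 25, 50, 75, 99))
  flat2 <- new("LandmarkSet", modality = "T1", anchors = c(1, 2, 2, 4, 5),
               percentiles = c(1, 25, 50, 75, 99))
  expect_error(buildStandardScale(list(flat1, flat2)), "degenerate")
})

test_that("piecewise-linear standardization matches a per-voxel oracle and is exact at anchors", {
  set.seed(21)
  v <- intensityVolume(array(runif(1000, 1, 100), dim = c(10, 10, 10)))
  lm <- computeLandmarks(v)
  ref <- new("StandardScale", modality = "T1",
             referenceAnchors = c(0, 20, 50, 90, 120),
             percentiles = lm@percentiles)
  out <- standardizeIntensity(v, lm, ref)
  expected <- oraclePiecewiseMap(as.vector(volValues(v)), anchors(lm),
                                 anchors(ref))
  expect_lt(max(abs(as.vector(volValues(out)) - expected)), 1e-9)

  # landmark exactness, including interior anchors
  vAtAnchors <- intensityVolume(array(rep(anchors(lm), 8), dim = c(2, 4, 5)))
  mapped <- standardizeIntensity(vAtAnchors, lm, ref)
  expect_identical(as.vector(volValues(mapped))[1:5], anchors(ref))

  # identity when the scale comes from this single record
  self <- buildStandardScale(list(lm))
  idm <- standardizeIntensity(v, lm, self)
  inRange <- volValues(v) >= anchors(lm)[1] & volValues(v) <= anchors(lm)[5]
  expect_lt(max(abs(volValues(idm)[inRange] - volValues(v)[inRange])), 1e-9)

  badScale <- new("StandardScale", modality = "T1",
                  referenceAnchors = c(0, 20, 50), percentiles = c(1, 50, 99))
  expect_error(standardizeIntensity(v, lm, badScale), "arities")
})

test_that("standardization is monotone and idempotent on random grids", {
  for (s in 1:4) {
    set.seed(s + 40)
    v <- intensityVolume(array(rlnorm(750, 4, 0.8), dim = c(5, 10, 15)))
    lm <- computeLandmarks(v)
    ref <- new("StandardScale", modality = "T1",
               referenceAnchors = sort(runif(5, 1, 200)),
               percentiles = lm@percentiles)
    out <- standardizeIntensity(v, lm, ref)
    ord <- order(as.vector(volValues(v)))
    expect_false(is.unsorted(as.vector(volValues(out))[ord]))

    # idempotence: re-standardizing against its own new landmarks is the
    # identity within the outer-anchor range; only the clamped tail mass
    # beyond the robust 1st/99th anchors may move
    lm2 <- computeLandmarks(out, foregroundRule = "all")
    out2 <- standardizeIntensity(out, lm2, buildStandardScale(list(lm2)))
    inr <- volValues(out) >= anchors(lm2)[1] & volValues(out) <= anchors(lm2)[5]
    expect_lt(max(abs(volValues(out2)[inr] - volValues(out)[inr])), 1e-6)
    expect_lte(mean(!inr), 0.025)
  }
})

test_that("void filling matches the iterative neighborhood-median oracle", {
  # no-op without voids
  v0 <- intensityVolume(array(runif(216), dim = c(6, 6, 6)),
                        mask = array(TRUE, dim = c(6, 6, 6)))
  expect_equal(volValues(fillMissing(v0)), volValues(v0))

  # single void surrounded by a constant
  vals <- array(5, dim = c(3, 3, 3)); mask <- array(TRUE, dim = c(3, 3, 3))
  vals[2, 2, 2] <- 0; mask[2, 2, 2] <- FALSE
  filled <- fillMissing(intensityVolume(vals, mask = mask))
  expect_equal(volValues(filled)[2, 2, 2], 5)
  expect_true(all(volMask(filled)))

  # 5% random voids vs the oracle
  set.seed(31)
  vals <- array(runif(10 * 12 * 8, 10, 20), dim = c(10, 12, 8))
  mask <- array(TRUE, dim = dim(vals))
  voidIdx <- sample(length(vals), round(0.05 * length(vals)))
  mask[voidIdx] <- FALSE
  vals[voidIdx] <- 0
  got <- fillMissing(intensityVolume(vals, mask = mask))
  expect_equal(volValues(got), oracleFill(vals, mask))

  expect_error(fillMissing(intensityVolume(vals)), "mask")
  allVoid <- intensityVolume(vals, mask = array(FALSE, dim = dim(vals)))
  expect_error(fillMissing(allVoid), "valid")
})

test_that("cohort standardization aligns landmarks across jittered records", {
  cohort <- smallCohort(4)
  std <- standardizeCohort(cohort)
  p50 <- function(rec) anchors(computeLandmarks(rec$t1, foregroundRule = "positive"))[3]
  pre <- vapply(cohort, p50, numeric(1))
  post <- vapply(std$records, p50, numeric(1))
  expect_gt(diff(range(pre)), 1)          # jitter separates the records
  # alignment collapses the spread to float-level relative precision
  expect_lt(diff(range(post)) / mean(post), 1e-6)
  expect_lt(diff(range(post)), 1e-8 + 1e-3)
})

test_that("landmark JSON sidecars round-trip", {
  lm <- new("LandmarkSet", modality = "T2", anchors = c(1, 2.5, 3, 4, 8),
            percentiles = c(1, 25, 50, 75, 99))
  path <- file.path(withr::local_tempdir(), "lm.json")
  writeLandmarksJSON(lm, path)
  back <- readLandmarksJSON(path)
  expect_s4_class(back, "LandmarkSet")
  expect_equal(anchors(back), anchors(lm))
  sc <- buildStandardScale(list(lm))
  writeLandmarksJSON(sc, path)
  expect_s4_class(readLandmarksJSON(path), "StandardScale")
})
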