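oneHotProbs <- function(labels, nClasses = 4L) {
  d <- dim(labels)
  p <- array(0, dim = c(d, nClasses))
  pm <- matrix(p, ncol = nClasses)
  pm[cbind(seq_along(labels), as.integer(labels) + 1L)] <- 1
  array(pm, dim = c(d, nClasses))
}

test_that("soft Dice handles perfect overlap, disjoint sets and forced arithmetic", {
  y <- randLabels(c(4, 4, 4), seed = 1)
  p <- oneHotProbs(y)
  expect_true(all(abs(softDicePerClass(p, y) - 1) < 1e-5))

  # prediction disjoint from truth for a class
  y2 <- array(0L, dim = c(2, 2, 2)); y2[1:4] <- 1L
  pred <- array(0L, dim = c(2, 2, 2)); pred[5:8] <- 1L
  d <- softDicePerClass(oneHotProbs(pred), y2)
  expect_lt(d["CSF"], 1e-5)

  # 2 predicted, 2 true, 1 overlapping voxel -> 2*1/(2+2) = 0.5
  y3 <- array(0L, dim = c(2, 2, 2)); y3[c(1, 2)] <- 1L
  p3 <- array(0L, dim = c(2, 2, 2)); p3[c(2, 3)] <- 1L
  expect_equal(unname(softDicePerClass(oneHotProbs(p3), y3)["CSF"]), 0.5,
               tolerance = 1e-5)
})

test_that("hybrid loss is zero at perfection and matches the closed form at uniformity", {
  y <- randLabels(c(4, 4, 4), seed = 2)
  expect_lt(hybridLoss(oneHotProbs(y), y), 1e-4)

  # uniform probabilities over 4 equally frequent classes:
  # 0.5 * ln 4 + 0.5 * (1 - 0.25) = 1.068147
  yb <- array(rep(0:3, each = 16), dim = c(4, 4, 4))
  pu <- array(0.25, dim = c(4, 4, 4, 4))
  expect_equal(hybridLoss(pu, yb), 0.5 * log(4) + 0.5 * 0.75,
               tolerance = 1e-6)
  # default weights are equal
  expect_equal(formals(hybridLoss)$wCe, 0.5)
  expect_equal(formals(hybridLoss)$wDice, 0.5)

  expect_error(hybridLoss(pu, array(0L, dim = c(4, 4, 5))), "extents")
})

test_that("hybrid loss is non-negative on random inputs", {
  for (s in 1:10) {
    set.seed(s)
    raw <- array(rexp(4^3 * 4), dim = c(4, 4, 4, 4))
    p <- raw / array(rep(apply(raw, c(1, 2, 3), sum), 4), dim = dim(raw))
    y <- randLabels(c(4, 4, 4), seed = s + 50)
    expect_gte(hybridLoss(p, y), 0)
  }
})

test_that("confusion matrices tally actual-by-predicted voxel counts", {
  y <- array(c(0L, 1L, 1L, 2L, 3L, 0L, 0L, 0L), dim = c(2, 2, 2))
  p <- array(c(0L, 1L, 2L, 2L, 2L, 0L, 0L, 0L), dim = c(2, 2, 2))
  cm <- tissueConfusion(p, y)
  counts <- confusionCounts(cm)
  expect_identical(counts["CSF", "CSF"], 1L)
  expect_identical(counts["CSF", "GM"], 1L)
  expect_identical(counts["GM", "GM"], 1L)
  expect_identical(counts["WM", "GM"], 1L)
  expect_identical(sum(counts), 8L)

  same <- tissueConfusion(y, y)
  expect_true(all(confusionCounts(same)[upper.tri(confusionCounts(same))] == 0))
  expect_error(tissueConfusion(array(5L, dim = c(1, 1, 1)),
                               array(0L, dim = c(1, 1, 1))), "range")
})

test_that("metrics from a confusion matrix match the set-formula oracle", {
  # hand tally: truth (0,1,1,2,3), pred (0,1,2,2,2)
  y <- array(c(0L, 1L, 1L, 2L, 3L, 0L, 0L, 0L), dim = c(2, 2, 2))
  p <- array(c(0L, 1L, 2L, 2L, 2L, 0L, 0L, 0L), dim = c(2, 2, 2))
  rep <- metricsFromConfusion(tissueConfusion(p, y))
  expect_equal(rep@acc, 6 / 8)
  expect_equal(unname(rep@tpr["CSF"]), 0.5)
  expect_equal(unname(rep@ppv["GM"]), 1 / 3)
  # one true GM voxel, three predicted, one overlapping: 2*1/(1+3)
  expect_equal(unname(rep@dsc["GM"]), 0.5)

  # random grids against the independent brute-force oracle
  for (s in 1:25) {
    yy <- randLabels(c(5, 5, 4), seed = s)
    pp <- randLabels(c(5, 5, 4), seed = s + 1000)
    got <- metricsFromConfusion(tissueConfusion(pp, yy))
    want <- oracleMetrics(pp, yy)
    expect_equal(got@acc, want$acc, tolerance = 1e-12)
    for (ti in 1:3) {
      w <- want$perClass[[ti + 1]]
      expect_equal(unname(got@tpr[ti]), w$tpr, tolerance = 1e-12)
      expect_equal(unname(got@ppv[ti]), w$ppv, tolerance = 1e-12)
      expect_equal(unname(got@dsc[ti]), w$dsc, tolerance = 1e-12)
    }
  }
})

test_that("DSC is the harmonic mean of TPR and PPV when margins are nonzero", {
  for (s in 1:10) {
    y <- randLabels(c(6, 6, 6), seed = s + 200)
    p <- randLabels(c(6, 6, 6), seed = s + 300)
    r <- metricsFromConfusion(tissueConfusion(p, y))
    ok <- !is.na(r@tpr) & !is.na(r@ppv) & (r@tpr + r@ppv) > 0
    expect_equal(r@dsc[ok], 2 * r@tpr[ok] * r@ppv[ok] / (r@tpr[ok] + r@ppv[ok]),
                 tolerance = 1e-12)
  }
})

test_that("empty classes yield NA metrics, never zero", {
  y <- array(0L, dim = c(2, 2, 2))   # only background present
  p <- array(0L, dim = c(2, 2, 2))
  r <- metricsFromConfusion(tissueConfusion(p, y))
  expect_true(all(is.na(r@tpr)))
  expect_true(all(is.na(r@ppv)))
  expect_equal(r@acc, 1)
})

test_that("soft Dice on one-hot probabilities equals hard confusion-matrix Dice", {
  for (s in 1:5) {
    y <- randLabels(c(6, 6, 4), seed = s + 400)
    p <- randLabels(c(6, 6, 4), seed = s + 500)
    soft <- softDicePerClass(oneHotProbs(p), y)
    hard <- metricsFromConfusion(tissueConfusion(p, y))@dsc
    present <- names(hard)[!is.na(hard)]
    expect_equal(soft[present], hard[present], tolerance = 1e-5)
  }
})

test_that("cohort aggregation uses mean, sample SD and interpolated quartiles", {
  expect_equal(unname(summaryStats(c(1, 2, 3, 4))["Q1"]), 1.75)
  const <- summaryStats(rep(0.5, 6))
  expect_equal(unname(const["std"]), 0)
  expect_true(all(const[c("min", "Q1", "Q2", "Q3", "max")] == 0.5))
  expect_true(is.na(summaryStats(1)["std"]))
  expect_error(summaryStats(numeric(0)), "empty")

  set.seed(61)
  x <- runif(9)
  s <- summaryStats(x)
  expect_equal(unname(s["avg"]), mean(x))
  expect_equal(unname(s["std"]), sd(x))
  for (nm in c("Q1", "Q2", "Q3"))
    expect_equal(unname(s[nm]),
                 oracleQuantile(x, c(Q1 = 0.25, Q2 = 0.5, Q3 = 0.75)[[nm]]))
  expect_true(all(diff(s[c("min", "Q1", "Q2", "Q3", "max")]) >= 0))
})

test_that("aggregateReports summarizes per-record report objects", {
  reports <- lapply(1:4, function(s) {
    y <- randLabels(c(6, 6, 6), seed = s + 600)
    p <- randLabels(c(6, 6, 6), seed = s + 700)
    metricsFromConfusion(tissueConfusion(p, y, recordId = paste0("r", s)))
  })
  tab <- aggregateReports(reports)
  expect_identical(rownames(tab),
                   c("avg", "std", "min", "Q1", "Q2", "Q3", "max"))
  expect_true("ACC" %in% colnames(tab))
  accs <- vapply(reports, function(r) r@acc, numeric(1))
  expect_equal(tab["avg", "ACC"], mean(accs))
  expect_equal(tab["std", "ACC"], sd(accs))
  expect_error(aggregateReports(list()), "aggregate")
})

test_that("the tissue-average F1 is the mean over CSF/GM/WM only", {
  expect_equal(tissueAverageF1(c(0.9528, 0.9203, 0.9034)), 0.9255)
  expect_equal(tissueAverageF1(c(1, 1, 1)), 1)
  expect_equal(tissueAverageF1(c(0, 0, 0.9)), 0.3)
  expect_error(tissueAverageF1(c(0.9, 0.9)), "three")
  expect_error(tissueAverageF1(c(0.9, 0.9, 1.2)), "0, 1")
})

test_that("metrics and confusion CSV writers produce readable tables", {
  y <- randLabels(c(4, 4, 4), seed = 801)
  p <- randLabels(c(4, 4, 4), seed = 802)
  cm <- tissueConfusion(p, y, recordId = "r1")
  dir <- withr::local_tempdir()
  writeConfusionCSV(cm, file.path(dir, "cm.csv"))
  back <- utils::read.csv(file.path(dir, "cm.csv"), row.names = 1)
  expect_equal(unname(as.matrix(back)), unname(confusionCounts(cm)))
  writeMetricsCSV(list(metricsFromConfusion(cm)), file.path(dir, "m.csv"))
  m <- utils::read.csv(file.path(dir, "m.csv"))
  expect_identical(m$record, "r1")
  expect_true("DSC_GM" %in% colnames(m))
})
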