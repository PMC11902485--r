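#' @include AllClasses.R
NULL

.probsArray <- function(probs) if (is(probs, "ProbabilityVolume")) probs@probs else probs
.labelsArray <- function(truth) if (is(truth, "LabelVolume")) truth@labels else truth

.checkExtents <- function(p, y) {
  if (!identical(dim(p)[1:3], dim(y)[1:3]))
    stop("probability and label extents differ: ",
         paste(dim(p)[1:3], collapse = "x"), " vs ",
         paste(dim(y)[1:3], collapse = "x"))
}

#' Soft Dice score per class
#'
#' For class `c`, `(2 * sum(p_c * y_c) + s) / (sum(p_c) + sum(y_c) + s)`
#' with `y` the one-hot ground truth and `s` a small smoothing constant.
#' With one-hot probabilities this reduces to the hard-count Dice; classes
#' absent from both prediction and truth score ~1 thanks to the smoothing.
#'
#' @param probs a [ProbabilityVolume-class] or 4-D array.
#' @param truth a [LabelVolume-class] or 3-D integer array.
#' @param smoothing smoothing constant `s` (default 1e-6).
#' @return named numeric vector, one soft Dice value per class.
#' @export
softDicePerClass <- function(probs, truth, smoothing = 1e-6) {
  p <- .probsArray(probs)
  y <- .labelsArray(truth)
  .checkExtents(p, y)
  C <- dim(p)[4]
  pm <- matrix(p, ncol = C)
  yi <- as.integer(y) + 1L
  vals <- vapply(seq_len(C), function(c) {
    yc <- as.numeric(yi == c)
    (2 * sum(pm[, c] * yc) + smoothing) /
      (sum(pm[, c]) + sum(yc) + smoothing)
  }, numeric(1))
  names(vals) <- if (C == length(ISOSEG_CLASSES)) ISOSEG_CLASSES else
    sprintf("class%d", seq_len(C) - 1L)
  vals
}

#' Hybrid cross-entropy + soft-Dice training cost
#'
#' `wCe * mean(-log p_true) + wDice * (1 - mean_c softDice_c)`, the sparse
#' categorical cross entropy and the Dice cost with equal weights by
#' default. The Dice mean runs over all classes including background
#' (`diceClasses = "all"`); `"tissues"` restricts it to CSF/GM/WM.
#' Probabilities are clipped below at `clip` inside the logarithm.
#'
#' @inheritParams softDicePerClass
#' @param wCe,wDice the two cost weights (default 0.5 each).
#' @param clip log-probability clipping constant.
#' @param diceClasses `"all"` or `"tissues"`.
#' @return scalar cost (non-negative).
#' @export
hybridLoss <- function(probs, truth, wCe = 0.5, wDice = 0.5,
                       smoothing = 1e-6, clip = 1e-7, diceClasses = "all") {
  p <- .probsArray(probs)
  y <- .labelsArray(truth)
  .checkExtents(p, y)
  C <- dim(p)[4]
  pm <- matrix(p, ncol = C)
  yi <- as.integer(y) + 1L
  ptrue <- pm[cbind(seq_along(yi), yi)]
  ce <- -mean(log(pmax(ptrue, clip)))
  dice <- softDicePerClass(p, y, smoothing)
  if (diceClasses == "tissues") dice <- dice[-1]
  ce * wCe + wDice * (1 - mean(dice))
}

# Loss value and gradient w.r.t. the pre-softmax logits, fused through the
# softmax Jacobian. Used by the trainer; probs must come from the model's
# own softmax so the Jacobian identity applies.
.hybridLossGrad <- function(probs, truth, wCe = 0.5, wDice = 0.5,
                            smoothing = 1e-6, clip = 1e-7,
                            diceClasses = "all") {
  d <- dim(probs)
  C <- d[4]
  N <- prod(d[1:3])
  pm <- matrix(probs, ncol = C)
  yi <- as.integer(truth) + 1L
  Y <- matrix(0, N, C)
  Y[cbind(seq_len(N), yi)] <- 1
  ptrue <- pm[cbind(seq_len(N), yi)]
  ce <- -mean(log(pmax(ptrue, clip)))
  # dCE/dp on the true class only, zero where clipped
  gP <- matrix(0, N, C)
  unclipped <- ptrue > clip
  gce <- numeric(N)
  gce[unclipped] <- -wCe / (N * ptrue[unclipped])
  gP[cbind(seq_len(N), yi)] <- gce
  # soft Dice and its gradient
  num <- 2 * colSums(pm * Y) + smoothing
  den <- colSums(pm) + colSums(Y) + smoothing
  dice <- num / den
  keep <- if (diceClasses == "tissues") 2:C else seq_len(C)
  nKeep <- length(keep)
  for (c in keep) {
    gD <- (2 * Y[, c] * den[c] - num[c]) / den[c]^2
    gP[, c] <- gP[, c] - wDice * gD / nKeep
  }
  loss <- wCe * ce + wDice * (1 - mean(dice[keep]))
  # softmax Jacobian: dL/dz_c = p_c * (dL/dp_c - sum_k p_k dL/dp_k)
  dot <- rowSums(pm * gP)
  gZ <- pm * (gP - dot)
  dim(gZ) <- d
  list(loss = loss, gradLogits = gZ)
}

#' Voxelwise confusion matrix
#'
#' Counts `counts[a, p]` = number of voxels with actual class `a` and
#' predicted class `p` (actual rows, predicted columns).
#'
#' @param pred predicted [LabelVolume-class] or integer array.
#' @param truth ground-truth [LabelVolume-class] or integer array.
#' @param nClasses number of classes.
#' @param recordId record tag.
#' @return a [TissueConfusion-class].
#' @export
tissueConfusion <- function(pred, truth, nClasses = 4L, recordId = "record") {
  p <- .labelsArray(pred)
  y <- .labelsArray(truth)
  if (!identical(dim(p), dim(y))) stop("pred and truth extents differ")
  if (max(p) >= nClasses || max(y) >= nClasses || min(p) < 0 || min(y) < 0)
    stop("labels out of range 0..", nClasses - 1L)
  cls <- if (nClasses == length(ISOSEG_CLASSES)) ISOSEG_CLASSES else
    sprintf("class%d", seq_len(nClasses) - 1L)
  idx <- as.integer(y) * nClasses + as.integer(p) + 1L
  cm <- matrix(tabulate(idx, nbins = nClasses^2), nrow = nClasses,
               byrow = TRUE, dimnames = list(actual = cls, predicted = cls))
  new("TissueConfusion", counts = cm, recordId = recordId)
}

#' Per-record metrics from a confusion matrix
#'
#' For each tissue class: sensitivity `TPR = TP / rowSum`, precision
#' `PPV = TP / colSum`, Dice `DSC = 2 TP / (rowSum + colSum)`; plus overall
#' accuracy `ACC = trace / total` over all classes including background.
#' A metric whose denominator is zero is reported as `NA` (flagged
#' missing), never as 0.
#'
#' @param cm a [TissueConfusion-class].
#' @return a [MetricsReport-class].
#' @export
metricsFromConfusion <- function(cm) {
  m <- cm@counts
  n <- nrow(m)
  tp <- diag(m)
  rs <- rowSums(m)
  cs <- colSums(m)
  safe <- function(num, den) ifelse(den > 0, num / den, NA_real_)
  tpr <- safe(tp, rs)
  ppv <- safe(tp, cs)
  dsc <- safe(2 * tp, rs + cs)
  tissues <- 2:n  # all classes except background (code 0)
  mk <- function(v) stats::setNames(v[tissues], rownames(m)[tissues])
  new("MetricsReport", tpr = mk(tpr), ppv = mk(ppv), dsc = mk(dsc),
      acc = sum(tp) / sum(m), recordId = cm@recordId)
}

#' Distribution summary of a numeric vector
#'
#' Mean, sample standard deviation (n-1), minimum, quartiles by linear
#' interpolation between order statistics, and maximum — the aggregation
#' used for cohort tables.
#'
#' @param x numeric vector.
#' @param naRm drop `NA` entries first.
#' @return named numeric: `avg`, `std`, `min`, `Q1`, `Q2`, `Q3`, `max`.
#'   `std` is `NA` for fewer than two values.
#' @export
summaryStats <- function(x, naRm = FALSE) {
  if (naRm) x <- x[!is.na(x)]
  if (length(x) == 0L) stop("empty vector")
  q <- stats::quantile(x, probs = c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  c(avg = mean(x), std = if (length(x) >= 2L) stats::sd(x) else NA_real_,
    min = min(x), Q1 = q[1], Q2 = q[2], Q3 = q[3], max = max(x))
}

.reportRow <- function(r) {
  v <- c(r@tpr, r@ppv, r@dsc, ACC = r@acc)
  names(v) <- c(paste0("TPR_", names(r@tpr)), paste0("PPV_", names(r@ppv)),
                paste0("DSC_", names(r@dsc)), "ACC")
  v
}

#' Aggregate per-record metrics into a cohort summary table
#'
#' Accepts either a list of [MetricsReport-class] objects or a
#' data.frame/matrix with one row per record and one column per metric,
#' and summarizes each metric with [summaryStats()].
#'
#' @param reports list of reports, or a per-record metric table.
#' @param naRm drop per-record `NA` metrics before aggregating.
#' @return data.frame with rows `avg`, `std`, `min`, `Q1`, `Q2`, `Q3`,
#'   `max` and one column per metric.
#' @export
aggregateReports <- function(reports, naRm = FALSE) {
  if (is.list(reports) && length(reports) > 0L &&
      is(reports[[1]], "MetricsReport")) {
    tab <- do.call(rbind, lapply(reports, .reportRow))
  } else {
    tab <- as.matrix(reports)
  }
  if (nrow(tab) == 0L) stop("no reports to aggregate")
  out <- apply(tab, 2, summaryStats, naRm = naRm)
  as.data.frame(out)
}

#' Tissue-averaged F1 score
#'
#' Arithmetic mean of the three per-tissue Dice/F1 values (CSF, GM, WM),
#' background excluded — the single-number benchmark used for method
#' comparison.
#'
#' @param perTissueDsc numeric length-3 vector of per-tissue Dice values
#'   in `[0, 1]`.
#' @return scalar mean.
#' @export
tissueAverageF1 <- function(perTissueDsc) {
  if (length(perTissueDsc) != 3L)
    stop("expected exactly three per-tissue values")
  if (any(perTissueDsc < 0 | perTissueDsc > 1, na.rm = TRUE))
    stop("Dice values must lie in [0, 1]")
  mean(perTissueDsc)
}

#' Write per-record metrics to CSV
#'
#' @param reports list of [MetricsReport-class].
#' @param path output CSV path.
#' @return `invisible(path)`.
#' @export
writeMetricsCSV <- function(reports, path) {
  tab <- do.call(rbind, lapply(reports, .reportRow))
  df <- data.frame(record = vapply(reports, function(r) r@recordId,
                                   character(1)), tab,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a confusion matrix to CSV (actual rows x predicted columns)
#'
#' @param cm a [TissueConfusion-class].
#' @param path output CSV path.
#' @return `invisible(path)`.
#' @export
writeConfusionCSV <- function(cm, path) {
  utils::write.csv(as.data.frame(cm@counts), path, row.names = TRUE)
  invisible(path)
}
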