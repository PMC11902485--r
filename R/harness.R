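#' @include AllClasses.R
NULL

#' Training configuration
#'
#' @param epochs number of epochs; the full-scale protocol trains for
#'   1000, reduced experiments use far fewer.
#' @param optimizer only `"adam"`.
#' @param learningRate ADAM step size (default 1e-3, the usual ADAM
#'   convention).
#' @param seed base RNG seed; fold `k` of cross-validation initializes its
#'   model with `seed + k`.
#' @param checkpointRule `"lowest-cost"`: keep the parameters of the epoch
#'   with the lowest evaluated mean training cost.
#' @param deterministicMode derive all randomness (init, dropout) from
#'   `seed` so runs are bitwise reproducible.
#' @param holdoutFraction optional fraction of training records used only
#'   for checkpoint selection; 0 (default) selects on training cost.
#' @return a [TrainConfig-class].
#' @export
trainConfig <- function(epochs = 1000L, optimizer = "adam",
                        learningRate = 1e-3, seed = 42L,
                        checkpointRule = "lowest-cost",
                        deterministicMode = TRUE, holdoutFraction = 0) {
  new("TrainConfig", epochs = as.integer(epochs), optimizer = optimizer,
      learningRate = learningRate, seed = as.integer(seed),
      checkpointRule = checkpointRule,
      deterministicMode = deterministicMode,
      holdoutFraction = holdoutFraction)
}

.trainableFields <- c("W", "b", "gamma", "beta")

.zeroLike <- function(params) {
  lapply(params, function(p) {
    out <- list()
    for (f in .trainableFields)
      if (!is.null(p[[f]]))
        out[[f]] <- if (is.null(dim(p[[f]]))) numeric(length(p[[f]]))
                    else array(0, dim = dim(p[[f]]))
    out
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.adamStep <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-7) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t
  c2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    for (f in names(grads[[nm]])) {
      g <- grads[[nm]][[f]]
      m <- state$m[[nm]][[f]] * beta1 + (1 - beta1) * g
      v <- state$v[[nm]][[f]] * beta2 + (1 - beta2) * g * g
      state$m[[nm]][[f]] <- m
      state$v[[nm]][[f]] <- v
      params[[nm]][[f]] <- params[[nm]][[f]] -
        lr * (m / c1) / (sqrt(v / c2) + eps)
    }
  }
  list(params = params, state = state)
}

.recordXY <- function(rec) {
  x <- if (is(rec$x, "MultiModalVolume")) rec$x@channels else rec$x
  y <- if (is(rec$y, "LabelVolume")) rec$y@labels else rec$y
  list(x = x, y = y)
}

#' Evaluate the mean training cost of a model on a record set
#'
#' Inference-mode forward pass (dropout off; batch norm uses each
#' volume's own statistics) followed by the hybrid cost, averaged over
#' records.
#' This is the quantity the checkpoint rule minimizes, so re-evaluating a
#' restored checkpoint reproduces its recorded cost.
#'
#' @param model a [SegModel-class].
#' @param records list of records, each with `x` ([MultiModalVolume-class]
#'   or 4-D array) and `y` ([LabelVolume-class] or integer array).
#' @param ... passed to [hybridLoss()].
#' @return mean cost.
#' @export
evaluateCost <- function(model, records, ...) {
  mean(vapply(records, function(rec) {
    xy <- .recordXY(rec)
    probs <- .netForward(model, xy$x, training = FALSE, keepCache = FALSE)$probs
    hybridLoss(probs, xy$y, ...)
  }, numeric(1)))
}

#' Train a segmentation model
#'
#' One volume per optimization step (batch of one), ADAM updates, and
#' best-model checkpointing: at the end of every epoch the mean training
#' cost is evaluated in inference mode and the parameters of the
#' lowest-cost epoch are kept. In deterministic mode the dropout stream of
#' epoch `e` is seeded with `cfg@seed + e`, so seeded runs reproduce their
#' history bitwise.
#'
#' @param model a [SegModel-class] (its initial parameters are the
#'   starting point).
#' @param records training records, each a list with `x` and `y` (see
#'   [evaluateCost()]).
#' @param cfg a [TrainConfig-class].
#' @param verbose print per-epoch costs.
#' @return list with `model` (checkpointed best parameters, inference
#'   mode), `history` (per-epoch evaluated mean cost), `bestEpoch`, and
#'   `stepCosts` (per-step in-training costs).
#' @export
trainModel <- function(model, records, cfg = trainConfig(epochs = 10L),
                       verbose = FALSE) {
  if (length(records) == 0L) stop("records must be non-empty")
  xys <- lapply(records, .recordXY)
  d1 <- dim(xys[[1]]$x)
  if (d1[4] != model@config@inChannels)
    stop("record channel count ", d1[4], " does not match model inChannels ",
         model@config@inChannels)
  nHold <- floor(cfg@holdoutFraction * length(xys))
  holdIdx <- if (nHold > 0) seq_len(nHold) else integer(0)
  trainIdx <- setdiff(seq_along(xys), holdIdx)
  if (length(trainIdx) == 0L) stop("holdoutFraction leaves no training records")

  params <- model@params
  state <- list(m = .zeroLike(params), v = .zeroLike(params), t = 0L)
  history <- numeric(cfg@epochs)
  stepCosts <- list()
  best <- Inf
  bestEpoch <- NA_integer_
  bestParams <- params
  work <- model
  for (e in seq_len(cfg@epochs)) {
    if (cfg@deterministicMode) set.seed(cfg@seed + e)
    costs <- numeric(length(trainIdx))
    for (j in seq_along(trainIdx)) {
      xy <- xys[[trainIdx[j]]]
      work@params <- params
      fw <- .netForward(work, xy$x, training = TRUE)
      lg <- .hybridLossGrad(fw$probs, xy$y)
      costs[j] <- lg$loss
      work@params <- params
      grads <- .netBackward(work, fw$cache, lg$gradLogits)
      upd <- .adamStep(params, grads, state, cfg@learningRate)
      params <- upd$params
      state <- upd$state
    }
    work@params <- params
    evalRecords <- if (length(holdIdx) > 0) records[holdIdx] else records[trainIdx]
    history[e] <- evaluateCost(work, evalRecords)
    stepCosts[[e]] <- costs
    if (history[e] < best) {
      best <- history[e]
      bestEpoch <- e
      bestParams <- params
    }
    if (verbose)
      message(sprintf("epoch %d/%d: step cost %.5f, eval cost %.5f%s",
                      e, cfg@epochs, mean(costs), history[e],
                      if (bestEpoch == e) " *" else ""))
  }
  out <- model
  out@params <- bestParams
  out@mode <- "inference"
  list(model = out, history = history, bestEpoch = bestEpoch,
       stepCosts = stepCosts)
}

#' Evaluate a segmentation against ground truth
#'
#' @param pred predicted [LabelVolume-class].
#' @param truth ground-truth [LabelVolume-class].
#' @param recordId record tag.
#' @return list with `confusion` ([TissueConfusion-class]) and `metrics`
#'   ([MetricsReport-class]).
#' @export
evaluateSegmentation <- function(pred, truth, recordId = "record") {
  cm <- tissueConfusion(pred, truth,
                        nClasses = length(truth@classNames),
                        recordId = recordId)
  list(confusion = cm, metrics = metricsFromConfusion(cm))
}

#' Leave-one-out cross-validation over a cohort
#'
#' One fold per record: fold `k` rebuilds the intensity standard scale
#' from the other records only (no test-set leakage), standardizes all
#' records against it, trains a freshly initialized model (seed
#' `cfg@seed + k`) on the training records, and evaluates on the held-out
#' record. Per-fold reports are aggregated into a cohort summary table.
#'
#' @param records cohort as returned by [generateCohort()] (each record a
#'   list with `t1`, `t2`, `labels`, `id`).
#' @param arch an [ArchitectureConfig-class]; the modality replication is
#'   derived from its `inChannels` (channels = 2 x replication).
#' @param cfg a [TrainConfig-class].
#' @param verbose print per-fold progress.
#' @return list with `folds` (list of [FoldResult-class]) and `summary`
#'   (cohort [aggregateReports()] table).
#' @export
runLOOCV <- function(records, arch = scaledArchConfig(),
                     cfg = trainConfig(epochs = 10L), verbose = FALSE) {
  n <- length(records)
  if (n < 2L) stop("leave-one-out cross-validation needs at least 2 records")
  if (arch@inChannels %% 2L != 0L)
    stop("arch inChannels must be even (two modalities)")
  replication <- arch@inChannels %/% 2L
  ids <- vapply(seq_len(n), function(k) records[[k]]$id %||% sprintf("rec%02d", k),
                character(1))
  folds <- vector("list", n)
  for (k in seq_len(n)) {
    trainIdx <- setdiff(seq_len(n), k)
    std <- standardizeCohort(records, trainIdx = trainIdx)
    iscale <- c(max(std$scales$t1@referenceAnchors),
                max(std$scales$t2@referenceAnchors))
    xy <- lapply(std$records, function(rec)
      list(x = recordInput(rec, replication, intensityScale = iscale),
           y = rec$labels))
    model <- buildModel(arch, seed = cfg@seed + k)
    foldCfg <- cfg
    foldCfg@seed <- cfg@seed + k
    tr <- trainModel(model, xy[trainIdx], foldCfg)
    pred <- predict(tr$model, xy[[k]]$x)
    ev <- evaluateSegmentation(pred$labels, records[[k]]$labels,
                               recordId = ids[k])
    folds[[k]] <- new("FoldResult", testRecordId = ids[k],
                      metrics = ev$metrics, confusion = ev$confusion,
                      history = tr$history,
                      bestEpoch = as.integer(tr$bestEpoch))
    if (verbose)
      message(sprintf("fold %d/%d (test %s): ACC %.4f", k, n, ids[k],
                      ev$metrics@acc))
  }
  summary <- aggregateReports(lapply(folds, function(f) f@metrics))
  list(folds = folds, summary = summary)
}
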