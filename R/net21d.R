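#' @include AllClasses.R
#' @useDynLib IsoSeg, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Batch-norm epsilon. Whole volumes are processed as a batch of one, so
# batch normalization degenerates to per-volume (instance) statistics;
# those same statistics are used at inference, which keeps inference
# deterministic and consistent with training (running averages cannot
# track weight-dependent statistics at one step per record).
BN_EPS <- 1e-3

#' Declarative (2+1)D U-Net architecture configuration
#'
#' The defaults reproduce the full-scale network: four encoder levels with
#' 65/32/16/8 filters (the decoder mirrors them bottom-up as 8/16/32/65), a
#' 4-filter bridge, six input channels (two modalities replicated three
#' times), four output classes, factorized kernels 1x3x3 (in-plane) then
#' 3x1x1 (across slices), 2x2x2 max pooling, ELU activations, dropout 0.2
#' and "same" zero padding.
#'
#' @param levels encoder depth.
#' @param filtersPerLevel filters per encoder level, top to bottom.
#' @param bridgeFilters filters in the bridge block.
#' @param inChannels,nClasses input channel and output class counts.
#' @param spatialKernel,sliceKernel factorized kernel extents.
#' @param pool pooling extents.
#' @param dropoutRate dropout fraction.
#' @param activation hidden activation ("elu").
#' @param paddingMode "same".
#' @return an [ArchitectureConfig-class].
#' @export
archConfig <- function(levels = 4L, filtersPerLevel = c(65L, 32L, 16L, 8L),
                       bridgeFilters = 4L, inChannels = 6L, nClasses = 4L,
                       spatialKernel = c(1L, 3L, 3L),
                       sliceKernel = c(3L, 1L, 1L), pool = c(2L, 2L, 2L),
                       dropoutRate = 0.2, activation = "elu",
                       paddingMode = "same") {
  new("ArchitectureConfig", levels = as.integer(levels),
      filtersPerLevel = as.integer(filtersPerLevel),
      bridgeFilters = as.integer(bridgeFilters),
      inChannels = as.integer(inChannels), nClasses = as.integer(nClasses),
      spatialKernel = as.integer(spatialKernel),
      sliceKernel = as.integer(sliceKernel), pool = as.integer(pool),
      dropoutRate = dropoutRate, activation = activation,
      paddingMode = paddingMode)
}

#' Reduced architecture profile for CPU-scale experiments
#'
#' Same topology as the default network with filter counts 16/8/4/2 and a
#' 2-filter bridge; two input channels (one copy of each modality).
#'
#' @param inChannels input channel count.
#' @return an [ArchitectureConfig-class].
#' @export
scaledArchConfig <- function(inChannels = 2L) {
  archConfig(filtersPerLevel = c(16L, 8L, 4L, 2L), bridgeFilters = 2L,
             inChannels = inChannels)
}

# ---- elementwise pieces ----------------------------------------------------

.elu <- function(x) {
  neg <- x < 0
  x[neg] <- expm1(x[neg])
  x
}

# derivative of ELU from its *output* y: 1 for y > 0, y + 1 otherwise
.eluGradFromOutput <- function(y) {
  g <- y + 1
  g[y > 0] <- 1
  g
}

.glorot <- function(kd, kh, kw, cin, cout) {
  k <- kd * kh * kw
  lim <- sqrt(6 / (k * cin + k * cout))
  array(stats::runif(k * cin * cout, -lim, lim), dim = c(kd, kh, kw, cin, cout))
}

.convParams <- function(kernel, cin, cout) {
  list(W = .glorot(kernel[1], kernel[2], kernel[3], cin, cout),
       b = numeric(cout))
}

.bnParams <- function(c) {
  list(gamma = rep(1, c), beta = numeric(c))
}

# ---- model construction ----------------------------------------------------

#' Build one (2+1)D convolution pair
#'
#' The factorized replacement for a dense 3x3x3 convolution: an in-plane
#' 1x3x3 convolution followed by an across-slice 3x1x1 convolution, each
#' with `filters` output channels and its own ELU nonlinearity (no
#' intermediate channel bottleneck), both stride 1 with "same" padding so
#' spatial extents are preserved.
#'
#' @param inChannels input channel count.
#' @param filters output channels of both stages.
#' @param cfg an [ArchitectureConfig-class] supplying the kernel extents.
#' @return a list with elements `spatial` and `slice` (each `W`, `b`) and
#'   attribute `paramCount` (number of trainable scalars).
#' @export
buildConv21dPair <- function(inChannels, filters, cfg = archConfig()) {
  if (inChannels < 1L || filters < 1L) stop("counts must be positive")
  pair <- list(spatial = .convParams(cfg@spatialKernel, inChannels, filters),
               slice = .convParams(cfg@sliceKernel, filters, filters))
  attr(pair, "paramCount") <-
    length(pair$spatial$W) + length(pair$spatial$b) +
    length(pair$slice$W) + length(pair$slice$b)
  pair
}

#' Apply a (2+1)D convolution pair to a 4-D activation tensor
#'
#' @param pair result of [buildConv21dPair()].
#' @param x numeric 4-D array `(slice, row, col, channel)`.
#' @return numeric 4-D array with `filters` channels and unchanged spatial
#'   extents.
#' @export
applyConv21dPair <- function(pair, x) {
  y <- .convFwd(x, pair$spatial$W, pair$spatial$b)
  y <- .elu(y)
  y <- .convFwd(y, pair$slice$W, pair$slice$b)
  .elu(y)
}

.convFwd <- function(x, W, b) {
  d <- dim(x); wd <- dim(W)
  y <- conv3d_fwd(as.double(x), as.integer(d), as.double(W),
                  as.integer(wd), as.double(b))
  dim(y) <- c(d[1:3], wd[5])
  y
}

# Append op helper used by buildModel
.op <- function(type, name = NULL, ...) c(list(type = type, name = name), list(...))

#' Build the (2+1)D U-Net
#'
#' Constructs the execution plan and seeded initial parameters of the
#' network: per encoder level a double (2+1)D pair with batch norm,
#' dropout, a skip tap and 2x2x2 max pooling; a bridge of two full pairs;
#' per decoder level a 2x2x2 stride-2 transpose convolution with ELU,
#' concatenation of the skip features, and a double pair with batch norm
#' and dropout; finally a 1x1x1 softmax classifier. Weights use seeded
#' Glorot-uniform initialization, so two builds from the same config and
#' seed are bitwise identical.
#'
#' @param cfg an [ArchitectureConfig-class].
#' @param seed integer RNG seed for weight initialization.
#' @return a [SegModel-class] in inference mode.
#' @export
buildModel <- function(cfg = archConfig(), seed = 42L) {
  validObject(cfg)
  L <- cfg@levels
  f <- cfg@filtersPerLevel
  ops <- list()
  params <- list()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  addConv <- function(name, kernel, cin, cout, activation) {
    params[[name]] <<- .convParams(kernel, cin, cout)
    ops[[length(ops) + 1L]] <<- .op("conv", name, activation = activation)
  }
  addBN <- function(name, c) {
    params[[name]] <<- .bnParams(c)
    ops[[length(ops) + 1L]] <<- .op("bn", name)
  }
  addPair <- function(prefix, cin, cout) {
    addConv(paste0(prefix, "_s"), cfg@spatialKernel, cin, cout, cfg@activation)
    addConv(paste0(prefix, "_t"), cfg@sliceKernel, cout, cout, cfg@activation)
  }
  addBlockBody <- function(prefix, cin, cout) {
    addPair(paste0(prefix, "_p1"), cin, cout)
    addBN(paste0(prefix, "_bn1"), cout)
    ops[[length(ops) + 1L]] <<- .op("dropout", paste0(prefix, "_drop"))
    addPair(paste0(prefix, "_p2"), cout, cout)
    addBN(paste0(prefix, "_bn2"), cout)
  }

  cin <- cfg@inChannels
  for (l in seq_len(L)) {
    addBlockBody(sprintf("enc%d", l), cin, f[l])
    ops[[length(ops) + 1L]] <- .op("skipsave", sprintf("skip%d", l), level = l)
    ops[[length(ops) + 1L]] <- .op("pool", sprintf("pool%d", l))
    cin <- f[l]
  }
  addBlockBody("bridge", cin, cfg@bridgeFilters)
  cin <- cfg@bridgeFilters
  for (l in rev(seq_len(L))) {
    nm <- sprintf("dec%d_up", l)
    params[[nm]] <- list(W = .glorot(2, 2, 2, cin, f[l]), b = numeric(f[l]))
    ops[[length(ops) + 1L]] <- .op("tconv", nm, activation = cfg@activation)
    ops[[length(ops) + 1L]] <- .op("concat", sprintf("dec%d_cat", l), level = l)
    addBlockBody(sprintf("dec%d", l), 2L * f[l], f[l])
    cin <- f[l]
  }
  addConv("head", c(1L, 1L, 1L), cin, cfg@nClasses, "softmax")

  new("SegModel", config = cfg, ops = ops, params = params,
      mode = "inference", seed = as.integer(seed))
}

#' Feature-map extents at a pooling level
#'
#' Each of the `level` pooling stages halves every spatial extent, so the
#' result is `inputExtents / 2^level`; e.g. a 112x192x144 input enters the
#' bridge (level 4) at 7x12x9.
#'
#' @param cfg an [ArchitectureConfig-class].
#' @param inputExtents integer length-3 spatial extents.
#' @param level integer in `0:cfg@levels`.
#' @return integer length-3 extents.
#' @export
levelShape <- function(cfg, inputExtents, level) {
  level <- as.integer(level)
  if (level < 0L || level > cfg@levels)
    stop("level must lie in 0..", cfg@levels)
  f <- cfg@pool[1]^level  # isotropic pooling: each level divides extents by 2
  if (any(inputExtents %% f != 0L))
    stop("input extents ", paste(inputExtents, collapse = "x"),
         " are not divisible by 2^", level)
  as.integer(inputExtents / f)
}

#' Shape trace of the encoder/bridge path
#'
#' Analytic per-level feature-map extents for a given input, as a
#' data.frame with one row per stage (input, each post-pooling level, and
#' the bridge input).
#'
#' @param cfg an [ArchitectureConfig-class].
#' @param inputExtents integer length-3 spatial extents.
#' @return data.frame with columns `stage`, `slices`, `rows`, `cols`.
#' @export
shapeTrace <- function(cfg, inputExtents) {
  lv <- 0:cfg@levels
  ext <- t(vapply(lv, function(l) levelShape(cfg, inputExtents, l),
                  integer(3)))
  stage <- c("input", sprintf("after_pool%d", seq_len(cfg@levels)))
  stage[length(stage)] <- "bridge_input"
  data.frame(stage = stage, slices = ext[, 1], rows = ext[, 2],
             cols = ext[, 3], stringsAsFactors = FALSE)
}

# ---- forward / backward ----------------------------------------------------

.bnFwd <- function(x, p, keepCache = FALSE) {
  d <- dim(x); C <- d[4]
  xm <- matrix(x, ncol = C)
  mu <- colMeans(xm)
  ctr <- sweep(xm, 2, mu)
  va <- colMeans(ctr * ctr)
  invstd <- 1 / sqrt(va + BN_EPS)
  xhat <- sweep(ctr, 2, invstd, "*")
  y <- sweep(sweep(xhat, 2, p$gamma, "*"), 2, p$beta, "+")
  dim(y) <- d
  list(y = y, cache = if (keepCache) list(xhat = xhat, invstd = invstd) else NULL)
}

.bnBwd <- function(gy, p, cache) {
  d <- dim(gy); C <- d[4]; N <- prod(d[1:3])
  gym <- matrix(gy, ncol = C)
  xhat <- cache$xhat
  ggamma <- colSums(gym * xhat)
  gbeta <- colSums(gym)
  # gx = gamma*invstd/N * (N*gy - gbeta - xhat*ggamma)
  gx <- sweep(gym, 2, gbeta / N) - sweep(xhat, 2, ggamma / N, "*")
  gx <- sweep(gx, 2, p$gamma * cache$invstd, "*")
  dim(gx) <- d
  list(gx = gx, ggamma = ggamma, gbeta = gbeta)
}

.softmax4 <- function(z) {
  d <- dim(z); C <- d[4]
  zm <- matrix(z, ncol = C)
  zm <- zm - apply(zm, 1, max)
  e <- exp(zm)
  pm <- e / rowSums(e)
  array(pm, dim = d)
}

# Execute the op list. Returns list(probs, cache) in training mode (cache
# holds everything backward needs) or list(probs) otherwise.
.netForward <- function(model, x, training = FALSE, keepCache = training) {
  cfg <- model@config
  params <- model@params
  skips <- list()
  cache <- if (keepCache) vector("list", length(model@ops)) else NULL
  for (i in seq_along(model@ops)) {
    op <- model@ops[[i]]
    p <- params[[op$name]]
    if (op$type == "conv") {
      xin <- x
      z <- .convFwd(xin, p$W, p$b)
      if (op$activation == "elu") {
        x <- .elu(z)
        if (keepCache) cache[[i]] <- list(xin = xin, y = x)
      } else if (op$activation == "softmax") {
        x <- .softmax4(z)
        if (keepCache) cache[[i]] <- list(xin = xin)
      } else {
        x <- z
        if (keepCache) cache[[i]] <- list(xin = xin)
      }
    } else if (op$type == "bn") {
      r <- .bnFwd(x, p, keepCache)
      x <- r$y
      if (keepCache) cache[[i]] <- r$cache
    } else if (op$type == "dropout") {
      if (training && cfg@dropoutRate > 0) {
        keepP <- 1 - cfg@dropoutRate
        mask <- (stats::runif(length(x)) < keepP) / keepP
        x <- x * mask
        if (keepCache) cache[[i]] <- list(mask = mask)
      }
    } else if (op$type == "skipsave") {
      skips[[op$level]] <- x
    } else if (op$type == "pool") {
      d <- dim(x)
      r <- maxpool3d_fwd(as.double(x), as.integer(d))
      if (keepCache) cache[[i]] <- list(argmax = r$argmax, inLen = length(x))
      x <- r$y
      dim(x) <- c(d[1:3] %/% 2L, d[4])
    } else if (op$type == "tconv") {
      xin <- x
      d <- dim(x)
      z <- tconv3d_fwd(as.double(x), as.integer(d), as.double(p$W),
                       as.double(p$b))
      dim(z) <- c(d[1:3] * 2L, length(p$b))
      x <- .elu(z)
      if (keepCache) cache[[i]] <- list(xin = xin, y = x)
    } else if (op$type == "concat") {
      sk <- skips[[op$level]]
      d <- dim(x)
      x <- array(c(x, sk), dim = c(d[1:3], d[4] + dim(sk)[4]))
      if (keepCache) cache[[i]] <- list(mainChannels = d[4])
    }
  }
  list(probs = x, cache = cache)
}

# Backward pass from the gradient w.r.t. the head-conv logits.
# Returns a named list of per-parameter gradients.
.netBackward <- function(model, cache, gz) {
  params <- model@params
  grads <- list()
  gskip <- vector("list", model@config@levels)
  g <- gz
  for (i in rev(seq_along(model@ops))) {
    op <- model@ops[[i]]
    cc <- cache[[i]]
    p <- params[[op$name]]
    if (op$type == "conv") {
      if (op$activation == "elu") g <- g * .eluGradFromOutput(cc$y)
      xin <- cc$xin
      r <- conv3d_bwd(as.double(xin), as.integer(dim(xin)), as.double(p$W),
                      as.integer(dim(p$W)), as.double(g))
      grads[[op$name]] <- list(W = array(r$gw, dim = dim(p$W)), b = r$gb)
      g <- r$gx
      dim(g) <- dim(xin)
    } else if (op$type == "bn") {
      r <- .bnBwd(g, p, cc)
      grads[[op$name]] <- list(gamma = r$ggamma, beta = r$gbeta)
      g <- r$gx
    } else if (op$type == "dropout") {
      if (!is.null(cc)) g <- g * cc$mask
    } else if (op$type == "skipsave") {
      if (!is.null(gskip[[op$level]])) g <- g + gskip[[op$level]]
    } else if (op$type == "pool") {
      d <- dim(g)
      g <- maxpool3d_bwd(cc$argmax, as.double(g), cc$inLen)
      dim(g) <- c(d[1:3] * 2L, d[4])
    } else if (op$type == "tconv") {
      g <- g * .eluGradFromOutput(cc$y)
      xin <- cc$xin
      r <- tconv3d_bwd(as.double(xin), as.integer(dim(xin)), as.double(p$W),
                       length(p$b), as.double(g))
      grads[[op$name]] <- list(W = array(r$gw, dim = dim(p$W)), b = r$gb)
      g <- r$gx
      dim(g) <- dim(xin)
    } else if (op$type == "concat") {
      d <- dim(g)
      cm <- cc$mainChannels
      gmain <- g[, , , seq_len(cm), drop = FALSE]
      gsk <- g[, , , cm + seq_len(d[4] - cm), drop = FALSE]
      lv <- op$level
      gskip[[lv]] <- if (is.null(gskip[[lv]])) gsk else gskip[[lv]] + gsk
      g <- gmain
    }
  }
  grads
}

#' @describeIn parameterCount trainable scalar count of a built model
#' @export
setMethod("parameterCount", "SegModel", function(x) {
  sum(vapply(x@params, function(p) {
    length(p$W) + length(p$b) + length(p$gamma) + length(p$beta)
  }, numeric(1)))
})

#' Layer-by-layer summary of a built model
#'
#' One row per layer in execution order (input layer included), reporting
#' the layer type, filter count, kernel extents, strides, pool extents,
#' activation and dropout rate — the shape audit used to verify the
#' construction against the published layer table.
#'
#' @param model a [SegModel-class].
#' @return data.frame with columns `layer`, `filters`, `kernel`, `strides`,
#'   `pool`, `activation`, `dropout`.
#' @export
layerTable <- function(model) {
  fmt <- function(v) paste0("(", paste(v, collapse = ", "), ")")
  rows <- list(data.frame(layer = "InputLayer", filters = NA_integer_,
                          kernel = NA_character_, strides = NA_character_,
                          pool = NA_character_, activation = NA_character_,
                          dropout = NA_real_, stringsAsFactors = FALSE))
  cfg <- model@config
  for (op in model@ops) {
    p <- model@params[[op$name]]
    row <- switch(op$type,
      conv = data.frame(layer = "Conv3D", filters = dim(p$W)[5],
                        kernel = fmt(dim(p$W)[1:3]), strides = fmt(c(1, 1, 1)),
                        pool = NA_character_, activation = op$activation,
                        dropout = NA_real_, stringsAsFactors = FALSE),
      bn = data.frame(layer = "BN", filters = NA_integer_,
                      kernel = NA_character_, strides = NA_character_,
                      pool = NA_character_, activation = NA_character_,
                      dropout = NA_real_, stringsAsFactors = FALSE),
      dropout = data.frame(layer = "Dropout", filters = NA_integer_,
                           kernel = NA_character_, strides = NA_character_,
                           pool = NA_character_, activation = NA_character_,
                           dropout = cfg@dropoutRate, stringsAsFactors = FALSE),
      pool = data.frame(layer = "MPool3D", filters = NA_integer_,
                        kernel = NA_character_, strides = fmt(cfg@pool),
                        pool = fmt(cfg@pool), activation = NA_character_,
                        dropout = NA_real_, stringsAsFactors = FALSE),
      tconv = data.frame(layer = "ConvT3d", filters = dim(p$W)[5],
                         kernel = fmt(dim(p$W)[1:3]), strides = fmt(c(2, 2, 2)),
                         pool = NA_character_, activation = op$activation,
                         dropout = NA_real_, stringsAsFactors = FALSE),
      concat = data.frame(layer = "Concatenate", filters = NA_integer_,
                          kernel = NA_character_, strides = NA_character_,
                          pool = NA_character_, activation = NA_character_,
                          dropout = NA_real_, stringsAsFactors = FALSE),
      skipsave = NULL)
    if (!is.null(row)) rows[[length(rows) + 1L]] <- row
  }
  do.call(rbind, rows)
}

.padToMultiple <- function(x, mult) {
  d <- dim(x)
  tgt <- as.integer(ceiling(d[1:3] / mult) * mult)
  if (all(tgt == d[1:3])) return(list(x = x, pad = c(0L, 0L, 0L), orig = d[1:3]))
  lo <- (tgt - d[1:3]) %/% 2L
  out <- array(0, dim = c(tgt, d[4]))
  out[lo[1] + seq_len(d[1]), lo[2] + seq_len(d[2]), lo[3] + seq_len(d[3]), ] <- x
  list(x = out, pad = lo, orig = d[1:3])
}

#' Segment a multi-modal volume
#'
#' Runs the forward pass in inference mode (dropout inactive; batch norm
#' normalizes by the input volume's own per-channel statistics, so
#' inference is deterministic) and returns the voxelwise class probabilities
#' together with the argmax segmentation. Argmax ties break toward the
#' lowest class index, deterministically.
#'
#' @param object a [SegModel-class].
#' @param newdata a [MultiModalVolume-class] whose channel count matches
#'   the model's `inChannels`.
#' @param padInput when TRUE, inputs whose extents are not divisible by
#'   `2^levels` are symmetrically zero-padded and the output cropped back;
#'   when FALSE (default) such inputs are an error.
#' @param ... unused.
#' @return list with elements `probabilities` ([ProbabilityVolume-class])
#'   and `labels` ([LabelVolume-class]).
#' @export
setMethod("predict", "SegModel", function(object, newdata, padInput = FALSE, ...) {
  cfg <- object@config
  x <- newdata@channels
  d <- dim(x)
  if (d[4] != cfg@inChannels)
    stop("input has ", d[4], " channels; model expects ", cfg@inChannels)
  mult <- 2L^cfg@levels
  padded <- NULL
  if (any(d[1:3] %% mult != 0L)) {
    if (!padInput)
      stop("input extents ", paste(d[1:3], collapse = "x"),
           " are not divisible by 2^", cfg@levels,
           "; set padInput = TRUE to zero-pad")
    padded <- .padToMultiple(x, mult)
    x <- padded$x
  }
  probs <- .netForward(object, x, training = FALSE, keepCache = FALSE)$probs
  if (!is.null(padded)) {
    lo <- padded$pad; od <- padded$orig
    probs <- probs[lo[1] + seq_len(od[1]), lo[2] + seq_len(od[2]),
                   lo[3] + seq_len(od[3]), , drop = FALSE]
  }
  pd <- dim(probs)
  pm <- matrix(probs, ncol = pd[4])
  lab <- max.col(pm, ties.method = "first") - 1L
  cls <- if (cfg@nClasses == length(ISOSEG_CLASSES)) ISOSEG_CLASSES else
    sprintf("class%d", seq_len(cfg@nClasses) - 1L)
  list(
    probabilities = new("ProbabilityVolume", probs = probs, classNames = cls),
    labels = labelVolume(array(lab, dim = pd[1:3]), classNames = cls,
                         spacing = newdata@spacing, origin = newdata@origin))
})

# ---- weight serialization --------------------------------------------------

#' Save model weights and architecture manifest
#'
#' Weights go to an RDS file, the architecture to a JSON sidecar, so a
#' checkpoint is self-describing.
#'
#' @param model a [SegModel-class].
#' @param path output path for the weights (`.rds`); the manifest is
#'   written next to it with extension `.json`.
#' @return `invisible(path)`.
#' @export
saveModel <- function(model, path) {
  saveRDS(list(params = model@params, seed = model@seed, mode = model@mode),
          path)
  cfg <- model@config
  manifest <- list(levels = cfg@levels, filtersPerLevel = cfg@filtersPerLevel,
                   bridgeFilters = cfg@bridgeFilters,
                   inChannels = cfg@inChannels, nClasses = cfg@nClasses,
                   spatialKernel = cfg@spatialKernel,
                   sliceKernel = cfg@sliceKernel, pool = cfg@pool,
                   dropoutRate = cfg@dropoutRate, activation = cfg@activation,
                   paddingMode = cfg@paddingMode)
  jsonlite::write_json(manifest, sub("\\.rds$", ".json", path),
                       digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' Load a saved model
#'
#' @param path path given to [saveModel()].
#' @return a [SegModel-class].
#' @export
loadModel <- function(path) {
  st <- readRDS(path)
  m <- jsonlite::read_json(sub("\\.rds$", ".json", path),
                           simplifyVector = TRUE)
  cfg <- archConfig(levels = m$levels, filtersPerLevel = m$filtersPerLevel,
                    bridgeFilters = m$bridgeFilters, inChannels = m$inChannels,
                    nClasses = m$nClasses, spatialKernel = m$spatialKernel,
                    sliceKernel = m$sliceKernel, pool = m$pool,
                    dropoutRate = m$dropoutRate, activation = m$activation,
                    paddingMode = m$paddingMode)
  model <- buildModel(cfg, seed = st$seed)
  model@params <- st$params
  model@mode <- st$mode
  model
}
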