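test_that("conv pair parameter counts follow the per-stage formula", {
  pair <- buildConv21dPair(6L, 65L)
  # spatial stage: 1*3*3*6*65 + 65; slice stage: 3*1*1*65*65 + 65
  expect_identical(attr(pair, "paramCount"), 3575L + 12740L)
  countFor <- function(cin, f)
    (9L * cin * f + f) + (3L * f * f + f)
  for (case in list(c(2L, 16L), c(16L, 8L), c(8L, 4L)))
    expect_identical(attr(buildConv21dPair(case[1], case[2]), "paramCount"),
                     countFor(case[1], case[2]))
  expect_error(buildConv21dPair(0L, 5L), "positive")
})

test_that("conv pair preserves spatial extents and is linear at zero weights", {
  pair <- buildConv21dPair(2L, 3L)
  x <- randArray(c(8, 16, 16, 2), seed = 3)
  y <- applyConv21dPair(pair, x)
  expect_identical(dim(y), c(8L, 16L, 16L, 3L))
  pair$spatial$W[] <- 0; pair$spatial$b[] <- 0
  pair$slice$W[] <- 0; pair$slice$b[] <- 0
  expect_true(all(applyConv21dPair(pair, x) == 0))
})

test_that("level shapes halve per pooling stage and scale equivariantly", {
  cfg <- archConfig()
  expect_identical(levelShape(cfg, c(112L, 192L, 144L), 4), c(7L, 12L, 9L))
  expect_identical(levelShape(cfg, c(112L, 192L, 144L), 1), c(56L, 96L, 72L))
  expect_identical(levelShape(cfg, c(16L, 32L, 32L), 2), c(4L, 8L, 8L))
  for (k in 0:3)
    expect_identical(levelShape(cfg, 2L * c(16L, 32L, 32L), k),
                     2L * levelShape(cfg, c(16L, 32L, 32L), k))
  expect_error(levelShape(cfg, c(15L, 32L, 32L), 4), "divisible")
  tr <- shapeTrace(cfg, c(112L, 192L, 144L))
  expect_identical(tr$stage[nrow(tr)], "bridge_input")
  expect_identical(unlist(tr[nrow(tr), 2:4], use.names = FALSE), c(7L, 12L, 9L))
})

test_that("the built default model matches the published layer plan", {
  model <- buildModel(archConfig(), seed = 42L)
  tab <- layerTable(model)
  convs <- tab[tab$layer == "Conv3D", ]
  # filter sequence down the encoder, bridge, up the decoder, head
  expect_identical(convs$filters,
                   c(rep(c(65L, 32L, 16L, 8L), each = 4), rep(4L, 4),
                     rep(c(8L, 16L, 32L, 65L), each = 4), 4L))
  # (2+1)D alternation: within every pair a (1,3,3) precedes a (3,1,1)
  body <- convs[-nrow(convs), ]
  expect_true(all(body$kernel[c(TRUE, FALSE)] == "(1, 3, 3)"))
  expect_true(all(body$kernel[c(FALSE, TRUE)] == "(3, 1, 1)"))
  expect_true(all(body$activation == "elu"))
  # classifier head: 1x1x1, 4 filters, softmax
  head <- convs[nrow(convs), ]
  expect_identical(head$kernel, "(1, 1, 1)")
  expect_identical(head$filters, 4L)
  expect_identical(head$activation, "softmax")
  # four pooling and four transpose stages, pool/stride 2x2x2, ELU on ConvT
  expect_identical(sum(tab$layer == "MPool3D"), 4L)
  tc <- tab[tab$layer == "ConvT3d", ]
  expect_identical(tc$filters, c(8L, 16L, 32L, 65L))
  expect_true(all(tc$strides == "(2, 2, 2)"))
  expect_true(all(tc$activation == "elu"))
  expect_identical(sum(tab$layer == "Concatenate"), 4L)
  expect_identical(sum(tab$layer == "Dropout"), 9L)
  expect_identical(sum(tab$layer == "BN"), 18L)
  # one dropout per block at the configured rate
  expect_true(all(tab$dropout[tab$layer == "Dropout"] == 0.2))
})

test_that("two builds with one seed are bitwise identical, different seeds differ", {
  m1 <- buildModel(scaledArchConfig(), seed = 42L)
  m2 <- buildModel(scaledArchConfig(), seed = 42L)
  expect_identical(m1@params, m2@params)
  m3 <- buildModel(scaledArchConfig(), seed = 43L)
  expect_false(identical(m1@params, m3@params))
})

test_that("inference produces normalized probabilities, argmax labels and deterministic output", {
  cfg <- archConfig(levels = 2L, filtersPerLevel = c(4L, 2L),
                    bridgeFilters = 2L, inChannels = 2L)
  model <- buildModel(cfg, seed = 9L)
  x <- new("MultiModalVolume", channels = randArray(c(8, 12, 8, 2), seed = 5),
           channelLabels = c("T1", "T2"))
  out1 <- predict(model, x)
  probs <- volValues(out1$probabilities)
  expect_identical(dim(probs), c(8L, 12L, 8L, 4L))
  sums <- rowSums(matrix(probs, ncol = 4))
  expect_lt(max(abs(sums - 1)), 1e-5)
  # labels are the per-voxel argmax
  pm <- matrix(probs, ncol = 4)
  expect_identical(as.integer(volValues(out1$labels)),
                   max.col(pm, ties.method = "first") - 1L)
  out2 <- predict(model, x)
  expect_identical(volValues(out1$probabilities), volValues(out2$probabilities))
})

test_that("argmax ties break toward the lowest class index", {
  probs <- array(0.25, dim = c(2, 2, 2, 4))
  pm <- matrix(probs, ncol = 4)
  expect_true(all(max.col(pm, ties.method = "first") == 1L))
  # the same rule through the exported path: force equal logits with zeroed head
  cfg <- archConfig(levels = 1L, filtersPerLevel = 2L, bridgeFilters = 2L,
                    inChannels = 2L)
  model <- buildModel(cfg, seed = 1L)
  model@params$head$W[] <- 0
  model@params$head$b[] <- 0
  x <- new("MultiModalVolume", channels = randArray(c(4, 4, 4, 2), seed = 6),
           channelLabels = c("T1", "T2"))
  out <- predict(model, x)
  expect_true(all(volValues(out$labels) == 0L))
})

test_that("channel mismatches and non-divisible extents are rejected; padding recovers", {
  model <- buildModel(scaledArchConfig(2L), seed = 2L)
  bad <- new("MultiModalVolume", channels = randArray(c(16, 16, 16, 4), seed = 1),
             channelLabels = rep("T1", 4))
  expect_error(predict(model, bad), "channels")
  odd <- new("MultiModalVolume", channels = randArray(c(18, 16, 16, 2), seed = 1),
             channelLabels = c("T1", "T2"))
  expect_error(predict(model, odd), "divisible")
  padded <- predict(model, odd, padInput = TRUE)
  expect_identical(dim(volValues(padded$probabilities)), c(18L, 16L, 16L, 4L))
})

test_that("backward pass agrees with numerical differentiation", {
  ns <- asNamespace("IsoSeg")
  cfg <- archConfig(levels = 2L, filtersPerLevel = c(3L, 2L),
                    bridgeFilters = 2L, inChannels = 2L, dropoutRate = 0)
  model <- buildModel(cfg, seed = 11L)
  x <- randArray(c(4, 8, 8, 2), seed = 7)
  y <- randLabels(c(4, 8, 8), seed = 8)
  fw <- ns$.netForward(model, x, training = TRUE)
  lg <- ns$.hybridLossGrad(fw$probs, y)
  grads <- ns$.netBackward(model, fw$cache, lg$gradLogits)
  lossAt <- function(m) {
    f <- ns$.netForward(m, x, training = TRUE)
    ns$.hybridLossGrad(f$probs, y)$loss
  }
  eps <- 1e-5
  set.seed(99)
  for (nm in sample(names(grads), 6)) {
    for (f in names(grads[[nm]])) {
      arr <- model@params[[nm]][[f]]
      for (i in sample(length(arr), min(3, length(arr)))) {
        mp <- model; mp@params[[nm]][[f]][i] <- arr[i] + eps
        mm <- model; mm@params[[nm]][[f]][i] <- arr[i] - eps
        fd <- (lossAt(mp) - lossAt(mm)) / (2 * eps)
        an <- grads[[nm]][[f]][i]
        expect_lt(abs(fd - an) / max(1e-6, abs(fd) + abs(an)), 1e-5)
      }
    }
  }
})

test_that("a scaled-down model runs a forward pass on 32x48x32x2 quickly", {
  model <- buildModel(scaledArchConfig(2L), seed = 3L)
  x <- new("MultiModalVolume", channels = randArray(c(32, 48, 32, 2), seed = 4),
           channelLabels = c("T1", "T2"))
  elapsed <- system.time(out <- predict(model, x))["elapsed"]
  expect_identical(dim(volValues(out$probabilities)), c(32L, 48L, 32L, 4L))
  expect_lt(elapsed, 5)
})

test_that("model save/load restores weights and architecture", {
  model <- buildModel(scaledArchConfig(2L), seed = 21L)
  path <- file.path(withr::local_tempdir(), "model.rds")
  saveModel(model, path)
  back <- loadModel(path)
  expect_identical(back@params, model@params)
  x <- new("MultiModalVolume", channels = randArray(c(16, 16, 16, 2), seed = 2),
           channelLabels = c("T1", "T2"))
  expect_identical(volValues(predict(back, x)$probabilities),
                   volValues(predict(model, x)$probabilities))
})
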