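sf <- asNamespace("strokefate")

smallUnet <- function(inCh = 4L) unetConfig(inCh, depth = 3L, baseFilters = 4L)

test_that("the UNet preserves the in-slice shape and outputs per-voxel probabilities", {
  m <- buildParamUnet(smallUnet(), seed = 1)
  x <- array(rnorm(16 * 24 * 4 * 2), c(16, 24, 4, 2))
  p <- modelPredict(m, x)
  expect_equal(dim(p), c(16L, 24L, 2L))
  expect_true(all(p >= 0 & p <= 1))
  # two-channel softmax: infarct + background probabilities sum to one
  h <- sf$.unetForward(m, x, keepCache = FALSE)$z
  p1 <- exp(h[, , 1, ]) / (exp(h[, , 1, ]) + exp(h[, , 2, ]))
  expect_equal(as.vector(p1 + p), rep(1, length(p)), tolerance = 1e-6)
  expect_error(modelPredict(m, array(0, c(15, 24, 4, 1))), "divisible")
})

test_that("the parameter count matches a hand-derived formula", {
  depth <- 3L; base <- 4L; inCh <- 4L
  m <- buildParamUnet(unetConfig(inCh, depth, base), seed = 2)
  f <- base * 2^(0:(depth - 1))
  convP <- function(cin, cout) 9 * cin * cout + cout
  expected <- 0
  cin <- inCh
  for (d in 1:(depth - 1)) {                 # encoder pairs
    expected <- expected + convP(cin, f[d]) + convP(f[d], f[d]); cin <- f[d]
  }
  expected <- expected + convP(cin, f[depth]) + convP(f[depth], f[depth])
  cin <- f[depth]
  for (d in (depth - 1):1) {                 # decoder pairs after concat
    expected <- expected + convP(cin + f[d], f[d]) + convP(f[d], f[d])
    cin <- f[d]
  }
  expected <- expected + (cin * 2 + 2)       # 1x1 softmax head
  expect_equal(sum(vapply(m$weights, length, numeric(1))), expected)
})

test_that("the simple block collapses 32 timepoints to exactly eight features", {
  m <- buildTemporalModel(temporalBlockConfig("simple"), smallUnet(8L),
                          seed = 3)
  x <- array(rnorm(8 * 8 * 32 * 1), c(8, 8, 32, 1))
  f <- temporalFeatureMaps(m, x)
  expect_equal(dim(f), c(8L, 8L, 8L, 1L))
  tr <- sf$.temporalShapeTrace(temporalBlockConfig("simple"))
  expect_equal(tr, c(32, 30, 28, 14, 12, 10, 5, 3, 1))
})

test_that("an incompatible window is rejected with a shape trace", {
  expect_error(
    buildTemporalModel(temporalBlockConfig("simple", windowLen = 31L),
                       smallUnet(8L)),
    "shape trace")
})

test_that("zero input yields zero temporal features", {
  for (v in c("simple", "causal")) {
    m <- buildTemporalModel(temporalBlockConfig(v), smallUnet(8L), seed = 4)
    f <- temporalFeatureMaps(m, array(0, c(8, 8, 32, 1)))
    expect_equal(max(abs(f)), 0)
  }
})

test_that("the causal block's retained element sees exactly all 32 timepoints", {
  cfg <- temporalBlockConfig("causal")
  expect_equal(receptiveField(cfg), 32L)
  expect_warning(temporalBlockConfig("causal", dilations = c(1L, 2L, 4L)),
                 "receptive field")
})

test_that("causal convolutions never leak future samples", {
  # finite-difference probe on the stacked causal layers: output position t
  # must be insensitive to inputs at t' > t
  m <- buildTemporalModel(temporalBlockConfig("causal"), smallUnet(8L),
                          seed = 5)
  set.seed(11)
  x0 <- array(rnorm(32), c(32, 1, 1))
  runFull <- function(x) {
    h <- x
    for (li in seq_along(m$tlayers)) {
      L <- m$tlayers[[li]]
      if (L$type == "conv1")
        h <- sf$.nnConv1Fw(h, m$weights[[L$w]], m$weights[[L$b]], L$k,
                           L$dil, L$causal)
      else if (L$type == "relu") h <- sf$.nnRelu(h)
      else break
    }
    h  # (32, 8, 1): full final-layer causal outputs
  }
  y0 <- runFull(x0)
  for (t in c(5L, 16L, 31L)) {
    xp <- x0; xp[t + 1L, 1, 1] <- xp[t + 1L, 1, 1] + 1   # perturb input t
    dy <- abs(runFull(xp) - y0)
    expect_equal(max(dy[seq_len(t), , ]), 0)             # past unaffected
    expect_gt(max(dy[(t + 1L):32, , ]), 0)               # present/future respond
  }
  # perturbing the final sample changes the retained features
  xp <- x0; xp[32, 1, 1] <- xp[32, 1, 1] + 1
  expect_gt(max(abs(runFull(xp)[32, , ] - y0[32, , ])), 0)
})

test_that("the strided cone evaluation equals the full dilated computation", {
  m <- buildTemporalModel(temporalBlockConfig("causal"), smallUnet(8L),
                          seed = 6)
  x <- array(rnorm(8 * 8 * 32 * 2), c(8, 8, 32, 2))
  fFast <- sf$.temporalForward(m, x, FALSE, NULL, fast = TRUE)$feat
  fFull <- sf$.temporalForward(m, x, FALSE, NULL, fast = FALSE)$feat
  expect_equal(fFast, fFull, tolerance = 1e-12)
})

test_that("temporal blocks share weights across voxels", {
  m <- buildTemporalModel(temporalBlockConfig("causal"), smallUnet(8L),
                          seed = 7)
  x <- array(rnorm(4 * 4 * 32), c(4, 4, 32, 1))
  f <- temporalFeatureMaps(m, x)
  perm <- sample(4)
  fp <- temporalFeatureMaps(m, x[perm, , , , drop = FALSE])
  expect_equal(fp, f[perm, , , , drop = FALSE], tolerance = 1e-12)
})

test_that("all four deep models share the same UNet trunk shapes", {
  u4 <- unetConfig(4L, depth = 3L, baseFilters = 8L)
  u8 <- unetConfig(8L, depth = 3L, baseFilters = 8L)
  models <- list(
    param = buildParamUnet(u4, seed = 1),
    rc_simple = buildTemporalModel(temporalBlockConfig("simple"), u8, 1),
    rc_causal = buildTemporalModel(temporalBlockConfig("causal"), u8, 1),
    ctc_causal = buildTemporalModel(temporalBlockConfig("causal"), u8, 1))
  shapes <- lapply(models, weightShapes, trunkOnly = TRUE)
  expect_true(all(vapply(shapes, function(s)
    identical(names(s), names(shapes[[1]])), logical(1))))
  for (nm in names(shapes[[1]])) {
    ref <- shapes$rc_simple[[nm]]
    for (mod in names(shapes)) {
      s <- shapes[[mod]][[nm]]
      if (nm == "enc1a.w" && mod == "param") {
        expect_equal(s[2], ref[2])     # only the input channels differ
      } else {
        expect_identical(s, ref)
      }
    }
  }
})

test_that("the soft Dice loss matches its formula and rejects the undefined case", {
  g <- array(c(1, 0, 1, 0, 0, 1), c(3, 2))
  expect_equal(softDiceLoss(g, g, smooth = 0), 0)
  expect_equal(softDiceLoss(g * 0, g, smooth = 0), 1)
  set.seed(12)
  p <- array(runif(60), c(5, 4, 3)); y <- array(rbinom(60, 1, 0.4), c(5, 4, 3))
  want <- 1 - (2 * sum(p * y) + 1) / (sum(p) + sum(y) + 1)
  expect_lt(abs(softDiceLoss(p, y, smooth = 1) - want), 1e-7)
  expect_error(softDiceLoss(y * 0, y * 0, smooth = 0), "undefined")
})

test_that("training overfits a single slice and is seed-reproducible", {
  set.seed(13)
  x <- array(rnorm(16 * 16 * 4), c(16, 16, 4, 1))
  y <- array(0, c(16, 16, 1)); y[3:14, 3:14, 1] <- 1
  x[, , 1, 1] <- x[, , 1, 1] + 10 * y[, , 1]       # learnable signal
  x[, , 2, 1] <- x[, , 2, 1] - 8 * y[, , 1]
  x[, , 3, 1] <- x[, , 3, 1] + 6 * y[, , 1]
  m <- buildParamUnet(smallUnet(), seed = 8)
  cfg <- trainConfig(maxEpochs = 200L, patience = 200L, batchSize = 1L,
                     seed = 21L)
  fit <- trainModel(m, x, y, x, y, cfg)
  p <- modelPredict(fit, x)
  expect_gte(diceCoefficient(p > 0.5, y), 0.9)
  fit2 <- trainModel(m, x, y, x, y, cfg)
  expect_identical(fit$history, fit2$history)
  expect_identical(fit$weights, fit2$weights)
})

test_that("early stopping halts eight epochs after the best and restores it", {
  set.seed(14)
  x <- array(rnorm(16 * 16 * 4 * 2), c(16, 16, 4, 2))
  y <- array(rbinom(16 * 16 * 2, 1, 0.3), c(16, 16, 2))
  m <- buildParamUnet(smallUnet(), seed = 9)
  fit <- trainModel(m, x, y, x * 0 + rnorm(length(x)), y,
                    trainConfig(maxEpochs = 60L, seed = 22L))
  h <- fit$history
  best <- which.min(h$val_loss)
  expect_equal(fit$bestEpoch, h$epoch[best])
  if (nrow(h) < 60) {
    # stopped early: exactly patience epochs without improvement follow
    expect_equal(nrow(h), fit$bestEpoch + 8L)
    expect_true(all(h$val_loss[(best + 1):nrow(h)] >= h$val_loss[best]))
  }
  expect_error(trainModel(m, x, y * 0, x, y), "infarct")
})

test_that("volume prediction restores the original geometry with values in [0, 1]", {
  p <- noiseFreePatient()$patient
  brain <- brainMask(baselineAverage(p$series))
  ms <- hemisphereSplit(brain, "left")
  stack4 <- array(rnorm(prod(dim(brain)) * 4), c(dim(brain), 4))
  prep <- spatialPrepare(stack4, ms, padShape = c(32, 64))
  m <- buildParamUnet(unetConfig(4L, 3L, 4L), seed = 10)
  vol <- predictVolume(m, prep$data, prep$geom)
  expect_equal(dim(vol), dim(brain))
  expect_true(all(vol >= 0 & vol <= 1))
  # un-padding inverts the spatial preparation voxel-for-voxel
  hemi <- hemisphereMask(ms, "left")
  onPad <- predictVolume(m, prep$data, geom = NULL,
                         mask = prep$geom$hemi)
  expect_equal(vol[hemi], onPad[prep$geom$hemi], tolerance = 1e-12)
})
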