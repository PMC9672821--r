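sf <- asNamespace("strokefate")

mkConc <- function(values, dt = 1) {
  new("PerfusionSeries", values = values, spacing = c(3, 3, 5), dt = dt,
      domain = "concentration")
}

test_that("singular values below 15% of the largest are zeroed, others inverted", {
  inv <- sf$.truncateSingular(c(10, 2, 1), 0.15)
  expect_equal(inv, c(1 / 10, 1 / 2, 0))
  expect_equal(sf$.truncateSingular(c(10, 2, 1), 0), c(0.1, 0.5, 1))
})

test_that("self-deconvolution recovers a unit impulse at lag zero", {
  tg <- 0:31
  aif <- genAif(aifModel(t0 = 5, shape = 2, scale = 1), tg)
  v <- array(rep(aif, each = 4), c(2, 2, 1, 32))
  k <- bcsvdDeconvolve(mkConc(v), aif, deconvConfig(truncationFraction = 0))
  curve <- k@values[1, 1, 1, ]
  expect_gte(curve[1], 0.99)
  expect_lt(max(abs(curve[-1])), 1e-6)
  expect_equal(seriesDomain(k), "residual")
})

test_that("deconvolution rejects mismatched or degenerate input", {
  v <- array(1, c(2, 2, 1, 16))
  expect_error(bcsvdDeconvolve(mkConc(v), numeric(16)), "zero")
  expect_error(bcsvdDeconvolve(mkConc(v), rep(1, 8)), "length")
  raw <- new("PerfusionSeries", values = v, spacing = c(1, 1, 1), dt = 1,
             domain = "raw")
  expect_error(bcsvdDeconvolve(raw, rep(1, 16)), "concentration")
})

test_that("a phantom voxel's CBF is recovered within 15% through the full chain", {
  tr <- tinyTruth(cbf = 0.6, mtt = 4, tmax = 4)
  conc <- genTissueCurves(tr, nTime = 48)
  ctc <- temporalResample(conc)
  tg <- (seq_len(dim(ctc@values)[4]) - 1)
  aif <- genAif(tr@aif, tg)
  k <- bcsvdDeconvolve(ctc, aif)
  expect_lt(abs(max(k@values[1, 1, 1, ]) - 0.6) / 0.6, 0.15)
})

test_that("deconvolution is linear and delay-covariant", {
  tr <- tinyTruth(cbf = 0.5, mtt = 5, tmax = 4)
  ctc <- temporalResample(genTissueCurves(tr, 48))
  tg <- (seq_len(dim(ctc@values)[4]) - 1)
  aif <- genAif(tr@aif, tg)
  k1 <- bcsvdDeconvolve(ctc, aif)
  ctc3 <- mkConc(ctc@values * 3)
  k3 <- bcsvdDeconvolve(ctc3, aif)
  expect_equal(k3@values, 3 * k1@values, tolerance = 1e-12)
  # shifting the tissue curve by s samples shifts the residue argmax by s
  s <- 4L
  shifted <- ctc@values
  T <- dim(shifted)[4]
  shifted[1, 1, 1, ] <- c(numeric(s), ctc@values[1, 1, 1, 1:(T - s)])
  ks <- bcsvdDeconvolve(mkConc(shifted), aif)
  expect_equal(which.max(ks@values[1, 1, 1, ]),
               which.max(k1@values[1, 1, 1, ]) + s)
})

test_that("raising the truncation fraction never increases the inverse operator norm", {
  aif <- genAif(aifModel(t0 = 4, shape = 2, scale = 1), 0:23)
  fr <- c(0, 0.05, 0.15, 0.3, 0.6)
  norms <- vapply(fr, function(f) {
    inv <- sf$.bcsvdInverse(aif, 1, deconvConfig(truncationFraction = f))
    sqrt(sum(inv$Dinv^2))
  }, numeric(1))
  expect_true(all(diff(norms) <= 1e-9))
})

test_that("parameter maps implement the standard conventions", {
  # residue with max 2.0 at sample index 5 (0-based), dt = 1 s
  T <- 16
  k <- numeric(T); k[6] <- 2; k[7] <- 1
  res <- new("PerfusionSeries", values = array(rep(k, each = 1), c(1, 1, 1, T)),
             spacing = c(1, 1, 1), dt = 1, domain = "residual")
  aif <- rep(1, T)
  ctc <- mkConc(array(8, c(1, 1, 1, T)))   # sum(ctc)/sum(aif) = 8
  maps <- parameterMaps(res, ctc, aif)
  expect_equal(parameterMap(maps, "cbf")[1, 1, 1], 2)
  expect_equal(parameterMap(maps, "tmax")[1, 1, 1], 5)
  expect_equal(parameterMap(maps, "cbv")[1, 1, 1], 8, tolerance = 1e-12)
  expect_equal(parameterMap(maps, "mtt")[1, 1, 1], 4, tolerance = 1e-12)
  expect_error(parameterMaps(res, ctc, -aif), "positive")
})

test_that("low-flow voxels get zero MTT and a flag", {
  T <- 8
  res <- new("PerfusionSeries", values = array(0, c(2, 1, 1, T)),
             spacing = c(1, 1, 1), dt = 1, domain = "residual")
  ctc <- mkConc(array(1, c(2, 1, 1, T)))
  maps <- parameterMaps(res, ctc, rep(1, T))
  expect_equal(parameterMap(maps, "mtt")[1, 1, 1], 0)
  expect_true(all(attr(maps@mtt, "lowFlow")))
})

test_that("phantom CBV estimates stay within 5% of CBF*MTT (noise off)", {
  nf <- noiseFreePatient()
  p <- nf$patient
  bavg <- baselineAverage(p$series)
  brain <- brainMask(bavg)
  ctc <- temporalResample(baselineSubtract(p$series, bavg))
  tg <- (seq_len(dim(ctc@values)[4]) - 1)
  aif <- genAif(p$truth@aif, tg)
  maps <- parameterMaps(bcsvdDeconvolve(ctc, aif), ctc, aif, mask = brain)
  sel <- (p$truth@cbf > 0) & brain
  relerr <- abs(maps@cbv[sel] - p$truth@cbv[sel]) / p$truth@cbv[sel]
  expect_lt(median(relerr), 0.05)
})

test_that("the convenience AIF pick returns the strongest in-mask curve", {
  v <- array(0, c(2, 2, 1, 10))
  v[1, 1, 1, ] <- c(0, 1, 5, 2, 1, 0, 0, 0, 0, 0)
  v[2, 1, 1, ] <- c(0, 1, 9, 3, 1, 0, 0, 0, 0, 0)
  mask <- array(TRUE, c(2, 2, 1))
  expect_equal(pickAif(mkConc(v), mask), v[2, 1, 1, ])
})
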