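mkRaw <- function(values, dt = 1) {
  new("PerfusionSeries", values = values, spacing = c(3, 3, 5), dt = dt,
      domain = "raw")
}

test_that("arrival is the first frame whose mean exceeds 115% of baseline", {
  T <- 20
  meanCurve <- rep(30, T)
  meanCurve[12:16] <- c(35, 40, 38, 33, 31)   # first crossing of 34.5 at 12
  v <- array(rep(meanCurve, each = 8), c(2, 2, 2, T))
  mask <- array(TRUE, c(2, 2, 2))
  expect_equal(detectArrival(mkRaw(v), mask), 12L)
  # brute-force oracle over the scan rule
  mt <- apply(array(v, c(8, T)), 2, mean)
  expect_equal(detectArrival(mkRaw(v), mask),
               which(mt > 1.15 * mean(mt[1:3]))[1])
})

test_that("a flat series yields the no-arrival signal", {
  v <- array(30, c(2, 2, 1, 10))
  expect_warning(a <- detectArrival(mkRaw(v), array(TRUE, c(2, 2, 1))),
                 "no contrast arrival")
  expect_true(is.na(a))
})

test_that("the arrival factor default is 115%", {
  expect_equal(roiConfig()$arrivalFactor, 1.15)
})

test_that("windows left of the acquisition start are edge-padded with the first-3 mean", {
  T <- 40
  v <- array(0, c(1, 1, 1, T))
  v[1, 1, 1, ] <- seq_len(T)           # distinct values per frame
  v[1, 1, 1, 6] <- 100                  # peak at 0-based index 5
  s <- new("PerfusionSeries", values = v, spacing = c(1, 1, 1), dt = 1,
           domain = "concentration")
  mask <- array(TRUE, c(1, 1, 1))
  out <- temporalRoi(s, mask = mask, arrival = 1L, type = "ctc")
  w <- out@values[1, 1, 1, ]
  expect_length(w, 32)
  # 0-based window [-11, 20]: 11 left-pad samples, then frames 1..21
  headMean <- mean(v[1, 1, 1, 1:3])
  expect_equal(w[1:11], rep(headMean, 11))
  expect_equal(w[12], v[1, 1, 1, 1])
  expect_equal(w[17], 100)              # peak lands at 0-based position 16
})

test_that("a comfortably centred peak gives a pure crop", {
  T <- 64
  v <- array(rnorm(T), c(1, 1, 1, T))
  v[1, 1, 1, 30] <- 50
  s <- new("PerfusionSeries", values = v, spacing = c(1, 1, 1), dt = 1,
           domain = "concentration")
  out <- temporalRoi(s, mask = array(TRUE, c(1, 1, 1)), arrival = 20L,
                     type = "ctc")
  expect_equal(out@values[1, 1, 1, ], v[1, 1, 1, 14:45])
})

test_that("residual curves are cropped to the first 32 timepoints", {
  v <- array(rnorm(48), c(1, 1, 1, 48))
  s <- new("PerfusionSeries", values = v, spacing = c(1, 1, 1), dt = 1,
           domain = "residual")
  out <- temporalRoi(s, type = "residual")
  expect_equal(out@values[1, 1, 1, ], v[1, 1, 1, 1:32])
})

test_that("the window length is 32 regardless of input length and peak position", {
  for (T in c(20, 33, 60)) for (pk in c(2L, T %/% 2L, T - 1L)) {
    v <- array(0, c(1, 1, 1, T)); v[1, 1, 1, pk] <- 10
    s <- new("PerfusionSeries", values = v, spacing = c(1, 1, 1), dt = 1,
             domain = "concentration")
    out <- suppressWarnings(
      temporalRoi(s, mask = array(TRUE, c(1, 1, 1)), arrival = 1L,
                  type = "ctc"))
    expect_equal(dim(out@values)[4], 32L)
  }
})

test_that("hemisphere preparation zeroes, crops, pads and restores", {
  p <- noiseFreePatient()$patient
  brain <- brainMask(baselineAverage(p$series))
  ms <- hemisphereSplit(brain, "left")
  vol <- p$truth@tmax
  prep <- spatialPrepare(vol, ms, padShape = c(32, 64))
  expect_equal(dim(prep$data)[1:2], c(32L, 64L))
  hemi <- hemisphereMask(ms, "left")
  # voxel count inside the mask is preserved by masking + padding
  expect_equal(sum(prep$data > 0), sum(vol > 0 & hemi))
  # restore inverts exactly
  back <- spatialRestore(prep$data, prep$geom)
  expect_equal(back, vol * hemi, tolerance = 1e-12)
  # content larger than the pad shape is rejected with a size report
  expect_error(spatialPrepare(vol, ms, padShape = c(8, 8)), "exceeds")
})

test_that("standardisation fits on training data only and inverts exactly", {
  set.seed(3)
  x <- array(rnorm(6 * 5 * 4, mean = 7, sd = 3), c(6, 5, 4))
  st <- fitStandardizer(x, channelDim = 3)
  z <- applyStandardizer(x, st)
  for (ch in 1:4) {
    expect_lt(abs(mean(z[, , ch])), 1e-6)
    expect_lt(abs(sd(as.vector(z[, , ch])) - 1), 1e-6)
  }
  shifted <- x + 5
  zs <- applyStandardizer(shifted, st)
  expect_gt(abs(mean(zs)), 1)          # no refit on test data
  expect_equal(invertStandardizer(z, st), x, tolerance = 1e-9)
})

test_that("spatiotemporal features share one statistic across all timepoints", {
  set.seed(4)
  x <- array(rnorm(5 * 4 * 10), c(5, 4, 10))  # last axis = time
  st1 <- fitStandardizer(x, channelDim = NULL)
  st2 <- fitStandardizer(x[, , sample(10)], channelDim = NULL)
  expect_identical(st1$mean, st2$mean)
  expect_identical(st1$sd, st2$sd)
})

test_that("constant features are epsilon-guarded with a warning", {
  x <- array(5, c(3, 3, 2))
  expect_warning(st <- fitStandardizer(x, channelDim = 3), "constant")
  expect_equal(st$sd, c(1, 1))
})
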