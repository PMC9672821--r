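test_that("the Tmax candidate grid spans (0, 24] s at 0.2 s intervals", {
  g <- tmaxGrid()
  expect_length(g, 120)
  expect_equal(min(g), 0.2)
  expect_equal(max(g), 24)
  expect_equal(unique(round(diff(g), 10)), 0.2)
})

test_that("Tmax thresholding uses a strict inequality and is monotone", {
  m <- array(c(0, 2, 6, 6.001, 10), c(5, 1, 1))
  expect_equal(sum(tmaxPredict(m, 6)), 2)      # 6 itself is excluded
  expect_equal(sum(tmaxPredict(m, 0)), 4)
  expect_equal(sum(tmaxPredict(m, 99)), 0)
  set.seed(5)
  r <- array(runif(200, 0, 12), c(10, 10, 2))
  lo <- tmaxPredict(r, 4); hi <- tmaxPredict(r, 8)
  expect_true(all(lo[hi]))                      # higher threshold => subset
})

test_that("leave-one-out optimisation matches a brute-force oracle and ignores the held-out row", {
  grid <- c(0.1, 0.2, 0.3, 0.4)
  tab <- rbind(p1 = c(0.2, 0.5, 0.4, 0.1),
               p2 = c(0.3, 0.4, 0.6, 0.2),
               p3 = c(0.1, 0.6, 0.5, 0.3))
  res <- looOptimize(tab, grid)
  for (i in 1:3) {
    means <- colMeans(tab[-i, , drop = FALSE])
    expect_equal(res$index[i], which.max(means))
    expect_equal(res$threshold[i], grid[which.max(means)])
  }
  # perturbing a patient's own row never changes their threshold
  tab2 <- tab; tab2[2, ] <- c(99, -99, 0, 42)
  expect_equal(looOptimize(tab2, grid)$threshold[2], res$threshold[2])
  # identical rows: everyone gets the global argmax (ties -> smallest)
  same <- matrix(rep(c(0.2, 0.5, 0.5, 0.1), each = 3), 3)
  expect_equal(looOptimize(same, grid)$threshold, rep(grid[2], 3))
  expect_error(looOptimize(tab[1, , drop = FALSE], grid), "fewer than 2")
})

test_that("per-patient undersampling balances classes exactly 1:1", {
  set.seed(6)
  n <- 600
  feats <- data.frame(cbf = rnorm(n), cbv = rnorm(n), mtt = rnorm(n),
                      tmax = rnorm(n))
  labels <- c(rep(1, 100), rep(0, 500))
  pats <- rep("p1", n)
  fit <- rdfTrain(feats, labels, pats, rdfConfig(seed = 1))
  expect_equal(fit$nTrain, 200)
  expect_error(rdfTrain(feats, rep(1, n), pats), "classes")
})

test_that("the forest separates a cleanly separable lesion signal", {
  set.seed(7)
  n <- 2000
  lesion <- rbinom(n, 1, 0.3)
  feats <- data.frame(cbf = rnorm(n, 0.6 - 0.4 * lesion, 0.02),
                      cbv = rnorm(n, 2.4, 0.1),
                      mtt = rnorm(n, 4 + 6 * lesion, 0.2),
                      tmax = rnorm(n, 4 + 8 * lesion, 0.2))
  pats <- rep(c("a", "b"), each = n / 2)
  fit <- rdfTrain(feats, lesion, pats, rdfConfig(seed = 2))
  expect_equal(fit$cfg$nTrees, 100L)
  expect_equal(fit$cfg$r, 0.5)
  p <- rdfPredict(fit, feats)
  expect_true(all(p >= 0 & p <= 1))
  roc <- rocCurveAuc(array(p, c(n, 1, 1)), array(lesion, c(n, 1, 1)),
                     array(TRUE, c(n, 1, 1)))
  expect_gt(roc$auc, 0.95)
})

test_that("forest predictions equal the mean of the individual tree outputs", {
  set.seed(8)
  n <- 300
  feats <- data.frame(cbf = rnorm(n), cbv = rnorm(n), mtt = rnorm(n),
                      tmax = rnorm(n))
  labels <- rbinom(n, 1, plogis(feats$tmax))
  fit <- rdfTrain(feats, labels, rep(c("a", "b"), n / 2), rdfConfig(seed = 3))
  p <- rdfPredict(fit, feats)
  all_trees <- predict(fit$forest, data = feats, predict.all = TRUE,
                       num.threads = 1)$predictions
  expect_equal(p, rowMeans(all_trees), tolerance = 1e-12)
  # voxel ordering invariance
  perm <- sample(n)
  expect_equal(rdfPredict(fit, feats[perm, ]), p[perm], tolerance = 1e-12)
  # reproducibility under a fixed seed
  fit2 <- rdfTrain(feats, labels, rep(c("a", "b"), n / 2), rdfConfig(seed = 3))
  expect_identical(rdfPredict(fit2, feats), p)
  expect_error(rdfPredict(fit, feats[, 1:2]), "feature")
})

test_that("noise filtering removes components below ten voxels, strictly", {
  m <- array(FALSE, c(20, 20, 3))
  m[2:4, 2:4, 1] <- TRUE               # 9 voxels -> removed
  m[10:14, 10:11, 2] <- TRUE           # 10 voxels -> kept
  out <- noiseFilter(m)
  expect_false(any(out[, , 1]))
  expect_true(all(out[10:14, 10:11, 2]))
})

test_that("closing welds an in-slice checkerboard into one component", {
  m <- array(FALSE, c(12, 12, 1))
  idx <- expand.grid(i = 3:10, j = 3:10)
  keep <- (idx$i + idx$j) %% 2 == 0
  m[cbind(idx$i[keep], idx$j[keep], 1)] <- TRUE
  out <- noiseFilter(m)
  lab <- strokefate:::.labelComponents3d(out)
  expect_equal(max(lab), 1)
  expect_gte(sum(out), sum(m))
})

test_that("noise filtering is idempotent and fixes the empty mask", {
  empty <- array(FALSE, c(5, 5, 2))
  expect_equal(sum(noiseFilter(empty)), 0)
  set.seed(9)
  m <- array(runif(20 * 20 * 3) < 0.35, c(20, 20, 3))
  once <- noiseFilter(m)
  expect_identical(noiseFilter(once), once)
})
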