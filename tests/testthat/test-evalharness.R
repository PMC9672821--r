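test_that("fold assignment yields the nominal 68/12/20 allocation", {
  cohort <- data.frame(patient_id = sprintf("p%02d", 1:25), arm = "IA")
  plan <- assignFolds(cohort, seed = 1)
  for (k in 1:5) {
    mem <- foldMembers(plan, "IA", k)
    expect_equal(length(mem$train), 17)   # 68%
    expect_equal(length(mem$val), 3)      # 12%
    expect_equal(length(mem$test), 5)     # 20%
  }
})

test_that("folds partition each arm and every patient is tested exactly once", {
  set.seed(2)
  cohort <- data.frame(patient_id = sprintf("q%02d", 1:23),
                       arm = rep(c("IA", "IV"), c(14, 9)))
  plan <- assignFolds(cohort, seed = 5)
  for (arm in c("IA", "IV")) {
    ids <- cohort$patient_id[cohort$arm == arm]
    tested <- unlist(lapply(1:5, function(k) foldMembers(plan, arm, k)$test))
    expect_setequal(tested, ids)
    expect_equal(length(tested), length(ids))      # no repeats
    for (k in 1:5) {
      mem <- foldMembers(plan, arm, k)
      expect_length(intersect(mem$train, mem$val), 0)
      expect_length(intersect(mem$train, mem$test), 0)
      expect_length(intersect(mem$val, mem$test), 0)
      expect_setequal(c(mem$train, mem$val, mem$test), ids)
    }
  }
  # deterministic in (cohort, seed)
  plan2 <- assignFolds(cohort, seed = 5)
  expect_identical(plan$assignment, plan2$assignment)
  expect_identical(plan$val, plan2$val)
  expect_error(assignFolds(data.frame(patient_id = c("a", "b"), arm = "IA")),
               "fewer")
})

test_that("five patients each appear in exactly one test fold", {
  plan <- assignFolds(data.frame(patient_id = letters[1:5], arm = "IA"),
                      seed = 3)
  tested <- sapply(1:5, function(k) foldMembers(plan, "IA", k)$test)
  expect_setequal(tested, letters[1:5])
})

test_that("Dice matches a voxel-counting oracle", {
  a <- array(c(TRUE, TRUE, FALSE, FALSE), c(2, 2, 1))
  expect_equal(diceCoefficient(a, a), 1)
  expect_equal(diceCoefficient(a, !a), 0)
  expect_equal(diceCoefficient(a & FALSE, a & FALSE), 1)  # both empty
  set.seed(4)
  for (i in 1:5) {
    p <- array(runif(60) < 0.4, c(5, 4, 3))
    g <- array(runif(60) < 0.3, c(5, 4, 3))
    want <- 2 * sum(p & g) / (sum(p) + sum(g))
    expect_equal(diceCoefficient(p, g), want)
  }
})

test_that("ROC-AUC behaves at the extremes and matches a rank-statistic oracle", {
  set.seed(5)
  g <- array(rbinom(400, 1, 0.3), c(20, 20, 1))
  mask <- array(TRUE, c(20, 20, 1))
  expect_equal(rocCurveAuc(g * 1, g, mask)$auc, 1)
  expect_equal(rocCurveAuc(g * 0 + 0.5, g, mask)$auc, 0.5)
  p <- array(runif(400), c(20, 20, 1))
  auc <- rocCurveAuc(p, g, mask)$auc
  # Mann-Whitney oracle
  pos <- p[g == 1]; neg <- p[g == 0]
  u <- mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
  expect_lt(abs(auc - u), 0.02)
  # single-class truth is flagged
  expect_true(is.na(rocCurveAuc(p, g * 0, mask)$auc))
})

test_that("volume errors follow the sign convention in ml", {
  sp <- c(0.45, 0.45, 5)
  g <- array(FALSE, c(50, 50, 4))
  p <- g; p[seq_len(1000)] <- TRUE
  ve <- volumeErrors(p, g, sp)
  expect_equal(ve[["volume_error"]], 1000 * prod(sp) / 1000)  # +1.0125 ml
  expect_equal(ve[["volume_error"]], 1.0125)
  expect_equal(ve[["abs_volume_error"]], 1.0125)
  expect_equal(volumeErrors(g, g, sp)[["volume_error"]], 0)
  set.seed(6)
  p2 <- array(runif(200) < 0.5, c(10, 10, 2))
  g2 <- array(runif(200) < 0.5, c(10, 10, 2))
  expect_equal(volumeErrors(p2, g2, sp)[["volume_error"]],
               (sum(p2) - sum(g2)) * prod(sp) / 1000)
})

test_that("optimal binarization uses the inclusive 101-value grid and a LOO search", {
  grid <- seq(0, 1, by = 0.01)
  expect_length(grid, 101)
  set.seed(7)
  probs <- truths <- list()
  for (i in 1:3) {
    g <- array(rbinom(200, 1, 0.3), c(10, 10, 2))
    probs[[i]] <- array(pmin(pmax(g * 0.8 + runif(200, 0, 0.3), 0), 1),
                        c(10, 10, 2))
    truths[[i]] <- g
  }
  names(probs) <- names(truths) <- c("a", "b", "c")
  bo <- binarizeOptimal(probs, truths)
  # brute-force oracle over the same table
  for (i in 1:3) {
    means <- colMeans(bo$table[-i, ])
    expect_equal(bo$thresholds$threshold[i], grid[which.max(means)])
    expect_equal(bo$masks[[i]],
                 probs[[i]] > grid[which.max(means)])
  }
  # identical patients get identical thresholds
  bo2 <- binarizeOptimal(probs[c(1, 1, 1)], truths[c(1, 1, 1)])
  expect_equal(length(unique(bo2$thresholds$threshold)), 1)
})

test_that("feature correlations match the Spearman rank formula", {
  set.seed(8)
  d <- c(6, 5, 2)
  tmax <- array(runif(prod(d), 0, 12), d)
  maps <- new("ParameterMaps", cbf = array(runif(prod(d)), d),
              cbv = array(runif(prod(d)), d), mtt = array(runif(prod(d)), d),
              tmax = tmax, spacing = c(1, 1, 1))
  mask <- array(TRUE, d)
  feats <- array(0, c(d, 3))
  feats[, , , 1] <- exp(tmax / 5)          # monotone transform -> rho 1
  feats[, , , 2] <- -tmax                  # rho -1
  feats[, , , 3] <- array(rnorm(prod(d)), d)
  rho <- correlateFeatures(feats, maps, mask)
  expect_equal(rho["feature1", "tmax"], 1)
  expect_equal(rho["feature2", "tmax"], -1)
  expect_equal(rho["feature3", "cbf"],
               spearmanOracle(feats[, , , 3][mask], maps@cbf[mask]),
               tolerance = 1e-9)
  feats[, , , 3] <- 1
  expect_warning(correlateFeatures(feats, maps, mask), "constant")
})

test_that("a small experiment produces coherent bookkeeping and reproduces bit-for-bit", {
  spec <- cohortSpec(nTotal = 6, nIA = 6, nIV = 0, seed = 31,
                     noiseSigma = 0.5)
  run1 <- runExperiment(spec, models = c("tmax", "rdf"), arms = "IA",
                        padShape = c(32, 64), nFolds = 3L,
                        foldSeed = 17L, rdfSeed = 23L, verbose = FALSE)
  # 2 models x 6 patients x 2 filter variants
  expect_equal(nrow(run1$metrics), 24)
  expect_true(all(run1$metrics$dice >= 0 & run1$metrics$dice <= 1))
  expect_true(all(run1$metrics$abs_volume_error ==
                    abs(run1$metrics$volume_error)))
  # method-average ROC curves are monotone and anchored
  for (mod in c("tmax", "rdf")) {
    rc <- run1$roc[run1$roc$model == mod, ]
    rc <- rc[order(rc$threshold), ]
    expect_true(all(diff(rc$fpr) <= 1e-9))
    expect_true(all(diff(rc$tpr) <= 1e-9))
  }
  run2 <- runExperiment(spec, models = c("tmax", "rdf"), arms = "IA",
                        padShape = c(32, 64), nFolds = 3L,
                        foldSeed = 17L, rdfSeed = 23L, verbose = FALSE)
  expect_identical(run1$metrics, run2$metrics)
  expect_identical(run1$summary, run2$summary)
})
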