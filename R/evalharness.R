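## Patient-level fivefold cross-validation, optimal binarization and all
## reported metrics (Dice, empirical ROC-AUC, volume errors, feature-map
## rank correlations).

#' Assign cross-validation folds
#'
#' Patients are partitioned per treatment arm into `nFolds` near-equal
#' test folds; within each fold the remaining patients form the training
#' portion, from which `valFraction` are sampled as the validation set
#' (nominal allocation 68% train / 12% validation / 20% test for five
#' folds and 15% validation sampling). The plan is a pure function of
#' `(cohort, seed)` and is reused across every prediction method.
#'
#' @param cohort data.frame with `patient_id` and `arm` columns.
#' @param seed fold RNG seed.
#' @param nFolds number of folds (default 5).
#' @param valFraction fraction of each fold's training portion used for
#'   validation.
#' @return an object of class `foldPlan`.
#' @export
assignFolds <- function(cohort, seed = 1L, nFolds = 5L, valFraction = 0.15) {
  stopifnot(all(c("patient_id", "arm") %in% names(cohort)))
  set.seed(seed)
  rows <- list(); val <- list()
  for (arm in unique(cohort$arm)) {
    ids <- cohort$patient_id[cohort$arm == arm]
    if (length(ids) < nFolds)
      stop("arm ", arm, " has fewer patients than folds")
    perm <- sample(ids)
    sizes <- rep(length(ids) %/% nFolds, nFolds) +
      (seq_len(nFolds) <= length(ids) %% nFolds)
    fold <- rep(seq_len(nFolds), times = sizes)
    rows[[arm]] <- data.frame(patient_id = perm, arm = arm, fold = fold,
                              stringsAsFactors = FALSE)
    val[[arm]] <- lapply(seq_len(nFolds), function(k) {
      trainIds <- perm[fold != k]
      nv <- max(1L, round(valFraction * length(trainIds)))
      sample(trainIds, nv)
    })
  }
  structure(list(assignment = do.call(rbind, c(rows, make.row.names = FALSE)),
                 val = val, nFolds = as.integer(nFolds),
                 valFraction = valFraction, seed = seed),
            class = "foldPlan")
}

#' Fold membership
#'
#' @param plan a `foldPlan` from [assignFolds()].
#' @param arm treatment arm.
#' @param fold fold index (1-based).
#' @return list with `train`, `val` and `test` patient-id vectors; the
#'   validation set is a subset of the fold's training portion and is
#'   removed from `train`.
#' @export
foldMembers <- function(plan, arm, fold) {
  a <- plan$assignment[plan$assignment$arm == arm, ]
  test <- a$patient_id[a$fold == fold]
  trainAll <- a$patient_id[a$fold != fold]
  val <- plan$val[[arm]][[fold]]
  list(train = setdiff(trainAll, val), val = val, test = test)
}

#' Dice similarity coefficient
#'
#' `2|P intersect G| / (|P| + |G|)`; two empty masks are defined to agree
#' perfectly (Dice 1).
#'
#' @param pred,truth logical arrays on the same grid.
#' @return scalar in `[0, 1]`.
#' @export
diceCoefficient <- function(pred, truth) {
  p <- sum(pred > 0); g <- sum(truth > 0)
  if (p + g == 0) return(1)
  2 * sum(pred > 0 & truth > 0) / (p + g)
}

#' Per-patient empirical ROC curve and AUC
#'
#' The probability map is binarized about a series of thresholds (default
#' 100 values, 0.00-0.99); the false and true positive rates at each
#' threshold form the patient's empirical curve, anchored at (0,0) and
#' (1,1), and the AUC is its trapezoidal area. Patients whose ground truth
#' contains a single class have no defined AUC and are flagged with `NA`.
#'
#' @param prob probability map.
#' @param truth binary ground truth.
#' @param evalMask logical mask of voxels entering the evaluation
#'   (the ipsilateral hemisphere).
#' @param thresholds binarization thresholds.
#' @return list with `fpr`, `tpr` (per threshold, decreasing in
#'   threshold), and `auc`.
#' @export
rocCurveAuc <- function(prob, truth, evalMask,
                        thresholds = seq(0, 0.99, by = 0.01)) {
  p <- prob[evalMask > 0]; g <- truth[evalMask > 0] > 0
  P <- sum(g); N <- sum(!g)
  if (P == 0 || N == 0)
    return(list(fpr = rep(NA_real_, length(thresholds)),
                tpr = rep(NA_real_, length(thresholds)), auc = NA_real_))
  tpr <- vapply(thresholds, function(th) sum(p > th & g) / P, numeric(1))
  fpr <- vapply(thresholds, function(th) sum(p > th & !g) / N, numeric(1))
  fx <- c(0, rev(fpr), 1); ty <- c(0, rev(tpr), 1)
  ord <- order(fx, ty)
  fx <- fx[ord]; ty <- ty[ord]
  auc <- sum(diff(fx) * (head(ty, -1) + tail(ty, -1)) / 2)
  list(fpr = fpr, tpr = tpr, auc = auc)
}

#' Lesion volume errors
#'
#' Signed volume error `(|P| - |G|) * voxelVolume` in ml (positive means
#' the prediction overestimates the infarct volume) and its absolute
#' value.
#'
#' @param pred,truth binary masks on the same grid.
#' @param spacing voxel spacing in mm.
#' @return named numeric `c(volume_error, abs_volume_error)` in ml.
#' @export
volumeErrors <- function(pred, truth, spacing) {
  voxMl <- prod(spacing) / 1000
  signed <- (sum(pred > 0) - sum(truth > 0)) * voxMl
  c(volume_error = signed, abs_volume_error = abs(signed))
}

#' Leave-one-out optimal binarization of probability maps
#'
#' Binarizes each patient's probability map at every grid threshold,
#' builds the patients-by-thresholds Dice table and delegates to
#' [looOptimize()]; each patient's map is then binarized at their
#' leave-one-out optimal threshold.
#'
#' @param probs named list of probability maps (one per patient).
#' @param truths matching list of binary ground-truth masks.
#' @param grid candidate thresholds (default 0 to 1 inclusive at 0.01,
#'   101 values).
#' @param postFn optional filter applied to every binarized mask before
#'   Dice evaluation (e.g. [noiseFilter()]).
#' @return list with `masks` (per patient), `thresholds` (from
#'   [looOptimize()]) and the Dice `table`.
#' @export
binarizeOptimal <- function(probs, truths, grid = seq(0, 1, by = 0.01),
                            postFn = NULL) {
  stopifnot(length(probs) == length(truths), length(probs) >= 2)
  binAt <- function(pm, th) {
    m <- pm > th
    if (!is.null(postFn)) m <- postFn(m)
    m
  }
  tab <- t(vapply(seq_along(probs), function(i) {
    vapply(grid, function(th)
      diceCoefficient(binAt(probs[[i]], th), truths[[i]]), numeric(1))
  }, numeric(length(grid))))
  rownames(tab) <- names(probs)
  opt <- looOptimize(tab, grid)
  masks <- lapply(seq_along(probs), function(i)
    binAt(probs[[i]], opt$threshold[i]))
  names(masks) <- names(probs)
  list(masks = masks, thresholds = opt, table = tab)
}

#' Rank correlation of learned temporal features with perfusion parameters
#'
#' Spearman's rho between every learned feature channel and every
#' perfusion parameter map over the pooled in-mask voxels.
#'
#' @param features array `(X, Y, Z, F)` of feature maps, or a list of such
#'   arrays (pooled).
#' @param params a [ParameterMaps-class] or list of them (matching the
#'   feature list).
#' @param masks logical mask (or list of masks) selecting the pooled
#'   foreground voxels.
#' @return numeric matrix `F x 4` of Spearman rho values (`NA` where a
#'   channel is constant, with a warning).
#' @export
correlateFeatures <- function(features, params, masks) {
  if (!is.list(features)) { features <- list(features); params <- list(params)
                            masks <- list(masks) }
  pool <- function(get) do.call(rbind, lapply(seq_along(features), get))
  fmat <- pool(function(i) {
    nf <- dim(features[[i]])[4]
    sapply(seq_len(nf), function(f) features[[i]][, , , f][masks[[i]] > 0])
  })
  pmat <- pool(function(i) {
    sapply(c("cbf", "cbv", "mtt", "tmax"), function(w)
      parameterMap(params[[i]], w)[masks[[i]] > 0])
  })
  rho <- matrix(NA_real_, ncol(fmat), 4,
                dimnames = list(paste0("feature", seq_len(ncol(fmat))),
                                c("cbf", "cbv", "mtt", "tmax")))
  for (f in seq_len(ncol(fmat))) {
    if (sd(fmat[, f]) < 1e-12) { warning("constant feature channel ", f); next }
    for (p in 1:4) rho[f, p] <- cor(fmat[, f], pmat[, p], method = "spearman")
  }
  rho
}

## which hemisphere holds the lesion
.lesionSide <- function(lesion, brain) {
  xs <- which(apply(brain, 1, any))
  mid <- (min(xs) + max(xs)) / 2
  xIdx <- slice.index(lesion, 1)
  nLeft <- sum(lesion & xIdx <= floor(mid))
  if (nLeft >= sum(lesion) - nLeft) "left" else "right"
}

#' Prepare one synthetic patient for modelling
#'
#' Runs the full processing chain on a generated patient: preprocessing
#' (baseline correction, 1 s resampling, brain and hemisphere masks),
#' bcSVD deconvolution with the known phantom AIF, parameter mapping,
#' temporal ROI extraction and hemisphere preparation of every model
#' input.
#'
#' @param spec a [CohortSpec-class].
#' @param index patient index.
#' @param padShape in-slice pad shape for [spatialPrepare()].
#' @param roiCfg,deconvCfg stage configurations.
#' @return list of prepared tensors and geometry (see source for fields).
#' @export
preparePatient <- function(spec, index, padShape = c(96, 64),
                           roiCfg = roiConfig(), deconvCfg = deconvConfig()) {
  p <- genPatient(spec, index)
  bavg <- baselineAverage(p$series)
  brain <- brainMask(bavg)
  side <- .lesionSide(p$truth@lesion, brain)
  masks <- hemisphereSplit(brain, side)
  ctc <- temporalResample(baselineSubtract(p$series, bavg))
  tGrid <- (seq_len(dim(ctc@values)[4]) - 1) * ctc@dt
  aif <- genAif(p$truth@aif, tGrid)
  residual <- bcsvdDeconvolve(ctc, aif, deconvCfg)
  maps <- parameterMaps(residual, ctc, aif, mask = brain)
  arrival <- suppressWarnings(detectArrival(p$series, brain, roiCfg))
  ctc32 <- temporalRoi(ctc, roiCfg, mask = brain, arrival = arrival,
                       type = "ctc")
  rc32 <- temporalRoi(residual, roiCfg, type = "residual")

  stack4 <- array(c(maps@cbf, maps@cbv, maps@mtt, maps@tmax),
                  c(dim(maps@cbf), 4L))
  prep <- spatialPrepare(stack4, masks, padShape = padShape)
  prepCtc <- spatialPrepare(ctc32@values, masks, padShape = padShape)
  prepRc <- spatialPrepare(rc32@values, masks, padShape = padShape)
  truthPrep <- spatialPrepare(p$followup * 1, masks, padShape = padShape)
  list(patient_id = p$patient_id, arm = p$arm,
       params4 = prep$data, ctc32 = prepCtc$data, rc32 = prepRc$data,
       tmaxPrep = prep$data[, , , 4L],
       truthPrep = truthPrep$data > 0, hemi = prep$geom$hemi,
       geom = prep$geom, spacing = spec@gridSpacing, maps = maps,
       masks = masks, followup = p$followup)
}

## pooled (mean, sd) standardizer over a list of prepared arrays
.poolStandardizer <- function(arrays, channelDim = NULL) {
  if (is.null(channelDim)) {
    n <- 0; s1 <- 0; s2 <- 0
    for (a in arrays) { n <- n + length(a); s1 <- s1 + sum(a); s2 <- s2 + sum(a^2) }
    mu <- s1 / n
    sg <- sqrt(max((s2 - n * mu^2) / (n - 1), 0))
    if (sg < 1e-12) sg <- 1
    return(structure(list(mean = mu, sd = sg, channelDim = NULL),
                     class = "standardizerState"))
  }
  nc <- dim(arrays[[1]])[channelDim]
  n <- 0; s1 <- numeric(nc); s2 <- numeric(nc)
  for (a in arrays) {
    m <- matrix(a, ncol = nc)
    n <- n + nrow(m); s1 <- s1 + colSums(m); s2 <- s2 + colSums(m^2)
  }
  mu <- s1 / n
  sg <- sqrt(pmax((s2 - n * mu^2) / (n - 1), 0))
  sg[sg < 1e-12] <- 1
  structure(list(mean = mu, sd = sg, channelDim = channelDim),
            class = "standardizerState")
}

## stack per-patient prepared tensors (H,W,Z,C) into slice batches
.stackSlices <- function(prepList, field, standardizer = NULL) {
  xs <- list(); ys <- list(); ms <- list()
  for (p in prepList) {
    x <- p[[field]]
    if (!is.null(standardizer)) x <- applyStandardizer(x, standardizer)
    xs[[length(xs) + 1L]] <- aperm(x, c(1, 2, 4, 3))   # (H,W,C,Z)
    ys[[length(ys) + 1L]] <- p$truthPrep * 1
    ms[[length(ms) + 1L]] <- p$hemi
  }
  H <- dim(xs[[1]])[1]; W <- dim(xs[[1]])[2]; C <- dim(xs[[1]])[3]
  ns <- vapply(xs, function(a) dim(a)[4], numeric(1))
  x <- array(0, c(H, W, C, sum(ns)))
  y <- array(0, c(H, W, sum(ns)))
  m <- array(FALSE, c(H, W, sum(ns)))
  at <- 0L
  for (i in seq_along(xs)) {
    x[, , , at + seq_len(ns[i])] <- xs[[i]]
    y[, , at + seq_len(ns[i])] <- ys[[i]]
    m[, , at + seq_len(ns[i])] <- ms[[i]]
    at <- at + ns[i]
  }
  list(x = x, y = y, m = m)
}

.deriveSeed <- function(base, arm, model, fold) {
  (base + 977L * fold + 131L * match(model, c(
    "tmax", "rdf", "param_unet", "rc_simple", "rc_causal", "ctc_causal")) +
     17L * (arm == "IV")) %% 2147483629L
}

## probability maps per patient for one model on one arm
.armProbabilities <- function(model, arm, prepList, plan, cfg) {
  ids <- vapply(prepList, `[[`, character(1), "patient_id")
  probs <- vector("list", length(prepList)); names(probs) <- ids
  if (model == "tmax") {
    for (i in seq_along(prepList))
      probs[[i]] <- prepList[[i]]$tmaxPrep
    return(probs)
  }
  for (k in seq_len(plan$nFolds)) {
    mem <- foldMembers(plan, arm, k)
    trIx <- which(ids %in% mem$train); vaIx <- which(ids %in% mem$val)
    teIx <- which(ids %in% mem$test)
    if (!length(teIx)) next
    if (model == "rdf") {
      trAll <- c(trIx, vaIx)  # the forest uses the full training portion
      feat <- do.call(rbind, lapply(trAll, function(i) {
        hemi <- prepList[[i]]$hemi
        data.frame(cbf = prepList[[i]]$params4[, , , 1][hemi],
                   cbv = prepList[[i]]$params4[, , , 2][hemi],
                   mtt = prepList[[i]]$params4[, , , 3][hemi],
                   tmax = prepList[[i]]$params4[, , , 4][hemi])
      }))
      labs <- unlist(lapply(trAll, function(i)
        prepList[[i]]$truthPrep[prepList[[i]]$hemi]))
      pats <- unlist(lapply(trAll, function(i)
        rep(ids[i], sum(prepList[[i]]$hemi))))
      fit <- rdfTrain(feat, labs, pats,
                      rdfConfig(seed = .deriveSeed(cfg$rdfSeed, arm, model, k)))
      for (i in teIx) {
        hemi <- prepList[[i]]$hemi
        fts <- data.frame(cbf = prepList[[i]]$params4[, , , 1][hemi],
                          cbv = prepList[[i]]$params4[, , , 2][hemi],
                          mtt = prepList[[i]]$params4[, , , 3][hemi],
                          tmax = prepList[[i]]$params4[, , , 4][hemi])
        pm <- array(0, dim(hemi))
        pm[hemi] <- rdfPredict(fit, fts)
        probs[[i]] <- pm
      }
    } else {
      field <- switch(model, param_unet = "params4", rc_simple = "rc32",
                      rc_causal = "rc32", ctc_causal = "ctc32")
      chDim <- if (model == "param_unet") 4L else NULL
      st <- .poolStandardizer(lapply(trIx, function(i) prepList[[i]][[field]]),
                              channelDim = chDim)
      tr <- .stackSlices(prepList[trIx], field, st)
      va <- .stackSlices(prepList[vaIx], field, st)
      seed <- .deriveSeed(cfg$trainCfg$seed, arm, model, k)
      net <- if (model == "param_unet")
        buildParamUnet(unetConfig(4L, cfg$unetDepth, cfg$baseFilters,
                                  cfg$l2Factor), seed = seed)
      else
        buildTemporalModel(
          temporalBlockConfig(if (model == "rc_simple") "simple" else "causal"),
          unetConfig(8L, cfg$unetDepth, cfg$baseFilters, cfg$l2Factor),
          seed = seed)
      tcfg <- cfg$trainCfg; tcfg$seed <- seed
      net <- trainModel(net, tr$x, tr$y, va$x, va$y, tcfg,
                        mTrain = tr$m, mVal = va$m)
      for (i in teIx) {
        x <- applyStandardizer(prepList[[i]][[field]], st)
        pm <- predictVolume(net, x, geom = NULL, mask = prepList[[i]]$hemi)
        pm[!prepList[[i]]$hemi] <- 0
        probs[[i]] <- pm
      }
    }
  }
  probs
}

#' Run a full tissue-outcome-prediction experiment
#'
#' Generates (or regenerates) each synthetic patient, runs the processing
#' chain, assigns patient-level folds once, trains and evaluates every
#' requested model per treatment arm on identical folds, performs
#' leave-one-out optimal binarization, and collects per-patient metrics
#' with and without morphological noise filtering.
#'
#' @param spec a [CohortSpec-class].
#' @param models subset of `c("tmax", "rdf", "param_unet", "rc_simple",
#'   "rc_causal", "ctc_causal")`.
#' @param arms treatment arms to evaluate.
#' @param padShape in-slice pad shape.
#' @param nFolds folds per arm.
#' @param unetDepth,baseFilters,l2Factor UNet trunk setting.
#' @param trainCfg a [trainConfig()].
#' @param foldSeed,rdfSeed named seeds (every randomness source is an
#'   explicit seed).
#' @param filterVariants which noise-filtering variants to evaluate
#'   (`FALSE` = raw masks, `TRUE` = morphologically filtered).
#' @param outDir optional directory for metrics/summary/ROC CSV exports.
#' @param verbose progress messages.
#' @return list with `metrics` (per patient x model x filter variant),
#'   `summary` (mean/sd), `roc` (method-average curves), `plan`, and the
#'   per-model probability maps.
#' @export
runExperiment <- function(spec,
                          models = c("tmax", "rdf", "param_unet",
                                     "rc_simple", "rc_causal", "ctc_causal"),
                          arms = c("IA", "IV"), padShape = c(96, 64),
                          nFolds = 5L, unetDepth = 4L, baseFilters = 64L,
                          l2Factor = 0.5e-4, trainCfg = trainConfig(),
                          foldSeed = 2024L, rdfSeed = 37L,
                          filterVariants = c(FALSE, TRUE), outDir = NULL,
                          verbose = TRUE) {
  tab <- cohortTable(spec)
  tab <- tab[tab$arm %in% arms, , drop = FALSE]
  plan <- assignFolds(tab, seed = foldSeed, nFolds = nFolds)
  cfg <- list(unetDepth = unetDepth, baseFilters = baseFilters,
              l2Factor = l2Factor, trainCfg = trainCfg, rdfSeed = rdfSeed)
  metrics <- list(); rocRows <- list(); probsAll <- list()
  for (arm in arms) {
    idx <- which(cohortTable(spec)$arm == arm &
                   cohortTable(spec)$patient_id %in% tab$patient_id)
    if (verbose) message("preparing ", length(idx), " ", arm, " patients")
    prepList <- lapply(idx, function(i)
      preparePatient(spec, i, padShape = padShape))
    ids <- vapply(prepList, `[[`, character(1), "patient_id")
    truths <- lapply(prepList, function(p) p$truthPrep)
    names(truths) <- ids
    for (model in models) {
      if (verbose) message("  model ", model, " (", arm, ")")
      probs <- .armProbabilities(model, arm, prepList, plan, cfg)
      probsAll[[paste(arm, model, sep = ".")]] <- probs
      grid <- if (model == "tmax") tmaxGrid() else seq(0, 1, by = 0.01)
      for (filtered in filterVariants) {
        post <- if (filtered) noiseFilter else NULL
        bo <- binarizeOptimal(probs, truths, grid = grid, postFn = post)
        for (i in seq_along(ids)) {
          rocMax <- if (model == "tmax") 24 else 1
          roc <- rocCurveAuc(pmin(probs[[i]] / rocMax, 1), truths[[i]],
                             prepList[[i]]$hemi)
          ve <- volumeErrors(bo$masks[[i]], truths[[i]], spec@gridSpacing)
          metrics[[length(metrics) + 1L]] <- data.frame(
            patient = ids[i], arm = arm, model = model, filtered = filtered,
            dice = diceCoefficient(bo$masks[[i]], truths[[i]]),
            roc_auc = roc$auc, volume_error = ve[["volume_error"]],
            abs_volume_error = ve[["abs_volume_error"]],
            threshold = bo$thresholds$threshold[i],
            stringsAsFactors = FALSE)
          if (!filtered)
            rocRows[[length(rocRows) + 1L]] <- data.frame(
              arm = arm, model = model, patient = ids[i],
              threshold = seq(0, 0.99, by = 0.01), fpr = roc$fpr,
              tpr = roc$tpr, stringsAsFactors = FALSE)
        }
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  roc <- do.call(rbind, rocRows)
  rocAvg <- stats::aggregate(cbind(fpr, tpr) ~ arm + model + threshold,
                             data = roc, FUN = mean, na.action = stats::na.omit)
  agg <- stats::aggregate(
    cbind(dice, roc_auc, volume_error, abs_volume_error) ~
      arm + model + filtered,
    data = metrics, FUN = function(v) c(mean = mean(v, na.rm = TRUE),
                                        sd = sd(v)))
  summary <- do.call(data.frame, agg)
  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    write.csv(metrics, file.path(outDir, "metrics.csv"), row.names = FALSE)
    write.csv(summary, file.path(outDir, "summary.csv"), row.names = FALSE)
    write.csv(rocAvg, file.path(outDir, "roc_curves.csv"), row.names = FALSE)
  }
  list(metrics = metrics, summary = summary, roc = rocAvg, plan = plan,
       probabilities = probsAll)
}
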