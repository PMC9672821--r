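## Training: soft Dice loss, Adam, early stopping with best-weight restore.

#' Training configuration
#'
#' Adam hyperparameters follow the reference setting
#' (alpha 0.0005, beta1 0.975, beta2 0.999, epsilon 0.08); training stops
#' after the validation loss fails to improve for `patience` consecutive
#' epochs and the best-epoch weights are restored.
#'
#' @param alpha,beta1,beta2,epsilon Adam parameters.
#' @param patience early-stopping patience in epochs (>= 1).
#' @param batchSize slices per optimisation step.
#' @param maxEpochs hard epoch cap.
#' @param seed RNG seed for shuffling.
#' @param diceSmooth smoothing constant of the training soft Dice loss.
#' @export
trainConfig <- function(alpha = 5e-4, beta1 = 0.975, beta2 = 0.999,
                        epsilon = 0.08, patience = 8L, batchSize = 8L,
                        maxEpochs = 500L, seed = 1L, diceSmooth = 1) {
  stopifnot(patience >= 1)
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon, patience = as.integer(patience),
                 batchSize = as.integer(batchSize),
                 maxEpochs = as.integer(maxEpochs), seed = as.integer(seed),
                 diceSmooth = diceSmooth),
            class = "trainConfig")
}

#' Soft Dice loss
#'
#' `L = 1 - (2 * sum(p*g) + s) / (sum(p) + sum(g) + s)`. With `smooth = 0`
#' and an empty ground truth the loss is not mathematically defined and an
#' error is raised (such slices are omitted from training).
#'
#' @param pred probabilities in `[0, 1]`.
#' @param truth binary array of the same shape.
#' @param smooth smoothing constant `s`.
#' @return scalar loss.
#' @export
softDiceLoss <- function(pred, truth, smooth = 0) {
  stopifnot(identical(dim(pred), dim(truth)) || length(pred) == length(truth))
  if (any(pred < -1e-9) || any(pred > 1 + 1e-9))
    stop("predictions must lie in [0, 1]")
  sg <- sum(truth)
  if (smooth == 0 && sg == 0 && sum(pred) == 0)
    stop("soft Dice loss is undefined for empty truth and empty prediction with smooth = 0")
  1 - (2 * sum(pred * truth) + smooth) / (sum(pred) + sg + smooth)
}

## per-slice soft Dice loss and gradient wrt the infarct probability;
## p, g are (H, W, N)
.diceLossGrad <- function(p, g, smooth) {
  d <- dim(p)
  n <- d[3]
  pm <- matrix(p, ncol = n); gm <- matrix(g, ncol = n)
  P <- colSums(pm); G <- colSums(gm); I <- colSums(pm * gm)
  den <- P + G + smooth
  loss <- 1 - (2 * I + smooth) / den
  # dL/dp = -(2 g den - (2 I + smooth)) / den^2, per slice
  dl <- -(2 * gm * rep(den, each = nrow(gm)) -
            rep(2 * I + smooth, each = nrow(gm))) / rep(den^2, each = nrow(gm))
  list(loss = mean(loss), grad = array(dl / n, d))
}

## gradient through the two-class softmax given dL/dp2 only
.softmaxBackward <- function(z, dp2) {
  d <- dim(z)
  z1 <- array(z[, , 1L, , drop = FALSE], d[c(1, 2, 4)])
  z2 <- array(z[, , 2L, , drop = FALSE], d[c(1, 2, 4)])
  m <- pmax(z1, z2)
  e1 <- exp(z1 - m); e2 <- exp(z2 - m)
  p2 <- e2 / (e1 + e2)
  dz <- array(0, d)
  dz[, , 2L, ] <- dp2 * p2 * (1 - p2)
  dz[, , 1L, ] <- -dp2 * p2 * (1 - p2)
  dz
}

## one forward+backward pass over a batch; returns loss and weight grads
.modelStep <- function(model, x, y, smooth, mask = NULL) {
  tfwd <- NULL
  h <- x
  if (!is.null(model$tlayers)) {
    tfwd <- .temporalForward(model, x, keepCache = TRUE, mask = mask)
    h <- tfwd$feat
  }
  ufwd <- .unetForward(model, h, keepCache = TRUE)
  p2 <- .softmaxProbArr(ufwd$z)
  lg <- .diceLossGrad(p2, y, smooth)
  dz <- .softmaxBackward(ufwd$z, lg$grad)
  ub <- .unetBackward(model, ufwd$caches, dz)
  grads <- ub$grads
  if (!is.null(tfwd)) {
    tg <- .temporalBackward(model, tfwd$caches, tfwd$info, ub$dx)
    grads <- c(grads, tg)
  }
  list(loss = lg$loss, grads = grads)
}

## infarct-channel probability with batch dimension kept
.softmaxProbArr <- function(z) {
  d <- dim(z)
  z1 <- array(z[, , 1L, , drop = FALSE], d[c(1, 2, 4)])
  z2 <- array(z[, , 2L, , drop = FALSE], d[c(1, 2, 4)])
  m <- pmax(z1, z2)
  e2 <- exp(z2 - m)
  e2 / (exp(z1 - m) + e2)
}

## validation loss: mean per-slice soft Dice loss over non-empty slices
.valLoss <- function(model, x, y, smooth, mask = NULL, batchSize = 16L) {
  n <- dim(x)[4]
  tot <- 0; cnt <- 0
  for (s in split(seq_len(n), ceiling(seq_len(n) / batchSize))) {
    p <- modelPredict(model, x[, , , s, drop = FALSE],
                      mask = if (!is.null(mask)) mask[, , s, drop = FALSE])
    lg <- .diceLossGrad(p, y[, , s, drop = FALSE], smooth)
    tot <- tot + lg$loss * length(s); cnt <- cnt + length(s)
  }
  tot / cnt
}

#' Train a model with Adam, soft Dice loss and early stopping
#'
#' Image slices with no infarct voxels in their ground truth are omitted
#' from the training set (and from the validation loss), since the Dice
#' loss is not defined for them. Training stops once the validation loss
#' has not improved for `patience` consecutive epochs, or at `maxEpochs`;
#' the weights of the best validation epoch are restored. With a fixed
#' seed the run (loss history and final weights) is reproducible.
#'
#' @param model a model object.
#' @param xTrain,yTrain training slices `(H, W, C, N)` and binary truths
#'   `(H, W, N)`.
#' @param xVal,yVal validation slices in the same layout.
#' @param cfg a [trainConfig()].
#' @param mTrain,mVal optional `(H, W, N)` hemisphere masks enabling the
#'   shared-background shortcut of the temporal block.
#' @param maxRestarts soft Dice training occasionally collapses into
#'   softmax saturation (an all-background predictor with vanishing
#'   gradients). If the validation loss still exceeds `restartValLoss`
#'   after `restartEpoch` epochs — far above anything a learning run
#'   shows — the attempt is abandoned and training restarts from a fresh
#'   deterministic initialisation, at most this many times.
#' @param restartEpoch,restartValLoss collapse-detection rule.
#' @param verbose print per-epoch losses.
#' @return the model with trained weights plus `history` (data.frame) and
#'   `bestEpoch` elements.
#' @export
trainModel <- function(model, xTrain, yTrain, xVal, yVal,
                       cfg = trainConfig(), mTrain = NULL, mVal = NULL,
                       maxRestarts = 2L, restartEpoch = 10L,
                       restartValLoss = 0.9, verbose = FALSE) {
  keepTr <- which(apply(yTrain, 3, sum) > 0)
  if (!length(keepTr)) stop("no training slice contains infarct voxels")
  keepVa <- which(apply(yVal, 3, sum) > 0)
  if (!length(keepVa)) keepVa <- seq_len(dim(yVal)[3])
  xTrain <- xTrain[, , , keepTr, drop = FALSE]
  yTrain <- yTrain[, , keepTr, drop = FALSE]
  xVal <- xVal[, , , keepVa, drop = FALSE]
  yVal <- yVal[, , keepVa, drop = FALSE]
  if (!is.null(mTrain)) mTrain <- mTrain[, , keepTr, drop = FALSE]
  if (!is.null(mVal)) mVal <- mVal[, , keepVa, drop = FALSE]

  for (attempt in 0:maxRestarts) {
    abortable <- attempt < maxRestarts
    fit <- .trainOnce(model, xTrain, yTrain, xVal, yVal, cfg, mTrain, mVal,
                      abortEpoch = if (abortable) restartEpoch else NA,
                      abortVal = restartValLoss, verbose = verbose)
    if (!isTRUE(fit$aborted)) return(fit)
    if (verbose)
      message("training collapsed (val loss ", round(fit$lastVal, 3),
              " at epoch ", restartEpoch, "); restarting")
    shapes <- lapply(model$weights,
                     function(w) if (is.matrix(w)) dim(w) else length(w))
    model$weights <- .initWeights(shapes,
                                  (cfg$seed + 99991L * (attempt + 1L)) %%
                                    2147483629L)
  }
}

.trainOnce <- function(model, xTrain, yTrain, xVal, yVal, cfg, mTrain, mVal,
                       abortEpoch = NA, abortVal = 0.9, verbose = FALSE) {
  W <- model$weights
  mAd <- lapply(W, function(w) w * 0)
  vAd <- mAd
  step <- 0L
  l2 <- model$ucfg$l2Factor
  kernels <- grepl("\\.w$", names(W))
  set.seed(cfg$seed)
  n <- dim(xTrain)[4]
  hist <- data.frame(epoch = integer(), train_loss = numeric(),
                     val_loss = numeric())
  best <- Inf; bestW <- W; bestEpoch <- 0L; wait <- 0L
  for (epoch in seq_len(cfg$maxEpochs)) {
    perm <- sample.int(n)
    eLoss <- 0
    for (batch in split(perm, ceiling(seq_along(perm) / cfg$batchSize))) {
      model$weights <- W
      st <- .modelStep(model, xTrain[, , , batch, drop = FALSE],
                       yTrain[, , batch, drop = FALSE], cfg$diceSmooth,
                       mask = if (!is.null(mTrain))
                         mTrain[, , batch, drop = FALSE])
      eLoss <- eLoss + st$loss * length(batch)
      step <- step + 1L
      for (nm in names(st$grads)) {
        g <- st$grads[[nm]]
        if (kernels[match(nm, names(W))]) g <- g + 2 * l2 * W[[nm]]
        mAd[[nm]] <- cfg$beta1 * mAd[[nm]] + (1 - cfg$beta1) * g
        vAd[[nm]] <- cfg$beta2 * vAd[[nm]] + (1 - cfg$beta2) * g^2
        mh <- mAd[[nm]] / (1 - cfg$beta1^step)
        vh <- vAd[[nm]] / (1 - cfg$beta2^step)
        W[[nm]] <- W[[nm]] - cfg$alpha * mh / (sqrt(vh) + cfg$epsilon)
      }
    }
    model$weights <- W
    vl <- .valLoss(model, xVal, yVal, cfg$diceSmooth, mask = mVal)
    hist <- rbind(hist, data.frame(epoch = epoch, train_loss = eLoss / n,
                                   val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, eLoss / n, vl))
    if (!is.na(abortEpoch) && epoch == abortEpoch && vl > abortVal)
      return(list(aborted = TRUE, lastVal = vl))
    if (vl < best - 1e-9) {
      best <- vl; bestW <- W; bestEpoch <- epoch; wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= cfg$patience) break
    }
  }
  model$weights <- bestW
  model$history <- hist
  model$bestEpoch <- bestEpoch
  model
}

#' Predict a full 3D probability map for a prepared patient
#'
#' Runs slice-wise inference over the prepared hemisphere tensor and
#' re-assembles the probabilistic tissue outcome map in the original
#' volume geometry (zero outside the hemisphere).
#'
#' @param model a trained model.
#' @param prepared array `(H, W, Z, C)` from [spatialPrepare()].
#' @param geom geometry from [spatialPrepare()]; when `NULL` the map stays
#'   on the prepared grid.
#' @param mask optional `(H, W, Z)` hemisphere mask (defaults to the
#'   geometry's padded hemisphere mask).
#' @return 3D probability array.
#' @export
predictVolume <- function(model, prepared, geom = NULL, mask = NULL) {
  x <- aperm(prepared, c(1, 2, 4, 3))
  if (is.null(mask) && !is.null(geom)) mask <- geom$hemi
  p <- modelPredict(model, x, mask = mask)
  if (is.null(geom)) p else spatialRestore(p, geom)
}
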