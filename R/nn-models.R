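## Modular deep models: a 2D UNet over perfusion parameter maps, and
## swappable 1D temporal processing blocks (plain convolutional or dilated
## causal) that reduce each voxel's 32-sample curve to eight learned
## temporal features feeding the same UNet trunk.
##
## The layers, backpropagation and optimiser are implemented in the
## package (R drivers over RcppArmadillo kernels); weights live in a flat
## named list so the optimiser and serialisation stay trivial.

#' UNet configuration
#'
#' @param inChannels input channels: 4 for perfusion parameter maps, 8 for
#'   learned temporal features.
#' @param depth number of resolution levels (the input must be divisible
#'   by `2^(depth-1)` in both in-slice dimensions).
#' @param baseFilters filters at the finest level; doubled at each level.
#' @param l2Factor weak L2 kernel regulariser factor (0.5e-4).
#' @export
unetConfig <- function(inChannels = 4L, depth = 4L, baseFilters = 64L,
                       l2Factor = 0.5e-4) {
  stopifnot(l2Factor >= 0, depth >= 2)
  structure(list(inChannels = as.integer(inChannels),
                 depth = as.integer(depth),
                 baseFilters = as.integer(baseFilters),
                 l2Factor = l2Factor),
            class = "unetConfig")
}

#' Temporal processing block configuration
#'
#' Two architectures reduce a 32-sample curve to eight features:
#' `"simple"` uses three pairs of un-padded 1D convolutions (kernel 3,
#' ReLU) with 32, 16 and 8 filters and factor-2 max pooling between pairs,
#' collapsing the temporal axis 32-30-28-14-12-10-5-3-1. `"causal"` uses
#' five dilated causal convolutions (8 filters, kernel 2, ReLU, dilations
#' 1, 2, 4, 8, 16); only the last output element — the one whose receptive
#' field spans all 32 input samples — is retained.
#'
#' @param variant `"simple"` or `"causal"`.
#' @param windowLen input window length (32).
#' @param filters simple-variant filter counts per convolution pair.
#' @param nFilters causal-variant filter count.
#' @param dilations causal dilation schedule.
#' @export
temporalBlockConfig <- function(variant = c("simple", "causal"),
                                windowLen = 32L,
                                filters = c(32L, 16L, 8L),
                                nFilters = 8L,
                                dilations = c(1L, 2L, 4L, 8L, 16L)) {
  variant <- match.arg(variant)
  cfg <- structure(list(variant = variant, windowLen = as.integer(windowLen),
                        filters = as.integer(filters),
                        nFilters = as.integer(nFilters),
                        kernel = if (variant == "simple") 3L else 2L,
                        dilations = as.integer(dilations)),
                   class = "temporalBlockConfig")
  if (variant == "causal") {
    rf <- 1L + sum(cfg$dilations) * (cfg$kernel - 1L)
    if (rf != cfg$windowLen)
      warning(sprintf(
        "receptive field of the retained element (%d) differs from the window length (%d)",
        rf, cfg$windowLen))
  }
  cfg
}

#' Receptive field of the causal block's retained element
#'
#' @param cfg a causal [temporalBlockConfig()].
#' @return integer receptive field in samples.
#' @export
receptiveField <- function(cfg) {
  stopifnot(cfg$variant == "causal")
  1L + sum(cfg$dilations) * (cfg$kernel - 1L)
}

## He-normal initialised convolution weight matrix; rows follow the im2col
## patch order (channel fastest)
.heConv <- function(fanK, cin, cout)
  matrix(rnorm(fanK * cin * cout, sd = sqrt(2 / (fanK * cin))),
         fanK * cin, cout)

## UNet layer plan; returns list(layers, shapes) where shapes maps weight
## names to c(rows, cols) of the kernel matrices
.unetPlan <- function(cfg) {
  layers <- list(); shapes <- list()
  convPair <- function(tag, cin, cout) {
    for (ab in c("a", "b")) {
      nm <- paste0(tag, ab)
      shapes[[paste0(nm, ".w")]] <<- c(9L * cin, cout)
      shapes[[paste0(nm, ".b")]] <<- cout
      layers[[length(layers) + 1L]] <<- list(type = "conv", k = 3L, pad = 1L,
                                             w = paste0(nm, ".w"),
                                             b = paste0(nm, ".b"))
      layers[[length(layers) + 1L]] <<- list(type = "relu")
      cin <- cout
    }
  }
  f <- cfg$baseFilters * 2L^(seq_len(cfg$depth) - 1L)
  cin <- cfg$inChannels
  for (d in seq_len(cfg$depth - 1L)) {
    convPair(paste0("enc", d), cin, f[d]); cin <- f[d]
    layers[[length(layers) + 1L]] <- list(type = "save", id = d)
    layers[[length(layers) + 1L]] <- list(type = "pool")
  }
  convPair("bot", cin, f[cfg$depth]); cin <- f[cfg$depth]
  for (d in rev(seq_len(cfg$depth - 1L))) {
    layers[[length(layers) + 1L]] <- list(type = "up")
    layers[[length(layers) + 1L]] <- list(type = "concat", id = d)
    convPair(paste0("dec", d), cin + f[d], f[d]); cin <- f[d]
  }
  shapes[["head.w"]] <- c(cin, 2L); shapes[["head.b"]] <- 2L
  layers[[length(layers) + 1L]] <- list(type = "conv", k = 1L, pad = 0L,
                                        w = "head.w", b = "head.b")
  list(layers = layers, shapes = shapes)
}

## temporal block layer plan (1D); input is a single-channel curve
.temporalPlan <- function(cfg) {
  layers <- list(); shapes <- list()
  addConv <- function(nm, cin, cout, k, dil, causal) {
    shapes[[paste0(nm, ".w")]] <<- c(k * cin, cout)
    shapes[[paste0(nm, ".b")]] <<- cout
    layers[[length(layers) + 1L]] <<- list(type = "conv1", k = k, dil = dil,
                                           causal = causal,
                                           w = paste0(nm, ".w"),
                                           b = paste0(nm, ".b"))
    layers[[length(layers) + 1L]] <<- list(type = "relu")
  }
  if (cfg$variant == "simple") {
    cin <- 1L
    for (p in seq_along(cfg$filters)) {
      addConv(sprintf("t.p%da", p), cin, cfg$filters[p], cfg$kernel, 1L, FALSE)
      addConv(sprintf("t.p%db", p), cfg$filters[p], cfg$filters[p],
              cfg$kernel, 1L, FALSE)
      cin <- cfg$filters[p]
      if (p < length(cfg$filters))
        layers[[length(layers) + 1L]] <- list(type = "pool1")
    }
  } else {
    cin <- 1L
    for (li in seq_along(cfg$dilations)) {
      addConv(sprintf("t.c%d", li), cin, cfg$nFilters, cfg$kernel,
              cfg$dilations[li], TRUE)
      cin <- cfg$nFilters
    }
  }
  layers[[length(layers) + 1L]] <- list(type = "last")
  list(layers = layers, shapes = shapes, outFeatures = cin)
}

## simulate the temporal shape collapse; errors with the trace when the
## window is incompatible with the un-padded stack
.temporalShapeTrace <- function(cfg) {
  t <- cfg$windowLen; trace <- t
  if (cfg$variant == "simple") {
    for (p in seq_along(cfg$filters)) {
      for (i in 1:2) { t <- t - (cfg$kernel - 1L); trace <- c(trace, t) }
      if (p < length(cfg$filters)) { t <- t %/% 2L; trace <- c(trace, t) }
    }
  } else {
    for (d in cfg$dilations) trace <- c(trace, t)  # causal keeps length
  }
  if (min(trace) < 1L)
    stop("window length ", cfg$windowLen,
         " is incompatible with the un-padded temporal stack (shape trace: ",
         paste(trace, collapse = " -> "), ")")
  trace
}

.initWeights <- function(shapes, seed) {
  set.seed(seed)
  W <- list()
  for (nm in names(shapes)) {
    s <- shapes[[nm]]
    W[[nm]] <- if (length(s) == 2L) {
      matrix(rnorm(s[1] * s[2], sd = sqrt(2 / s[1])), s[1], s[2])
    } else numeric(s)
  }
  # terminal bias initialised to a background prior: softmax(1.5, -1.5)
  # gives p(infarct) ~ 0.047, sparing the first epochs from unlearning a
  # uniform foreground prediction under heavy class imbalance
  if (!is.null(W[["head.b"]])) W[["head.b"]] <- c(1.5, -1.5)
  W
}

## dependency-cone execution plan for the causal block: because only the
## last output element is retained, the dilated causal stack is exactly
## equivalent to kernel-2 stride-2 valid convolutions halving the window
## 32 -> 16 -> 8 -> 4 -> 2 -> 1 (same weights, identical retained
## features, ~5x less work)
.temporalFastPlan <- function(cfg) {
  layers <- list()
  for (li in seq_along(cfg$dilations)) {
    layers[[length(layers) + 1L]] <- list(type = "conv1", k = cfg$kernel,
                                          dil = 1L, causal = FALSE,
                                          stride = cfg$kernel,
                                          w = sprintf("t.c%d.w", li),
                                          b = sprintf("t.c%d.b", li))
    layers[[length(layers) + 1L]] <- list(type = "relu")
  }
  layers[[length(layers) + 1L]] <- list(type = "last")
  layers
}

#' Build the Param-UNet model
#'
#' A 2D UNet over the four perfusion parameter maps with zero-padded
#' convolutions (so the output resolution equals the input) and a terminal
#' 1 x 1 convolution with per-voxel two-class softmax.
#'
#' @param cfg a [unetConfig()] (use `inChannels = 4`).
#' @param seed weight initialisation seed.
#' @return a model object (list) for [trainModel()] / [modelPredict()].
#' @export
buildParamUnet <- function(cfg = unetConfig(inChannels = 4L), seed = 1L) {
  plan <- .unetPlan(cfg)
  structure(list(kind = "param_unet", ucfg = cfg, tcfg = NULL,
                 layers = plan$layers, tlayers = NULL,
                 weights = .initWeights(plan$shapes, seed)),
            class = "sfModel")
}

#' Build a temporal-feature model (RC-Simple, RC-Causal, CTC-Causal)
#'
#' The temporal block processes every voxel's 32-sample curve with a
#' single shared set of weights, producing eight temporal feature maps
#' that replace the perfusion parameter maps as the UNet input. Block and
#' UNet train jointly. Whether the curves are deconvolved residual curves
#' or raw concentration-time curves is decided by the data fed to the
#' model.
#'
#' @param tcfg a [temporalBlockConfig()].
#' @param ucfg a [unetConfig()]; `inChannels` must equal the block's
#'   output feature count (8).
#' @param seed weight initialisation seed.
#' @return a model object.
#' @export
buildTemporalModel <- function(tcfg = temporalBlockConfig("causal"),
                               ucfg = unetConfig(inChannels = 8L),
                               seed = 1L) {
  .temporalShapeTrace(tcfg)
  tp <- .temporalPlan(tcfg)
  if (ucfg$inChannels != tp$outFeatures)
    stop("UNet inChannels must match the temporal block output (",
         tp$outFeatures, ")")
  up <- .unetPlan(ucfg)
  fast <- NULL
  if (tcfg$variant == "causal" &&
      tcfg$windowLen == tcfg$kernel^length(tcfg$dilations) &&
      identical(tcfg$dilations, as.integer(tcfg$kernel^(seq_along(tcfg$dilations) - 1))))
    fast <- .temporalFastPlan(tcfg)
  structure(list(kind = paste0("temporal_", tcfg$variant), ucfg = ucfg,
                 tcfg = tcfg, layers = up$layers, tlayers = tp$layers,
                 tlayersFast = fast,
                 weights = .initWeights(c(tp$shapes, up$shapes), seed)),
            class = "sfModel")
}

#' @export
print.sfModel <- function(x, ...) {
  np <- sum(vapply(x$weights, length, numeric(1)))
  cat(sprintf("<%s> depth %d, base %d filters, %s parameters\n", x$kind,
              x$ucfg$depth, x$ucfg$baseFilters, format(np, big.mark = ",")))
  invisible(x)
}

#' Weight shapes of a model
#'
#' Named list mapping every weight tensor to its dimensions; UNet-trunk
#' names are shared across all model variants, which makes the modularity
#' of the architecture directly checkable.
#'
#' @param model a model object.
#' @param trunkOnly drop the temporal-block weights (prefix `t.`).
#' @export
weightShapes <- function(model, trunkOnly = FALSE) {
  W <- model$weights
  if (trunkOnly) W <- W[!startsWith(names(W), "t.")]
  lapply(W, function(w) if (is.matrix(w)) dim(w) else length(w))
}

## ---- forward / backward ----------------------------------------------

.relu <- function(x) .nnRelu(x)

.upsample2 <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
    drop = FALSE]
}

.upsample2Bw <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], by = 2L); i2 <- seq(2L, d[1], by = 2L)
  j1 <- seq(1L, d[2], by = 2L); j2 <- seq(2L, d[2], by = 2L)
  dy[i1, j1, , , drop = FALSE] + dy[i2, j1, , , drop = FALSE] +
    dy[i1, j2, , , drop = FALSE] + dy[i2, j2, , , drop = FALSE]
}

## UNet trunk forward; x is (H, W, C, N)
.unetForward <- function(model, x, keepCache = TRUE) {
  W <- model$weights
  d <- dim(x)
  div <- 2L^(model$ucfg$depth - 1L)
  if (d[1] %% div != 0L || d[2] %% div != 0L)
    stop(sprintf("in-slice shape %d x %d is not divisible by 2^(depth-1) = %d",
                 d[1], d[2], div))
  skips <- list(); caches <- vector("list", length(model$layers))
  h <- x
  for (li in seq_along(model$layers)) {
    L <- model$layers[[li]]
    if (L$type == "conv") {
      if (keepCache) caches[[li]] <- h
      h <- .nnConv2Fw(h, W[[L$w]], W[[L$b]], L$k, L$pad)
    } else if (L$type == "relu") {
      h <- .relu(h)
      if (keepCache) caches[[li]] <- h
    } else if (L$type == "pool") {
      r <- .nnPool2Fw(h)
      if (keepCache) caches[[li]] <- list(idx = r$idx, dimIn = dim(h))
      h <- r$y
    } else if (L$type == "up") {
      h <- .upsample2(h)
    } else if (L$type == "save") {
      skips[[L$id]] <- h
    } else if (L$type == "concat") {
      s <- skips[[L$id]]
      dh <- dim(h)
      out <- array(0, c(dh[1], dh[2], dh[3] + dim(s)[3], dh[4]))
      out[, , seq_len(dh[3]), ] <- h
      out[, , dh[3] + seq_len(dim(s)[3]), ] <- s
      if (keepCache) caches[[li]] <- dh[3]
      h <- out
    }
  }
  list(z = h, caches = caches)
}

## backward through the UNet trunk; returns grads (named list) and dx
.unetBackward <- function(model, caches, dz) {
  W <- model$weights
  grads <- list()
  skipGrads <- list()
  dy <- dz
  for (li in rev(seq_along(model$layers))) {
    L <- model$layers[[li]]
    if (L$type == "conv") {
      r <- .nnConv2Bw(caches[[li]], W[[L$w]], dy, L$k, L$pad)
      grads[[L$w]] <- r$dw + (grads[[L$w]] %||% 0)
      grads[[L$b]] <- r$db + (grads[[L$b]] %||% 0)
      dy <- r$dx
    } else if (L$type == "relu") {
      dy <- .nnReluBw(dy, caches[[li]])
    } else if (L$type == "pool") {
      dy <- .nnPool2Bw(dy, caches[[li]]$idx, caches[[li]]$dimIn)
    } else if (L$type == "up") {
      dy <- .upsample2Bw(dy)
    } else if (L$type == "save") {
      sg <- skipGrads[[as.character(L$id)]]
      if (!is.null(sg)) dy <- dy + sg
    } else if (L$type == "concat") {
      nUp <- caches[[li]]
      tot <- dim(dy)[3]
      skipGrads[[as.character(L$id)]] <- dy[, , (nUp + 1L):tot, , drop = FALSE]
      dy <- dy[, , seq_len(nUp), , drop = FALSE]
    }
  }
  list(grads = grads, dx = dy)
}

## temporal block forward: x (H, W, T, N) -> features (H, W, F, N).
## When a pixel mask is given, curves are processed only for in-mask
## pixels; out-of-mask pixels all carry the same constant background curve
## (zeroed, then standardised), so their shared feature vector is computed
## once and broadcast. This is exact, not an approximation.
.temporalForward <- function(model, x, keepCache = TRUE, mask = NULL,
                             fast = TRUE) {
  W <- model$weights
  d <- dim(x)
  tlayers <- if (fast && !is.null(model$tlayersFast) &&
                 d[3] == model$tcfg$windowLen) model$tlayersFast
             else model$tlayers
  xm <- matrix(aperm(x, c(3, 1, 2, 4)), nrow = d[3])  # T x (H*W*N)
  vIdx <- NULL; hasBg <- FALSE
  if (!is.null(mask)) {
    mv <- as.vector(mask) > 0
    vIdx <- which(mv)
    hasBg <- length(vIdx) < ncol(xm)
    sel <- if (hasBg) c(vIdx, which(!mv)[1]) else vIdx
    xm <- xm[, sel, drop = FALSE]
  }
  h <- array(xm, c(d[3], 1L, ncol(xm)))
  caches <- vector("list", length(tlayers))
  for (li in seq_along(tlayers)) {
    L <- tlayers[[li]]
    if (L$type == "conv1") {
      if (keepCache) caches[[li]] <- h
      h <- .nnConv1Fw(h, W[[L$w]], W[[L$b]], L$k, L$dil, L$causal,
                      L$stride %||% 1L)
    } else if (L$type == "relu") {
      h <- .relu(h)
      if (keepCache) caches[[li]] <- h
    } else if (L$type == "pool1") {
      r <- .nnPool1Fw(h)
      if (keepCache) caches[[li]] <- list(idx = r$idx, dimIn = dim(h))
      h <- r$y
    } else if (L$type == "last") {
      if (keepCache) caches[[li]] <- dim(h)
      dh <- dim(h)
      h <- h[dh[1], , , drop = FALSE]     # (1, F, V)
    }
  }
  f <- dim(h)[2]
  fm <- matrix(h, f, dim(h)[3])
  if (is.null(vIdx)) {
    FM <- fm
  } else {
    FM <- matrix(0, f, d[1] * d[2] * d[4])
    if (hasBg) {
      FM[] <- fm[, ncol(fm)]
      FM[, vIdx] <- fm[, seq_along(vIdx), drop = FALSE]
    } else FM[, vIdx] <- fm
  }
  feat <- aperm(array(FM, c(f, d[1], d[2], d[4])), c(2, 3, 1, 4))
  list(feat = feat, caches = caches,
       info = list(inDim = d, vIdx = vIdx, hasBg = hasBg,
                   tlayers = tlayers))
}

.temporalBackward <- function(model, caches, info, dFeat) {
  W <- model$weights
  f <- dim(dFeat)[3]
  DM <- matrix(aperm(dFeat, c(3, 1, 2, 4)), nrow = f)
  if (!is.null(info$vIdx)) {
    dIn <- DM[, info$vIdx, drop = FALSE]
    if (info$hasBg) {
      # all background pixels share one input curve: their weight-gradient
      # contribution is the backward pass with their dy summed
      DM <- cbind(dIn, rowSums(DM) - rowSums(dIn))
    } else DM <- dIn
  }
  dy <- array(0, c(1L, f, ncol(DM)))
  dy[1L, , ] <- DM
  grads <- list()
  tlayers <- info$tlayers
  for (li in rev(seq_along(tlayers))) {
    L <- tlayers[[li]]
    if (L$type == "conv1") {
      r <- .nnConv1Bw(caches[[li]], W[[L$w]], dy, L$k, L$dil, L$causal,
                      L$stride %||% 1L)
      grads[[L$w]] <- r$dw + (grads[[L$w]] %||% 0)
      grads[[L$b]] <- r$db + (grads[[L$b]] %||% 0)
      dy <- r$dx
    } else if (L$type == "relu") {
      dy <- .nnReluBw(dy, caches[[li]])
    } else if (L$type == "pool1") {
      dy <- .nnPool1Bw(dy, caches[[li]]$idx, caches[[li]]$dimIn)
    } else if (L$type == "last") {
      dInDim <- caches[[li]]
      full <- array(0, dInDim)
      full[dInDim[1], , ] <- dy
      dy <- full
    }
  }
  grads
}

#' Forward pass: per-voxel infarct probabilities
#'
#' @param model a model from [buildParamUnet()] or [buildTemporalModel()].
#' @param x input batch `(H, W, C, N)` — C feature channels for the
#'   Param-UNet, C = 32 timepoints for temporal models.
#' @param mask optional `(H, W, N)` pixel mask; out-of-mask pixels carry a
#'   shared constant (background) curve whose temporal features are
#'   computed once.
#' @return probability array `(H, W, N)` in `[0, 1]`.
#' @export
modelPredict <- function(model, x, mask = NULL) {
  h <- x
  if (!is.null(model$tlayers))
    h <- .temporalForward(model, x, keepCache = FALSE, mask = mask)$feat
  z <- .unetForward(model, h, keepCache = FALSE)$z
  .softmaxProbArr(z)
}

#' Learned temporal feature maps of a voxel batch
#'
#' Runs only the temporal block, returning the eight feature maps that the
#' UNet consumes (for feature-correlation analysis).
#'
#' @param model a temporal model.
#' @param x input batch `(H, W, T, N)`.
#' @return feature array `(H, W, 8, N)`.
#' @export
temporalFeatureMaps <- function(model, x) {
  stopifnot(!is.null(model$tlayers))
  .temporalForward(model, x, keepCache = FALSE)$feat
}
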