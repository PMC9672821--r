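## Model-ready tensor preparation: contrast-arrival detection, 32-timepoint
## temporal region of interest, hemisphere masking with in-slice padding,
## and z-score standardisation with frozen training statistics.

#' Temporal ROI configuration
#'
#' @param windowLen temporal window length in samples (32).
#' @param arrivalFactor contrast arrival is the first timepoint whose mean
#'   in-mask enhancement exceeds this multiple of the baseline enhancement
#'   (1.15, i.e. 115%).
#' @param searchHorizonS peak search horizon after arrival, seconds (40).
#' @param edgePadSamples number of leading/trailing samples averaged for
#'   edge padding (3).
#' @export
roiConfig <- function(windowLen = 32L, arrivalFactor = 1.15,
                      searchHorizonS = 40, edgePadSamples = 3L) {
  stopifnot(windowLen > 0, arrivalFactor > 1)
  structure(list(windowLen = as.integer(windowLen),
                 arrivalFactor = arrivalFactor,
                 searchHorizonS = searchHorizonS,
                 edgePadSamples = as.integer(edgePadSamples)),
            class = "roiConfig")
}

#' Detect contrast arrival
#'
#' The arrival index is the first timepoint at which the mean attenuation
#' of all voxels inside the brain mask exceeds `arrivalFactor` times the
#' mean in-mask attenuation of the baseline average image. Detection runs
#' on the raw (pre-subtraction) series, where baseline enhancement is
#' meaningful.
#'
#' @param series raw-domain [PerfusionSeries-class].
#' @param mask logical 3D brain mask (nonempty).
#' @param cfg a [roiConfig()].
#' @return integer timepoint index (1-based), or `NA_integer_` with a
#'   warning when no timepoint qualifies.
#' @export
detectArrival <- function(series, mask, cfg = roiConfig()) {
  stopifnot(is(series, "PerfusionSeries"))
  if (series@domain != "raw")
    stop("arrival detection requires the raw-domain series")
  if (!any(mask)) stop("empty brain mask")
  d <- dim(series@values)
  keep <- as.vector(mask > 0)
  v <- matrix(series@values, ncol = d[4])[keep, , drop = FALSE]
  meanT <- colMeans(v)
  base <- mean((meanT[1] + meanT[2] + meanT[3]) / 3)
  hit <- which(meanT > cfg$arrivalFactor * base)
  if (!length(hit)) {
    warning("no contrast arrival detected; callers fall back to the global peak")
    return(NA_integer_)
  }
  hit[1]
}

## per-voxel edge padding values: means of the first / last few samples
.edgeMeans <- function(v, nEdge, side = c("head", "tail")) {
  side <- match.arg(side)
  n <- min(nEdge, ncol(v))
  idx <- if (side == "head") seq_len(n) else ncol(v) - n + seq_len(n)
  rowMeans(v[, idx, drop = FALSE])
}

#' Extract the temporal region of interest
#'
#' For concentration-time curves the window is centred on the timepoint
#' with the maximum mean in-mask intensity within `searchHorizonS` seconds
#' after contrast arrival; the peak sits at 0-based window position
#' `windowLen/2` (window `[p-16, p+15]` for 32 samples). Residual curves
#' carry no global bolus delay and are simply cropped to the first
#' `windowLen` timepoints. Samples beyond either end of the acquisition
#' are filled with the per-voxel mean of the first or last
#' `edgePadSamples` existing timepoints.
#'
#' @param series a [PerfusionSeries-class] (concentration or residual).
#' @param cfg a [roiConfig()].
#' @param mask brain mask used for the mean-intensity peak search (ctc
#'   mode).
#' @param arrival arrival index from [detectArrival()]; `NA` falls back to
#'   the global mean-intensity peak.
#' @param type `"ctc"` (centred window) or `"residual"` (leading crop).
#' @return a [PerfusionSeries-class] with exactly `windowLen` timepoints.
#' @export
temporalRoi <- function(series, cfg = roiConfig(), mask = NULL,
                        arrival = NULL, type = c("ctc", "residual")) {
  type <- match.arg(type)
  d <- dim(series@values)
  T <- d[4]
  W <- cfg$windowLen
  v <- matrix(series@values, ncol = T)
  if (type == "residual") {
    idx <- seq_len(W)
    pad <- idx > T
    out <- matrix(0, nrow(v), W)
    out[, !pad] <- v[, idx[!pad]]
    if (any(pad)) out[, pad] <- .edgeMeans(v, cfg$edgePadSamples, "tail")
  } else {
    if (is.null(mask)) stop("ctc windowing needs a brain mask")
    keep <- as.vector(mask > 0)
    meanT <- colMeans(v[keep, , drop = FALSE])
    if (is.null(arrival) || is.na(arrival)) {
      peak <- which.max(meanT)
    } else {
      if (arrival > T) stop("arrival index beyond the acquisition")
      horizon <- min(T, arrival + floor(cfg$searchHorizonS / series@dt))
      rng <- arrival:horizon
      peak <- rng[which.max(meanT[rng])]
    }
    p0 <- peak - 1L                     # 0-based peak index
    want0 <- (p0 - W %/% 2L) + 0:(W - 1L)   # 0-based window
    idx <- want0 + 1L
    out <- matrix(0, nrow(v), W)
    inRange <- idx >= 1L & idx <= T
    out[, inRange] <- v[, idx[inRange]]
    if (any(idx < 1L)) out[, idx < 1L] <- .edgeMeans(v, cfg$edgePadSamples, "head")
    if (any(idx > T)) out[, idx > T] <- .edgeMeans(v, cfg$edgePadSamples, "tail")
  }
  new("PerfusionSeries", values = array(out, c(d[1:3], W)),
      spacing = series@spacing, dt = series@dt, domain = series@domain)
}

#' Hemisphere masking, cropping and in-slice padding
#'
#' Zeroes all voxels outside the requested hemisphere mask, crops to the
#' in-slice bounding box of that mask, and pads symmetrically to the
#' configured in-slice shape (ties give the leading edge the extra voxel).
#' The clinical default pad shape is 480 x 320 at 0.45 mm; the phantom
#' default is 96 x 64. All slices (z) are kept.
#'
#' @param x 3D array, or 4D array whose 4th dimension indexes feature
#'   channels/timepoints.
#' @param maskSet a [MaskSet-class].
#' @param side hemisphere selector, default ipsilateral.
#' @param padShape in-slice output shape `c(nx, ny)`.
#' @return list with `data` (padded array) and `geom` (geometry needed by
#'   [spatialRestore()]), including the matching padded hemisphere mask.
#' @export
spatialPrepare <- function(x, maskSet, side = "ipsilateral",
                           padShape = c(96, 64)) {
  hemi <- hemisphereMask(maskSet, side)
  d3 <- dim(hemi)
  xs <- range(which(apply(hemi, 1, any)))
  ys <- range(which(apply(hemi, 2, any)))
  nx <- xs[2] - xs[1] + 1L; ny <- ys[2] - ys[1] + 1L
  if (nx > padShape[1] || ny > padShape[2])
    stop(sprintf("masked content (%d x %d) exceeds the pad shape (%d x %d)",
                 nx, ny, padShape[1], padShape[2]))
  before <- c(ceiling((padShape[1] - nx) / 2), ceiling((padShape[2] - ny) / 2))
  is4d <- length(dim(x)) == 4L
  nc <- if (is4d) dim(x)[4] else 1L
  xm <- x * as.vector(hemi)
  out <- array(0, c(padShape, d3[3], nc))
  src <- if (is4d) xm else array(xm, c(d3, 1L))
  out[before[1] + seq_len(nx), before[2] + seq_len(ny), , ] <-
    src[xs[1]:xs[2], ys[1]:ys[2], , , drop = FALSE]
  hemiPad <- array(FALSE, c(padShape, d3[3]))
  hemiPad[before[1] + seq_len(nx), before[2] + seq_len(ny), ] <-
    hemi[xs[1]:xs[2], ys[1]:ys[2], ]
  geom <- list(dim = d3, xs = xs, ys = ys, before = before,
               padShape = padShape, hemi = hemiPad)
  list(data = if (is4d) out else array(out, c(padShape, d3[3])), geom = geom)
}

#' Invert [spatialPrepare()] for a prediction volume
#'
#' @param pred 3D array on the padded hemisphere grid.
#' @param geom geometry list from [spatialPrepare()].
#' @return 3D array on the original full grid, zero outside the
#'   hemisphere.
#' @export
spatialRestore <- function(pred, geom) {
  out <- array(0, geom$dim)
  nx <- geom$xs[2] - geom$xs[1] + 1L; ny <- geom$ys[2] - geom$ys[1] + 1L
  out[geom$xs[1]:geom$xs[2], geom$ys[1]:geom$ys[2], ] <-
    pred[geom$before[1] + seq_len(nx), geom$before[2] + seq_len(ny), ,
         drop = FALSE]
  out
}

#' Fit a z-score standardiser on training data
#'
#' One (mean, sd) pair per feature channel, computed across the entire
#' training stack. For spatiotemporal features all timepoints of a channel
#' share one pair, so pass the time axis as part of the pooled dimensions
#' (`channelDim = NULL` treats the whole array as a single feature).
#'
#' @param x numeric array.
#' @param channelDim dimension indexing feature channels, or `NULL` for a
#'   single shared feature.
#' @return an object of class `standardizerState`.
#' @export
fitStandardizer <- function(x, channelDim = NULL) {
  if (is.null(channelDim)) {
    mu <- mean(x); sg <- sd(as.vector(x))
  } else {
    m <- apply(x, channelDim, function(v) c(mean(v), sd(v)))
    mu <- m[1, ]; sg <- m[2, ]
  }
  bad <- !is.finite(sg) | sg < 1e-12
  if (any(bad)) {
    warning("constant feature(s); unit scale used")
    sg[bad] <- 1
  }
  structure(list(mean = mu, sd = sg, channelDim = channelDim),
            class = "standardizerState")
}

#' Apply (or invert) a fitted standardiser
#'
#' @param x numeric array shaped like the training data.
#' @param state a `standardizerState` from [fitStandardizer()].
#' @return standardised array of the same shape.
#' @export
applyStandardizer <- function(x, state) {
  if (is.null(state$channelDim)) return((x - state$mean) / state$sd)
  d <- dim(x)
  cd <- state$channelDim
  sw <- function(v, i) sweep(v, cd, i, FUN = "-")
  out <- sweep(sweep(x, cd, state$mean, "-"), cd, state$sd, "/")
  out
}

#' @rdname applyStandardizer
#' @export
invertStandardizer <- function(x, state) {
  if (is.null(state$channelDim)) return(x * state$sd + state$mean)
  sweep(sweep(x, state$channelDim, state$sd, "*"), state$channelDim,
        state$mean, "+")
}
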