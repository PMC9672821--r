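## Raw-series preprocessing: baseline correction, temporal resampling to
## 1 s with B-spline smoothing, brain masking and hemisphere splitting.

#' Motion correction stage (pass-through hook)
#'
#' Rigid motion correction is a standard registration step that the rest of
#' the pipeline is agnostic to; synthetic phantom data is motion-free. This
#' stage exists so a registration backend can be plugged in for clinical
#' data: when `hook` is supplied it receives and must return the series.
#'
#' @param series a [PerfusionSeries-class].
#' @param hook optional `function(series) -> series`.
#' @export
motionCorrect <- function(series, hook = NULL) {
  stopifnot(is(series, "PerfusionSeries"))
  if (is.null(hook)) series else hook(series)
}

#' Baseline average image
#'
#' Temporal mean intensity projection of the first three timepoints of a
#' raw series.
#'
#' @param series a raw-domain [PerfusionSeries-class] with at least three
#'   timepoints.
#' @return 3D numeric array (HU).
#' @export
baselineAverage <- function(series) {
  stopifnot(is(series, "PerfusionSeries"))
  if (dim(series@values)[4] < 3L)
    stop("baseline average requires at least 3 timepoints")
  (series@values[, , , 1L] + series@values[, , , 2L] +
     series@values[, , , 3L]) / 3
}

#' Baseline signal correction
#'
#' Subtracts the baseline average image from every timepoint, moving the
#' series into the concentration domain.
#'
#' @param series a raw-domain [PerfusionSeries-class].
#' @param baseline 3D array from [baselineAverage()]; computed if missing.
#' @return concentration-domain [PerfusionSeries-class].
#' @export
baselineSubtract <- function(series, baseline = baselineAverage(series)) {
  d <- dim(series@values)
  if (!identical(dim(baseline), d[1:3]))
    stop("baseline shape does not match the series grid")
  new("PerfusionSeries", values = series@values - as.vector(baseline),
      spacing = series@spacing, dt = series@dt, domain = "concentration")
}

## least-squares cubic B-spline resampling operator mapping values sampled
## at tIn onto tOut; knots every knotSpacing input intervals
resampleOperator <- function(tIn, tOut, knotSpacing = 1.5, smooth = TRUE) {
  if (!smooth) {
    # plain linear interpolation matrix
    M <- matrix(0, length(tOut), length(tIn))
    for (i in seq_along(tOut)) {
      j <- findInterval(tOut[i], tIn, rightmost.closed = TRUE)
      j <- min(max(j, 1L), length(tIn) - 1L)
      f <- (tOut[i] - tIn[j]) / (tIn[j + 1] - tIn[j])
      M[i, j] <- 1 - f; M[i, j + 1] <- f
    }
    return(M)
  }
  dtIn <- tIn[2] - tIn[1]
  kn <- seq(tIn[1], tIn[length(tIn)], by = knotSpacing * dtIn)
  kn <- kn[-c(1, length(kn))]
  Bin <- splines::bs(tIn, knots = kn, degree = 3, intercept = TRUE,
                     Boundary.knots = range(tIn))
  Bout <- splines::bs(tOut, knots = kn, degree = 3, intercept = TRUE,
                      Boundary.knots = range(tIn))
  Bout %*% qr.solve(qr(Bin), diag(length(tIn)))
}

#' Temporal resampling with B-spline approximation
#'
#' Interpolates the series to a target temporal resolution (1 s by default)
#' while smoothing each voxel curve with a least-squares cubic B-spline
#' whose knots are placed every `knotSpacing` input frame intervals. The
#' acquisition duration is preserved to within one output sample. When the
#' series is already at the target resolution and smoothing is disabled the
#' input is returned unchanged.
#'
#' @param series a [PerfusionSeries-class] with at least 4 timepoints.
#' @param targetDt output temporal spacing in seconds.
#' @param knotSpacing B-spline knot spacing in input frame intervals.
#' @param smooth apply the smoothing spline (`TRUE`) or plain linear
#'   interpolation (`FALSE`).
#' @return resampled [PerfusionSeries-class] (same domain).
#' @export
temporalResample <- function(series, targetDt = 1, knotSpacing = 1.5,
                             smooth = TRUE) {
  d <- dim(series@values)
  if (d[4] < 4L) stop("temporal resampling requires at least 4 timepoints")
  if (!smooth && isTRUE(all.equal(series@dt, targetDt))) return(series)
  tIn <- (seq_len(d[4]) - 1) * series@dt
  tOut <- seq(0, tIn[length(tIn)], by = targetDt)
  M <- resampleOperator(tIn, tOut, knotSpacing, smooth)
  v <- matrix(series@values, ncol = d[4])      # voxels x T
  out <- tcrossprod(v, M)                      # voxels x Tout
  new("PerfusionSeries", values = array(out, c(d[1:3], length(tOut))),
      spacing = series@spacing, dt = targetDt, domain = series@domain)
}

## in-slice (per-frame) box morphology; EBImage applies a 2D brush to each
## slice of a 3D array, which matches the 5 x 5 x 1 / 3 x 3 x 1 kernels.
## Slices are zero-padded first: everything outside the grid is background
## (EBImage's own border convention would treat it as foreground during
## erosion).
.slabMorph <- function(mask, k, op = c("erode", "dilate", "close")) {
  op <- match.arg(op)
  brush <- EBImage::makeBrush(k, shape = "box")
  d <- dim(mask)
  p <- as.integer(k)
  padded <- array(0, c(d[1] + 2 * p, d[2] + 2 * p, d[3]))
  padded[p + seq_len(d[1]), p + seq_len(d[2]), ] <- mask * 1
  out <- switch(op,
    erode = EBImage::erode(padded, brush),
    dilate = EBImage::dilate(padded, brush),
    close = EBImage::closing(padded, brush))
  array(out[p + seq_len(d[1]), p + seq_len(d[2]), ] > 0, d)
}

#' Automatic brain tissue mask
#'
#' Segmentation pipeline applied to the baseline average image: Gaussian
#' blurring, binary thresholding to the open interval (1, 100) HU, in-slice
#' erosion by a 5 x 5 x 1 box kernel, connected component analysis (3D,
#' 6-neighbourhood) keeping only the largest component, and in-slice
#' dilation by the same 5 x 5 x 1 kernel.
#'
#' @param baselineAvg 3D array in HU.
#' @param blurSigma in-slice Gaussian sigma in voxels (no smoothing across
#'   slices).
#' @param huRange exclusive attenuation bounds, default `c(1, 100)`.
#' @param kernel in-slice box kernel width for erosion/dilation.
#' @return logical 3D array.
#' @export
brainMask <- function(baselineAvg, blurSigma = 1, huRange = c(1, 100),
                      kernel = 5L) {
  # normalised smoothing: average only over supported (non-air) voxels so
  # a masked-out or cropped background does not drag the tissue edge down
  supp <- (baselineAvg != 0) * 1
  sm <- gaussSmooth3d(baselineAvg, sigma = c(blurSigma, blurSigma, 0))
  sw <- gaussSmooth3d(supp, sigma = c(blurSigma, blurSigma, 0))
  sm <- ifelse(sw > 1e-6, sm / sw, 0) * (supp > 0)
  th <- sm > huRange[1] & sm < huRange[2]
  if (!any(th)) stop("no brain found: threshold produced an empty mask")
  er <- .slabMorph(th, kernel, "erode")
  if (!any(er)) stop("no brain found: erosion removed all voxels")
  lab <- .labelComponents3d(er)
  sizes <- tabulate(lab[lab > 0])
  keep <- lab == which.max(sizes)
  .slabMorph(keep, kernel, "dilate")
}

#' Split a brain mask into hemispheres
#'
#' Partitions the brain mask at the midsagittal plane of its bounding box.
#' "Left" is the lower x-index half (radiological convention); the plane
#' voxel column at an odd-width box goes to the left half.
#'
#' @param brain logical 3D array (nonempty).
#' @param ipsilateral which side holds the stroke lesion.
#' @return a [MaskSet-class].
#' @export
hemisphereSplit <- function(brain, ipsilateral = c("left", "right")) {
  ipsilateral <- match.arg(ipsilateral)
  if (!any(brain)) stop("hemisphere split of an empty mask")
  xs <- which(apply(brain, 1, any))
  mid <- (min(xs) + max(xs)) / 2
  xIdx <- slice.index(brain, 1)
  left <- brain & (xIdx <= floor(mid))
  right <- brain & !left
  storage.mode(left) <- "logical"; storage.mode(right) <- "logical"
  new("MaskSet", brain = brain, left = left, right = right,
      ipsilateral = ipsilateral)
}

#' Full preprocessing chain for a raw series
#'
#' Motion-correction hook, baseline average, brain mask, hemisphere split,
#' baseline subtraction and temporal resampling to 1 s.
#'
#' @param series raw-domain [PerfusionSeries-class].
#' @param ipsilateral lesion side for the mask set.
#' @param targetDt,knotSpacing see [temporalResample()].
#' @param motionHook see [motionCorrect()].
#' @return list with `ctc` (1 s concentration series), `masks`
#'   ([MaskSet-class]), `baselineAvg`, and the motion-corrected `raw`
#'   series.
#' @export
preprocess <- function(series, ipsilateral = "left", targetDt = 1,
                       knotSpacing = 1.5, motionHook = NULL) {
  raw <- motionCorrect(series, motionHook)
  bavg <- baselineAverage(raw)
  brain <- brainMask(bavg)
  masks <- hemisphereSplit(brain, ipsilateral)
  ctc <- temporalResample(baselineSubtract(raw, bavg), targetDt = targetDt,
                          knotSpacing = knotSpacing)
  list(ctc = ctc, masks = masks, baselineAvg = bavg, raw = raw)
}
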