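## Block-circulant SVD deconvolution and perfusion parameter mapping.
##
## The concentration-time curve of a voxel is modelled as the convolution
## of the arterial input function (AIF) with the flow-scaled residue
## function k(t) = CBF * R(t). Deconvolution inverts this relation by
## building a circulant convolution matrix from the zero-padded AIF and
## regularising its inverse by truncating singular values below a fraction
## of the largest one. The circulant (rather than triangular) formulation
## makes the estimate insensitive to tracer arrival delay.

#' Deconvolution configuration
#'
#' @param truncationFraction singular values below this fraction of the
#'   largest are zeroed (default 0.15).
#' @param padFactor zero-padding multiple for the circulant embedding
#'   (>= 2).
#' @param clipNegative clip negative residue values to zero before taking
#'   the maximum (off by default; the raw maximum is used).
#' @return a list of class `deconvConfig`.
#' @export
deconvConfig <- function(truncationFraction = 0.15, padFactor = 2,
                         clipNegative = FALSE) {
  stopifnot(truncationFraction >= 0, truncationFraction < 1, padFactor >= 2)
  structure(list(truncationFraction = truncationFraction,
                 padFactor = padFactor, clipNegative = clipNegative),
            class = "deconvConfig")
}

## regularised reciprocal singular values: zero below frac * max
.truncateSingular <- function(s, frac) {
  inv <- ifelse(s < frac * max(s), 0, 1 / s)
  inv[!is.finite(inv)] <- 0
  inv
}

## truncated-SVD inverse of the circulant matrix built from the padded AIF
.bcsvdInverse <- function(aif, dt, cfg) {
  T <- length(aif)
  L <- as.integer(cfg$padFactor * T)
  col <- c(aif * dt, numeric(L - T))
  D <- matrix(0, L, L)
  for (j in seq_len(L)) D[, j] <- col[((seq_len(L) - j) %% L) + 1]
  sv <- svd(D)
  inv <- .truncateSingular(sv$d, cfg$truncationFraction)
  list(Dinv = sv$v %*% (inv * t(sv$u)), d = sv$d, L = L)
}

#' Block-circulant SVD deconvolution
#'
#' Deconvolves every voxel's concentration-time curve with the arterial
#' input function, yielding the flow-scaled residue curve
#' `k(t) = CBF * R(t)`. Singular values of the circulant AIF matrix below
#' `truncationFraction` of the largest are discarded; the circulant
#' padding rows beyond the acquisition length are dropped from the result.
#'
#' @param ctc concentration-domain [PerfusionSeries-class].
#' @param aif numeric AIF curve sampled on the same time grid as `ctc`.
#' @param cfg a [deconvConfig()].
#' @return residual-domain [PerfusionSeries-class] (units 1/s times
#'   relative flow).
#' @export
bcsvdDeconvolve <- function(ctc, aif, cfg = deconvConfig()) {
  stopifnot(is(ctc, "PerfusionSeries"))
  if (ctc@domain != "concentration")
    stop("deconvolution expects a concentration-domain series")
  d <- dim(ctc@values)
  if (length(aif) != d[4])
    stop("AIF length must equal the number of timepoints")
  if (all(aif == 0)) stop("AIF is identically zero")
  inv <- .bcsvdInverse(aif, ctc@dt, cfg)
  DinvTT <- inv$Dinv[seq_len(d[4]), seq_len(d[4])]
  v <- matrix(ctc@values, ncol = d[4])         # voxels x T
  k <- tcrossprod(v, DinvTT)                   # voxels x T
  new("PerfusionSeries", values = array(k, d), spacing = ctc@spacing,
      dt = ctc@dt, domain = "residual")
}

#' Perfusion parameter maps from residual curves
#'
#' Standard map conventions: CBF is the maximum of the residue curve, Tmax
#' the time of that maximum, CBV the ratio of the concentration-curve
#' integral to the AIF integral (central volume theorem numerator), and
#' MTT = CBV/CBF. Where CBF does not exceed `cbfTol`, MTT is set to zero
#' and the voxel is flagged in the `"lowFlow"` attribute of the returned
#' object's MTT map. CBF and CBV are in relative units; no
#' hematocrit/tissue-density scaling is applied.
#'
#' @param residual residual-domain [PerfusionSeries-class] from
#'   [bcsvdDeconvolve()].
#' @param ctc the matching concentration-domain series.
#' @param aif AIF curve on the same grid.
#' @param mask optional logical 3D array; voxels outside are zeroed.
#' @param cbfTol reliability tolerance for the MTT ratio.
#' @param clipNegative clip negative residue values before the maximum.
#' @return a [ParameterMaps-class].
#' @export
parameterMaps <- function(residual, ctc, aif, mask = NULL, cbfTol = 1e-6,
                          clipNegative = FALSE) {
  stopifnot(is(residual, "PerfusionSeries"), is(ctc, "PerfusionSeries"))
  if (residual@domain != "residual")
    stop("parameter mapping expects a residual-domain series")
  if (sum(aif) <= 0) stop("AIF integral must be positive")
  d <- dim(residual@values)
  k <- matrix(residual@values, ncol = d[4])
  if (clipNegative) k[k < 0] <- 0
  cbf <- apply(k, 1, max)
  tmax <- (apply(k, 1, which.max) - 1) * residual@dt
  cbv <- rowSums(matrix(ctc@values, ncol = d[4])) / sum(aif)
  low <- cbf <= cbfTol
  mtt <- numeric(length(cbf))
  mtt[!low] <- cbv[!low] / cbf[!low]
  if (!is.null(mask)) {
    keep <- as.vector(mask > 0)
    cbf[!keep] <- 0; cbv[!keep] <- 0; mtt[!keep] <- 0; tmax[!keep] <- 0
    low <- low & keep
  }
  tmax[tmax < 0 | !is.finite(tmax)] <- 0
  mttArr <- array(mtt, d[1:3])
  attr(mttArr, "lowFlow") <- array(low, d[1:3])
  new("ParameterMaps", cbf = array(cbf, d[1:3]), cbv = array(cbv, d[1:3]),
      mtt = mttArr, tmax = array(pmax(tmax, 0), d[1:3]),
      spacing = residual@spacing)
}

#' Convenience AIF pick from the tissue data
#'
#' Returns the curve of the in-mask voxel with the highest peak
#' concentration. This is a crude stand-in convenience, explicitly not the
#' automatic multi-voxel AIF definition used with clinical data; for the
#' synthetic phantom the generating AIF model is known and should be used
#' instead.
#'
#' @param ctc concentration-domain [PerfusionSeries-class].
#' @param mask logical 3D array restricting the search.
#' @return numeric AIF curve of length `T`.
#' @export
pickAif <- function(ctc, mask) {
  d <- dim(ctc@values)
  v <- matrix(ctc@values, ncol = d[4])[as.vector(mask > 0), , drop = FALSE]
  v[which.max(apply(v, 1, max)), ]
}
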