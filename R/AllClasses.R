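#' 4D perfusion series
#'
#' Container for a spatiotemporal perfusion acquisition: an `X x Y x Z x T`
#' scalar grid together with its spatial spacing (mm), temporal spacing (s)
#' and a domain tag recording where in the processing chain the values live.
#' The domain is one of `"raw"` (Hounsfield units as acquired),
#' `"concentration"` (baseline-subtracted contrast enhancement) or
#' `"residual"` (deconvolved, flow-scaled residue curves).
#'
#' @slot values numeric 4D array, `X x Y x Z x T`.
#' @slot spacing numeric length-3 voxel spacing in mm.
#' @slot dt temporal spacing in seconds.
#' @slot domain character domain tag.
#' @exportClass PerfusionSeries
setClass("PerfusionSeries",
  representation(values = "array", spacing = "numeric", dt = "numeric",
                 domain = "character"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@values)
    if (length(d) != 4L) msg <- c(msg, "values must be a 4D array")
    else if (d[4] < 4L) msg <- c(msg, "series must have at least 4 timepoints")
    if (length(object@spacing) != 3L || any(object@spacing <= 0))
      msg <- c(msg, "spacing must be 3 positive numbers (mm)")
    if (length(object@dt) != 1L || object@dt <= 0)
      msg <- c(msg, "dt must be a positive scalar (s)")
    if (!object@domain %in% c("raw", "concentration", "residual"))
      msg <- c(msg, "domain must be raw, concentration or residual")
    if (length(msg)) msg else TRUE
  })

#' Brain and hemisphere masks
#'
#' A brain tissue mask together with its partition into left and right
#' hemisphere masks and a record of which side is ipsilateral to the stroke
#' lesion. Left and right are disjoint and their union is the brain mask;
#' "left" follows the radiological convention of the lower x-index half.
#'
#' @slot brain,left,right logical 3D arrays.
#' @slot ipsilateral `"left"` or `"right"`.
#' @exportClass MaskSet
setClass("MaskSet",
  representation(brain = "array", left = "array", right = "array",
                 ipsilateral = "character"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@brain), dim(object@left)) ||
        !identical(dim(object@brain), dim(object@right)))
      msg <- c(msg, "mask dimensions differ")
    if (any(object@left & object@right))
      msg <- c(msg, "left and right hemisphere masks overlap")
    if (!identical((object@left | object@right), (object@brain > 0)))
      msg <- c(msg, "left and right masks must partition the brain mask")
    if (!object@ipsilateral %in% c("left", "right"))
      msg <- c(msg, "ipsilateral must be 'left' or 'right'")
    if (length(msg)) msg else TRUE
  })

#' Perfusion parameter maps
#'
#' Co-registered 3D maps of cerebral blood flow (CBF, relative flow units),
#' cerebral blood volume (CBV, relative volume units), mean transit time
#' (MTT, s) and time-to-maximum of the residue curve (Tmax, s), as derived
#' from deconvolved residual curves. MTT is defined by the central volume
#' theorem MTT = CBV/CBF and is set to zero (flagged) where CBF falls below
#' the reliability tolerance.
#'
#' @slot cbf,cbv,mtt,tmax numeric 3D arrays.
#' @slot spacing voxel spacing in mm.
#' @exportClass ParameterMaps
setClass("ParameterMaps",
  representation(cbf = "array", cbv = "array", mtt = "array", tmax = "array",
                 spacing = "numeric"),
  validity = function(object) {
    msg <- character()
    d <- dim(object@cbf)
    for (s in c("cbv", "mtt", "tmax"))
      if (!identical(dim(slot(object, s)), d))
        msg <- c(msg, sprintf("map '%s' has mismatching dimensions", s))
    if (any(!is.finite(object@cbf)) || any(!is.finite(object@tmax)))
      msg <- c(msg, "maps contain non-finite values")
    if (any(object@tmax < 0)) msg <- c(msg, "tmax must be non-negative")
    if (length(msg)) msg else TRUE
  })

#' Arterial input function model
#'
#' Peak-normalised gamma-variate bolus model
#' `A * (u/(a*b))^a * exp(a - u/b)` with `u = t - t0`, zero for `t <= t0`.
#' Its single maximum of height `amplitude` occurs at `t0 + a*b`.
#'
#' @slot t0 bolus arrival delay (s).
#' @slot shape gamma shape parameter `a` (dimensionless, > 0).
#' @slot scale gamma scale parameter `b` (s, > 0).
#' @slot amplitude peak height (HU).
#' @exportClass AIFModel
setClass("AIFModel",
  representation(t0 = "numeric", shape = "numeric", scale = "numeric",
                 amplitude = "numeric"),
  validity = function(object) {
    msg <- character()
    if (object@shape <= 0) msg <- c(msg, "shape must be > 0")
    if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
    if (object@t0 < 0) msg <- c(msg, "t0 must be >= 0")
    if (length(msg)) msg else TRUE
  })

#' Hemodynamic ground truth of a synthetic patient
#'
#' Per-voxel true perfusion parameters used to generate a synthetic 4D CTP
#' series, plus the hypoperfused lesion mask, the driving arterial input
#' function, the base tissue attenuation and acquisition geometry. Wherever
#' CBF is positive, `mtt == cbv / cbf`; `tmax` is the argmax of the
#' generating residue curve (bolus delay plus rise time).
#'
#' @slot cbf,cbv,mtt,tmax numeric 3D arrays (rel. flow, rel. volume, s, s).
#' @slot lesion logical 3D array, the hypoperfused region.
#' @slot baseHU numeric 3D array of unenhanced attenuation (HU).
#' @slot aif [AIFModel-class].
#' @slot riseTau residue rise time (s).
#' @slot noiseSigma additive image noise standard deviation (HU).
#' @slot spacing voxel spacing (mm); @slot dt frame spacing (s).
#' @exportClass PhantomTruth
setClass("PhantomTruth",
  representation(cbf = "array", cbv = "array", mtt = "array", tmax = "array",
                 lesion = "array", baseHU = "array", aif = "AIFModel",
                 riseTau = "numeric", noiseSigma = "numeric",
                 spacing = "numeric", dt = "numeric"),
  validity = function(object) {
    msg <- character()
    pos <- object@cbf > 0
    if (any(pos)) {
      dev <- abs(object@mtt[pos] * object@cbf[pos] - object@cbv[pos])
      if (max(dev) > 1e-8 * max(object@cbv))
        msg <- c(msg, "mtt * cbf must equal cbv where cbf > 0")
    }
    if (any(object@tmax < 0)) msg <- c(msg, "tmax must be non-negative")
    if (any(object@lesion & !(object@cbf > 0)))
      msg <- c(msg, "lesion mask must lie inside perfused tissue")
    if (length(msg)) msg else TRUE
  })

#' Synthetic cohort specification
#'
#' Sizes, treatment-arm split, lesion volume distributions and the master
#' seed for a synthetic patient cohort. Defaults mirror the study cohort
#' structure: 145 patients, 102 treated with intra-arterial mechanical
#' thrombectomy (IA) and 43 with intravenous thrombolysis (IV), with
#' log-normal lesion-volume distributions per arm (ml).
#'
#' @slot nTotal,nIA,nIV patient counts, `nIA + nIV == nTotal`.
#' @slot seed master seed; every patient derives its own stream from it.
#' @slot lesionMeanMl,lesionSdMl named numeric (IA, IV): mean and sd of the
#'   target lesion volume (ml).
#' @slot noiseSigma image noise sd (HU).
#' @slot infarctSlopeTmax,infarctSlopeCbf,infarctTmax0,infarctCbf0 logistic
#'   link parameters for the follow-up infarct probability.
#' @slot dim,gridSpacing,nTime,gridDt acquisition geometry.
#' @exportClass CohortSpec
setClass("CohortSpec",
  representation(nTotal = "numeric", nIA = "numeric", nIV = "numeric",
                 seed = "numeric", lesionMeanMl = "numeric",
                 lesionSdMl = "numeric", noiseSigma = "numeric",
                 infarctSlopeTmax = "numeric", infarctSlopeCbf = "numeric",
                 infarctTmax0 = "numeric", infarctCbf0 = "numeric",
                 dim = "numeric", gridSpacing = "numeric", nTime = "numeric",
                 gridDt = "numeric"),
  validity = function(object) {
    if (object@nIA + object@nIV != object@nTotal)
      "nIA + nIV must equal nTotal"
    else TRUE
  })
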