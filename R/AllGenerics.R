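#' @rdname PerfusionSeries-class
#' @param object a `PerfusionSeries`
#' @export
setGeneric("seriesValues", function(object) standardGeneric("seriesValues"))
#' @rdname PerfusionSeries-class
#' @export
setGeneric("seriesDt", function(object) standardGeneric("seriesDt"))
#' @rdname PerfusionSeries-class
#' @export
setGeneric("seriesDomain", function(object) standardGeneric("seriesDomain"))
#' @rdname PerfusionSeries-class
#' @export
setGeneric("voxelSpacing", function(object) standardGeneric("voxelSpacing"))
#' @rdname MaskSet-class
#' @param object a `MaskSet`
#' @export
setGeneric("brainMaskOf", function(object) standardGeneric("brainMaskOf"))
#' @rdname MaskSet-class
#' @param side `"left"`, `"right"` or `"ipsilateral"`
#' @export
setGeneric("hemisphereMask",
           function(object, side = "ipsilateral") standardGeneric("hemisphereMask"))
#' @rdname ParameterMaps-class
#' @param object a `ParameterMaps`
#' @param which one of `"cbf"`, `"cbv"`, `"mtt"`, `"tmax"`
#' @export
setGeneric("parameterMap",
           function(object, which) standardGeneric("parameterMap"))

setMethod("seriesValues", "PerfusionSeries", function(object) object@values)
setMethod("seriesDt", "PerfusionSeries", function(object) object@dt)
setMethod("seriesDomain", "PerfusionSeries", function(object) object@domain)
setMethod("voxelSpacing", "PerfusionSeries", function(object) object@spacing)
setMethod("voxelSpacing", "ParameterMaps", function(object) object@spacing)
setMethod("voxelSpacing", "PhantomTruth", function(object) object@spacing)
setMethod("brainMaskOf", "MaskSet", function(object) object@brain > 0)
setMethod("hemisphereMask", "MaskSet", function(object, side = "ipsilateral") {
  side <- match.arg(side, c("ipsilateral", "contralateral", "left", "right"))
  if (side == "ipsilateral") side <- object@ipsilateral
  if (side == "contralateral")
    side <- if (object@ipsilateral == "left") "right" else "left"
  slot(object, side) > 0
})
setMethod("parameterMap", "ParameterMaps", function(object, which) {
  which <- match.arg(which, c("cbf", "cbv", "mtt", "tmax"))
  slot(object, which)
})

setMethod("show", "PerfusionSeries", function(object) {
  d <- dim(object@values)
  cat(sprintf("PerfusionSeries [%s]: %d x %d x %d voxels, %d timepoints\n",
              object@domain, d[1], d[2], d[3], d[4]))
  cat(sprintf("  spacing %s mm, dt %.3g s\n",
              paste(signif(object@spacing, 3), collapse = " x "), object@dt))
})
setMethod("show", "MaskSet", function(object) {
  cat(sprintf("MaskSet: %d brain voxels (%d left / %d right), ipsilateral %s\n",
              sum(object@brain > 0), sum(object@left > 0),
              sum(object@right > 0), object@ipsilateral))
})
setMethod("show", "ParameterMaps", function(object) {
  d <- dim(object@cbf)
  cat(sprintf("ParameterMaps: %d x %d x %d (cbf, cbv, mtt, tmax)\n",
              d[1], d[2], d[3]))
})
setMethod("show", "AIFModel", function(object) {
  cat(sprintf(
    "AIFModel: gamma-variate, t0 %.3g s, shape %.3g, scale %.3g s, peak %.3g HU at %.3g s\n",
    object@t0, object@shape, object@scale, object@amplitude,
    object@t0 + object@shape * object@scale))
})
setMethod("show", "PhantomTruth", function(object) {
  d <- dim(object@cbf)
  cat(sprintf("PhantomTruth: %d x %d x %d, %d lesion voxels, noise sigma %.3g HU\n",
              d[1], d[2], d[3], sum(object@lesion > 0), object@noiseSigma))
})
setMethod("show", "CohortSpec", function(object) {
  cat(sprintf("CohortSpec: %d patients (IA %d / IV %d), seed %d\n",
              object@nTotal, object@nIA, object@nIV, object@seed))
})
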