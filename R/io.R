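## NIfTI-1 input/output. All volumes travel as .nii.gz with voxel spacing
## in pixdim[1:3] (mm) and, for 4D series, the frame spacing in pixdim[4]
## (s). Masks are written as unsigned bytes.

#' Write a volume to a NIfTI-1 file
#'
#' @param x a [PerfusionSeries-class], or a numeric 3D/4D array.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param spacing voxel spacing in mm (taken from the object when `x` is a
#'   series).
#' @param dt temporal spacing in s, required for bare 4D arrays.
#' @return the path, invisibly.
#' @export
writeVolume <- function(x, path, spacing = c(1, 1, 1), dt = NULL) {
  if (is(x, "PerfusionSeries")) {
    spacing <- x@spacing; dt <- x@dt; x <- x@values
  }
  img <- RNifti::asNifti(x)
  nd <- length(dim(x))
  if (nd == 4L) {
    if (is.null(dt)) stop("a 4D volume needs a temporal spacing (dt)")
    img <- RNifti::`pixdim<-`(img, c(spacing, dt))
    img$xyzt_units <- 10L               # mm + seconds
  } else {
    img <- RNifti::`pixdim<-`(img, spacing)
  }
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname writeVolume
#' @param mask logical/binary 3D array; stored as unsigned byte with
#'   values restricted to 0 and 1.
#' @export
writeMask <- function(mask, path, spacing = c(1, 1, 1)) {
  img <- RNifti::asNifti(array(as.integer(mask > 0), dim(mask)))
  img <- RNifti::`pixdim<-`(img, spacing)
  RNifti::writeNifti(img, path, datatype = "uint8")
  invisible(path)
}

#' Read a volume from a NIfTI-1 file
#'
#' 4D files are returned as [PerfusionSeries-class] (the temporal spacing
#' must be present in `pixdim[4]`); 3D files are returned as arrays with a
#' `spacing` attribute.
#'
#' @param path NIfTI file.
#' @param domain domain tag to stamp on a 4D series.
#' @export
readVolume <- function(path, domain = "raw") {
  img <- RNifti::readNifti(path)
  a <- array(as.vector(img), dim(img))
  pd <- RNifti::pixdim(img)
  if (length(dim(a)) == 4L) {
    tUnit <- bitwAnd(RNifti::niftiHeader(img)$xyzt_units, 56L)
    if (length(pd) < 4L || pd[4] <= 0 || tUnit == 0L)
      stop("4D input lacks a temporal spacing; set pixdim[4] to the frame ",
           "interval in seconds (and xyzt_units to a time unit)")
    new("PerfusionSeries", values = a, spacing = pd[1:3], dt = pd[4],
        domain = domain)
  } else {
    attr(a, "spacing") <- pd[seq_len(min(3, length(pd)))]
    a
  }
}
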