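## Comparison predictors: optimal Tmax thresholding with leave-one-out
## threshold selection, and a voxelwise random decision forest with
## class balancing and morphological noise reduction.

#' Candidate Tmax threshold grid
#'
#' 120 threshold values spanning (0, 24] s at 0.2 s intervals. The
#' degenerate 0 s threshold is excluded so that the grid has exactly 120
#' elements.
#'
#' @return numeric vector of length 120.
#' @export
tmaxGrid <- function() seq_len(120L) * 0.2

#' Threshold a Tmax map into a lesion prediction
#'
#' Voxels are predicted as infarct only if their Tmax strictly exceeds the
#' threshold.
#'
#' @param tmaxMap numeric 3D array (s).
#' @param threshold threshold in seconds (>= 0).
#' @return logical array of the same shape.
#' @export
tmaxPredict <- function(tmaxMap, threshold) {
  stopifnot(threshold >= 0)
  tmaxMap > threshold
}

#' Leave-one-out threshold optimisation
#'
#' For each patient, the mean Dice over all *other* patients is computed at
#' each candidate threshold and the patient receives the argmax threshold.
#' Ties resolve to the smallest threshold. The held-out patient's own Dice
#' row never influences their threshold.
#'
#' @param diceTable numeric matrix, patients x thresholds.
#' @param grid candidate thresholds matching the table columns.
#' @return data.frame with per-patient `index`, `threshold` and the
#'   achieved leave-one-out mean Dice.
#' @export
looOptimize <- function(diceTable, grid) {
  diceTable <- as.matrix(diceTable)
  if (nrow(diceTable) < 2L)
    stop("leave-one-out optimisation is undefined for fewer than 2 patients")
  if (ncol(diceTable) != length(grid))
    stop("grid length must match the table columns")
  res <- t(vapply(seq_len(nrow(diceTable)), function(i) {
    m <- colMeans(diceTable[-i, , drop = FALSE])
    j <- which.max(m)                       # first max = smallest threshold
    c(index = j, threshold = grid[j], looDice = m[j])
  }, numeric(3)))
  out <- as.data.frame(res)
  out$patient <- rownames(diceTable) %||% as.character(seq_len(nrow(out)))
  out[, c("patient", "index", "threshold", "looDice")]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Random decision forest configuration
#'
#' @param nTrees number of trees (100).
#' @param r proportion of training instances used to fit each tree (0.5).
#' @param seed RNG seed for undersampling and forest growth.
#' @export
rdfConfig <- function(nTrees = 100L, r = 0.5, seed = 1L) {
  stopifnot(r > 0, r <= 1, nTrees >= 1)
  structure(list(nTrees = as.integer(nTrees), r = r, seed = as.integer(seed)),
            class = "rdfConfig")
}

#' Train the voxelwise random decision forest
#'
#' Input features are the four perfusion parameters of each voxel. The
#' training set is balanced by per-patient stratified random
#' undersampling: within every patient, all minority-class voxels are kept
#' together with an equal number of randomly chosen majority-class voxels.
#' The forest is a regression forest over the binary labels; its averaged
#' tree output is the infarct probability.
#'
#' @param features data.frame or matrix with columns `cbf`, `cbv`, `mtt`,
#'   `tmax` (one row per voxel).
#' @param labels binary (0/1) outcome per voxel.
#' @param patients patient id per voxel, for per-patient undersampling.
#' @param cfg an [rdfConfig()].
#' @return a fitted model (class `rdfModel`).
#' @export
rdfTrain <- function(features, labels, patients, cfg = rdfConfig()) {
  features <- as.data.frame(features)
  stopifnot(nrow(features) == length(labels),
            length(labels) == length(patients))
  labels <- as.integer(labels > 0)
  if (length(unique(labels)) < 2L)
    stop("both outcome classes must be present in the training data")
  set.seed(cfg$seed)
  keep <- unlist(lapply(split(seq_along(labels), patients), function(ix) {
    l <- labels[ix]
    nPos <- sum(l == 1); nNeg <- sum(l == 0)
    if (nPos == 0L || nNeg == 0L) return(integer(0))  # nothing to balance on
    minority <- if (nPos <= nNeg) 1L else 0L
    minIx <- ix[l == minority]
    majIx <- ix[l != minority]
    c(minIx, sample(majIx, length(minIx)))
  }), use.names = FALSE)
  if (!length(keep)) stop("no patient contributed both outcome classes")
  dat <- features[keep, , drop = FALSE]
  dat$.outcome <- as.numeric(labels[keep])
  fit <- ranger::ranger(
    dependent.variable.name = ".outcome", data = dat,
    num.trees = cfg$nTrees, sample.fraction = cfg$r, replace = FALSE,
    seed = cfg$seed, num.threads = 1)
  structure(list(forest = fit, features = colnames(features), cfg = cfg,
                 nTrain = length(keep)),
            class = "rdfModel")
}

#' Predict infarct probabilities with a trained forest
#'
#' @param model an `rdfModel` from [rdfTrain()].
#' @param features data.frame/matrix with the training feature columns.
#' @return numeric vector of probabilities in `[0, 1]` (the mean of the
#'   individual tree outputs).
#' @export
rdfPredict <- function(model, features) {
  features <- as.data.frame(features)
  if (!all(model$features %in% colnames(features)))
    stop("feature columns do not match the trained model")
  p <- predict(model$forest, data = features[, model$features, drop = FALSE],
               num.threads = 1)$predictions
  pmin(pmax(p, 0), 1)
}

#' Morphological noise reduction of a lesion mask
#'
#' In-slice morphological closing with a 3 x 3 voxel kernel followed by 3D
#' connected component analysis (6-neighbourhood) removing components of
#' fewer than 10 voxels. Idempotent.
#'
#' @param mask logical 3D array.
#' @param minVoxels strict lower size bound for surviving components.
#' @return filtered logical array.
#' @export
noiseFilter <- function(mask, minVoxels = 10L) {
  if (!any(mask)) return(mask & FALSE)
  cl <- .slabMorph(mask, 3L, "close")
  lab <- .labelComponents3d(cl)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= minVoxels)
  out <- array(lab %in% keep, dim(mask))
  out
}
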