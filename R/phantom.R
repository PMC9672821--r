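## Synthetic 4D CTP head phantom with known hemodynamic ground truth.
##
## The phantom drives every downstream stage: a head-shaped volume (skull
## shell / brain / ventricles), per-voxel concentration-time curves obtained
## by convolving a gamma-variate arterial input function with a
## flow-scaled residue function, a hypoperfused lesion with reduced CBF and
## prolonged MTT/Tmax, and a follow-up infarct mask drawn stochastically
## from the hemodynamic deficit.

#' Construct an arterial input function model
#'
#' Peak-normalised gamma-variate bolus: zero until `t0`, then
#' `amplitude * (u/(shape*scale))^shape * exp(shape - u/scale)` with
#' `u = t - t0`. The single maximum of height `amplitude` is at
#' `t0 + shape*scale`.
#'
#' @param t0 bolus arrival delay in seconds.
#' @param shape,scale gamma shape (dimensionless) and scale (s).
#' @param amplitude peak height in HU.
#' @return an [AIFModel-class] object.
#' @export
aifModel <- function(t0 = 10, shape = 2, scale = 1, amplitude = 10) {
  new("AIFModel", t0 = t0, shape = shape, scale = scale,
      amplitude = amplitude)
}

#' Evaluate an AIF model on a time grid
#'
#' @param model an [AIFModel-class].
#' @param timepoints strictly increasing, uniformly spaced time grid (s).
#' @return numeric vector of concentrations (HU), non-negative, zero before
#'   `t0`, unimodal.
#' @export
genAif <- function(model, timepoints) {
  stopifnot(is(model, "AIFModel"))
  if (length(timepoints) > 1) {
    d <- diff(timepoints)
    if (any(d <= 0) || max(d) - min(d) > 1e-8 * max(d))
      stop("timepoints must be a strictly increasing uniform grid")
  }
  u <- timepoints - model@t0
  y <- numeric(length(u))
  p <- u > 0
  ab <- model@shape * model@scale
  y[p] <- model@amplitude * (u[p] / ab)^model@shape *
    exp(model@shape - u[p] / model@scale)
  y
}

## analytic integral of the gamma-variate over (t0, Inf); used by tests and
## by CBV sanity checks
aifIntegral <- function(model) {
  a <- model@shape; b <- model@scale
  model@amplitude * exp(a) / (a * b)^a * b^(a + 1) * gamma(a + 1)
}

## Residue function with a smooth bolus-dispersion rise: sin^2 ramp from 0
## to 1 over `tau` seconds starting at `delay`, then exponential decay with
## scale mtt - tau/2 so that the integral equals mtt (and hence
## CBV = CBF * MTT). The argmax is exactly delay + tau, which is the Tmax
## ground truth of the voxel.
residueCurve <- function(t, delay, mtt, tau = 3) {
  stopifnot(mtt > tau / 2)
  u <- t - delay
  r <- numeric(length(t))
  rise <- u >= 0 & u < tau
  r[rise] <- sin(pi * u[rise] / (2 * tau))^2
  dec <- u >= tau
  r[dec] <- exp(-(u[dec] - tau) / (mtt - tau / 2))
  r
}

## default head geometry: concentric ellipsoids in mm coordinates
phantomGeometry <- function(dim = c(64, 64, 8), spacing = c(3, 3, 5)) {
  cx <- (seq_len(dim[1]) - (dim[1] + 1) / 2) * spacing[1]
  cy <- (seq_len(dim[2]) - (dim[2] + 1) / 2) * spacing[2]
  cz <- (seq_len(dim[3]) - (dim[3] + 1) / 2) * spacing[3]
  x <- array(rep(cx, times = dim[2] * dim[3]), dim)
  y <- array(rep(rep(cy, each = dim[1]), times = dim[3]), dim)
  z <- array(rep(cz, each = dim[1] * dim[2]), dim)
  semi <- c(0.46 * dim[1] * spacing[1], 0.48 * dim[2] * spacing[2], 60)
  r <- sqrt((x / semi[1])^2 + (y / semi[2])^2 + (z / semi[3])^2)
  vent <- ((abs(x) - 12) / 8)^2 + ((y + 5) / 20)^2 + (z / 12)^2 <= 1
  # a subarachnoid CSF gap separates brain tissue from the skull shell, as
  # in a real head; it keeps the blurred skull out of the brain rim during
  # threshold-based masking
  list(x = x, y = y, z = z, r = r,
       skull = r > 0.9 & r <= 1, csf = r > 0.85 & r <= 0.9,
       brain = r <= 0.85, ventricle = vent & r <= 0.85)
}

#' Synthetic cohort specification
#'
#' Defaults mirror the reference cohort structure: 145 patients split
#' 102 (70%) IA / 43 (30%) IV, with per-arm log-normal lesion volume
#' distributions matching the reported arm means and standard deviations
#' (IA 55.6 (74.4) ml, IV 117.5 (134.9) ml).
#'
#' @param nTotal,nIA,nIV cohort sizes (`nIA + nIV == nTotal`).
#' @param seed master seed; each patient's random stream derives from it.
#' @param lesionMeanMl,lesionSdMl named numeric `c(IA=, IV=)`: target lesion
#'   volume moments in ml.
#' @param noiseSigma additive Gaussian image noise sd (HU).
#' @param infarctSlopeTmax,infarctSlopeCbf,infarctTmax0,infarctCbf0
#'   parameters of the logistic infarct link
#'   `plogis(sT*(Tmax - T0) + sC*(C0 - CBF))`; `infarctSlopeTmax = Inf`
#'   degenerates to the deterministic rule `Tmax > infarctTmax0`.
#' @param dim,gridSpacing,nTime,gridDt acquisition geometry (voxels, mm,
#'   frames, s).
#' @return a [CohortSpec-class].
#' @export
cohortSpec <- function(nTotal = 145, nIA = 102, nIV = nTotal - nIA, seed = 1,
                       lesionMeanMl = c(IA = 55.64, IV = 117.5),
                       lesionSdMl = c(IA = 74.37, IV = 134.9),
                       noiseSigma = 2,
                       infarctSlopeTmax = 3, infarctSlopeCbf = 3,
                       infarctTmax0 = 6, infarctCbf0 = 0.35,
                       dim = c(64, 64, 8), gridSpacing = c(3, 3, 5),
                       nTime = 48, gridDt = 1.8) {
  new("CohortSpec", nTotal = nTotal, nIA = nIA, nIV = nIV, seed = seed,
      lesionMeanMl = lesionMeanMl, lesionSdMl = lesionSdMl,
      noiseSigma = noiseSigma, infarctSlopeTmax = infarctSlopeTmax,
      infarctSlopeCbf = infarctSlopeCbf, infarctTmax0 = infarctTmax0,
      infarctCbf0 = infarctCbf0, dim = dim, gridSpacing = gridSpacing,
      nTime = nTime, gridDt = gridDt)
}

## normal-tissue hemodynamics (relative flow units / seconds)
.normalTissue <- list(cbf = 0.6, mtt = 4, tmax = 4, tau = 3,
                      huBrain = 35, huVentricle = 5, huCsf = 10,
                      huSkull = 1000)

#' Generate the hemodynamic ground truth of one synthetic patient
#'
#' Builds the head geometry, samples a lesion (side, volume, position) for
#' the given treatment arm from the cohort specification and fills the true
#' CBF/CBV/MTT/Tmax maps. Lesion severity decreases linearly from the core
#' to the boundary; severity `s` maps to `CBF*(1-0.7s)`, `MTT*(1+1.5s)` and
#' `Tmax + 8s`. Uses the current RNG stream.
#'
#' @param spec a [CohortSpec-class].
#' @param arm `"IA"` or `"IV"`.
#' @return a [PhantomTruth-class].
#' @export
genPhantomTruth <- function(spec, arm = "IA") {
  g <- phantomGeometry(spec@dim, spec@gridSpacing)
  nt <- .normalTissue
  perf <- g$brain & !g$ventricle
  cbf <- array(0, spec@dim); mtt <- array(0, spec@dim)
  tmax <- array(0, spec@dim)
  cbf[perf] <- nt$cbf; mtt[perf] <- nt$mtt; tmax[perf] <- nt$tmax

  side <- sample(c(-1, 1), 1)
  mu <- log(spec@lesionMeanMl[[arm]]^2 /
              sqrt(spec@lesionMeanMl[[arm]]^2 + spec@lesionSdMl[[arm]]^2))
  sig <- sqrt(log(1 + (spec@lesionSdMl[[arm]] / spec@lesionMeanMl[[arm]])^2))
  volMl <- min(max(rlnorm(1, mu, sig), 5), 250)
  czl <- runif(1, -6, 6)
  cyl <- runif(1, -25, 25)
  cxl <- side * runif(1, 25, 45)
  c.ax <- 14
  a.ax <- sqrt(volMl * 1000 * 3 / (4 * pi * 0.85 * c.ax))
  rl <- sqrt(((g$x - cxl) / a.ax)^2 + ((g$y - cyl) / (0.85 * a.ax))^2 +
               ((g$z - czl) / c.ax)^2)
  lesion <- rl <= 1 & perf
  # quantised severity keeps the number of distinct curves small
  s <- round(pmax(0, 1 - rl[lesion]), 3)
  cbf[lesion] <- nt$cbf * (1 - 0.7 * s)
  mtt[lesion] <- nt$mtt * (1 + 1.5 * s)
  tmax[lesion] <- nt$tmax + 8 * s

  base <- array(0, spec@dim)
  base[g$skull] <- nt$huSkull
  base[g$csf] <- nt$huCsf
  base[g$brain] <- nt$huBrain
  base[g$ventricle] <- nt$huVentricle

  new("PhantomTruth", cbf = cbf, cbv = cbf * mtt, mtt = mtt, tmax = tmax,
      lesion = lesion, baseHU = base,
      aif = aifModel(amplitude = 10), riseTau = nt$tau,
      noiseSigma = spec@noiseSigma, spacing = spec@gridSpacing,
      dt = spec@gridDt)
}

#' Generate noise-free tissue concentration-time curves
#'
#' Forward model: each voxel's curve is the continuous convolution of the
#' arterial input function with the voxel's flow-scaled residue function,
#' `C(t) = CBF * (AIF (*) R)(t)`, evaluated on a supersampled grid
#' (`dt/18`) by FFT and sampled at the frame times. Voxels with zero CBF
#' produce identically zero curves.
#'
#' @param truth a [PhantomTruth-class].
#' @param nTime number of frames.
#' @return a [PerfusionSeries-class] in the concentration domain.
#' @export
genTissueCurves <- function(truth, nTime = 48) {
  dt <- truth@dt
  perf <- truth@cbf > 0
  if (any(truth@mtt[perf] <= 0))
    stop("MTT must be positive wherever CBF > 0")
  oversample <- 18L
  dtf <- dt / oversample
  tf <- seq(0, (nTime - 1) * dt, by = dtf)
  nf <- length(tf)
  aifF <- genAif(truth@aif, tf)

  key <- paste(truth@mtt[perf], truth@tmax[perf])
  uk <- unique(key)
  ui <- match(key, uk)
  parts <- strsplit(uk, " ", fixed = TRUE)
  np <- 2^ceiling(log2(2 * nf))
  fA <- fft(c(aifF, numeric(np - nf)))
  K <- vapply(parts, function(p) {
    mtt <- as.numeric(p[1]); tmx <- as.numeric(p[2])
    residueCurve(tf, delay = tmx - truth@riseTau, mtt = mtt,
                 tau = truth@riseTau)
  }, numeric(nf))
  Kp <- rbind(K, matrix(0, np - nf, ncol(K)))
  conv <- Re(stats::mvfft(stats::mvfft(Kp) * fA, inverse = TRUE))[seq_len(nf), , drop = FALSE] / np
  conv <- conv * dtf
  conv[conv < 0] <- 0          # FFT round-off; the true convolution is >= 0
  frameIdx <- round(seq(0, (nTime - 1) * dt, by = dt) / dtf) + 1
  Cu <- conv[frameIdx, , drop = FALSE]          # nTime x nUnique

  vals <- array(0, c(dim(truth@cbf), nTime))
  flat <- matrix(0, nrow = sum(perf), ncol = nTime)
  flat[] <- t(Cu[, ui, drop = FALSE]) * truth@cbf[perf]
  for (t in seq_len(nTime)) {
    v <- array(0, dim(truth@cbf)); v[perf] <- flat[, t]
    vals[, , , t] <- v
  }
  new("PerfusionSeries", values = vals, spacing = truth@spacing, dt = dt,
      domain = "concentration")
}

## follow-up infarct mask: logistic link on (Tmax, CBF) thresholded against
## a spatially smoothed uniform field (coherent, learnable but noisy target)
genFollowupMask <- function(truth, spec) {
  perf <- truth@cbf > 0
  if (is.infinite(spec@infarctSlopeTmax)) {
    p <- (truth@tmax > spec@infarctTmax0) * 1
  } else {
    p <- plogis(spec@infarctSlopeTmax * (truth@tmax - spec@infarctTmax0) +
                  spec@infarctSlopeCbf * (spec@infarctCbf0 - truth@cbf))
  }
  g <- array(rnorm(length(truth@cbf)), dim(truth@cbf))
  g <- gaussSmooth3d(g, sigma = c(1.5, 1.5, 0.5))
  u <- pnorm(g / sd(g))
  mask <- (u < p) & perf
  storage.mode(mask) <- "logical"
  mask
}

## separable Gaussian smoothing of a 3D array (small kernels, edge-clamped
## normalisation)
gaussSmooth3d <- function(x, sigma = c(1.5, 1.5, 0.5)) {
  smooth1 <- function(a, s, axis) {
    if (s <= 0) return(a)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2)); k <- k / sum(k)
    d <- dim(a)
    perm <- switch(axis, c(1, 2, 3), c(2, 1, 3), c(3, 1, 2))
    ap <- aperm(a, perm)
    m <- matrix(ap, nrow = d[axis])
    n <- nrow(m)
    out <- matrix(0, n, ncol(m))
    wt <- numeric(n)
    for (j in seq_along(k)) {
      off <- j - r - 1L
      src <- seq_len(n) + off
      ok <- src >= 1 & src <= n
      out[ok, ] <- out[ok, ] + k[j] * m[src[ok], ]
      wt[ok] <- wt[ok] + k[j]
    }
    out <- out / wt
    inv <- order(perm)
    aperm(array(out, dim(ap)), inv)
  }
  x <- smooth1(x, sigma[1], 1L)
  x <- smooth1(x, sigma[2], 2L)
  smooth1(x, sigma[3], 3L)
}

## deterministic per-patient seed derived from the master seed
patientSeed <- function(spec, index) {
  (spec@seed * 1009L + index * 7919L) %% 2147483629L
}

#' Cohort table for a specification
#'
#' @param spec a [CohortSpec-class].
#' @return data.frame with `patient_id`, `arm` and `seed` columns; the first
#'   `nIA` patients belong to the IA arm.
#' @export
cohortTable <- function(spec) {
  n <- spec@nTotal
  data.frame(
    patient_id = sprintf("sf%03d", seq_len(n)),
    arm = rep(c("IA", "IV"), c(spec@nIA, spec@nIV)),
    seed = vapply(seq_len(n), function(i) patientSeed(spec, i), numeric(1)),
    stringsAsFactors = FALSE)
}

#' Generate one synthetic patient
#'
#' Produces the raw 4D series in HU (tissue attenuation plus contrast
#' enhancement plus Gaussian noise), the hemodynamic ground truth and the
#' stochastic follow-up infarct mask. A fixed `(spec, index)` pair is
#' bit-reproducible.
#'
#' @param spec a [CohortSpec-class].
#' @param index patient index in `cohortTable(spec)`.
#' @return list with elements `series` ([PerfusionSeries-class], raw HU),
#'   `truth` ([PhantomTruth-class]), `followup` (logical 3D array),
#'   `arm` and `patient_id`.
#' @export
genPatient <- function(spec, index) {
  tab <- cohortTable(spec)
  stopifnot(index >= 1, index <= nrow(tab))
  set.seed(tab$seed[index])
  truth <- genPhantomTruth(spec, tab$arm[index])
  conc <- genTissueCurves(truth, spec@nTime)
  vals <- conc@values + as.vector(truth@baseHU)
  if (spec@noiseSigma > 0)
    vals <- vals + array(rnorm(length(vals), sd = spec@noiseSigma), dim(vals))
  followup <- genFollowupMask(truth, spec)
  list(series = new("PerfusionSeries", values = vals,
                    spacing = spec@gridSpacing, dt = spec@gridDt,
                    domain = "raw"),
       truth = truth, followup = followup,
       arm = tab$arm[index], patient_id = tab$patient_id[index])
}

#' Write a synthetic cohort to disk
#'
#' One NIfTI file set per patient (4D CTP, truth parameter maps, lesion and
#' follow-up masks), a JSON truth sidecar, and a cohort manifest CSV.
#'
#' @param spec a [CohortSpec-class].
#' @param dir output directory (created if needed).
#' @param overwrite error on an existing manifest unless `TRUE`.
#' @return the manifest data.frame, invisibly.
#' @export
genCohort <- function(spec, dir, overwrite = FALSE) {
  manifestPath <- file.path(dir, "manifest.csv")
  if (file.exists(manifestPath) && !overwrite)
    stop("manifest already exists at ", manifestPath)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tab <- cohortTable(spec)
  tab$path <- file.path(dir, tab$patient_id)
  for (i in seq_len(nrow(tab))) {
    p <- genPatient(spec, i)
    pdir <- tab$path[i]
    dir.create(pdir, showWarnings = FALSE)
    writeVolume(p$series, file.path(pdir, "ctp_4d.nii.gz"))
    for (m in c("cbf", "cbv", "mtt", "tmax"))
      writeVolume(slot(p$truth, m), file.path(pdir, paste0("true_", m, ".nii.gz")),
                  spacing = spec@gridSpacing)
    writeMask(p$truth@lesion, file.path(pdir, "true_lesion.nii.gz"),
              spacing = spec@gridSpacing)
    writeMask(p$followup, file.path(pdir, "followup_infarct.nii.gz"),
              spacing = spec@gridSpacing)
    jsonlite::write_json(
      list(patient_id = p$patient_id, arm = p$arm, seed = tab$seed[i],
           aif = list(t0 = p$truth@aif@t0, shape = p$truth@aif@shape,
                      scale = p$truth@aif@scale,
                      amplitude = p$truth@aif@amplitude),
           rise_tau = p$truth@riseTau, noise_sigma = p$truth@noiseSigma,
           dt = p$truth@dt, spacing = p$truth@spacing),
      file.path(pdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  }
  write.csv(tab, manifestPath, row.names = FALSE)
  invisible(tab)
}
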