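# Shared fixtures. Everything is generated in code; the memoised patient
# avoids regenerating the default-geometry phantom in every test file.

.fixtureEnv <- new.env(parent = emptyenv())

# one noise-free patient on the default 64 x 64 x 8 grid
noiseFreePatient <- function() {
  if (is.null(.fixtureEnv$nf)) {
    spec <- cohortSpec(nTotal = 5, nIA = 5, nIV = 0, seed = 424,
                      noiseSigma = 0)
    .fixtureEnv$nf <- list(spec = spec, patient = genPatient(spec, 1))
  }
  .fixtureEnv$nf
}

# a single-voxel ground truth embedded in a tiny grid, for forward-model
# oracles
tinyTruth <- function(cbf = 0.6, mtt = 4, tmax = 4, dt = 1.8,
                      noise = 0) {
  d <- c(2, 2, 1)
  z <- array(0, d)
  cbfA <- z; cbfA[1, 1, 1] <- cbf
  mttA <- z; mttA[1, 1, 1] <- mtt
  tmaxA <- z; tmaxA[1, 1, 1] <- tmax
  new("PhantomTruth", cbf = cbfA, cbv = cbfA * mttA, mtt = mttA,
      tmax = tmaxA, lesion = z > 1, baseHU = z + 35,
      aif = aifModel(), riseTau = 3, noiseSigma = noise,
      spacing = c(3, 3, 5), dt = dt)
}

# Spearman rho from the rank formula (no ties): 1 - 6*sum(d^2)/(n(n^2-1))
spearmanOracle <- function(x, y) {
  d <- rank(x) - rank(y)
  1 - 6 * sum(d^2) / (length(x) * (length(x)^2 - 1))
}
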