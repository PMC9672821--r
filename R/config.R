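## Experiment configuration: YAML round-trip and hashing. Every source of
## randomness is a named seed; no hidden global state.

#' Build an experiment configuration
#'
#' @param cohort named list of [cohortSpec()] arguments.
#' @param models model roster.
#' @param arms treatment arms.
#' @param padShape in-slice pad shape.
#' @param nFolds folds per arm.
#' @param unetDepth,baseFilters UNet trunk setting.
#' @param maxEpochs,batchSize training budget.
#' @param seeds named list: `cohort`, `folds`, `training`, `undersampling`.
#' @return list of class `experimentConfig`.
#' @export
experimentConfig <- function(cohort = list(), models = c("tmax", "param_unet"),
                             arms = "IA", padShape = c(96, 64), nFolds = 5L,
                             unetDepth = 4L, baseFilters = 64L,
                             maxEpochs = 500L, batchSize = 8L,
                             seeds = list(cohort = 1L, folds = 2024L,
                                          training = 7L, undersampling = 37L)) {
  need <- c("cohort", "folds", "training", "undersampling")
  if (!all(need %in% names(seeds)))
    stop("seeds must name: ", paste(need, collapse = ", "))
  structure(list(cohort = cohort, models = models, arms = arms,
                 padShape = padShape, nFolds = nFolds, unetDepth = unetDepth,
                 baseFilters = baseFilters, maxEpochs = maxEpochs,
                 batchSize = batchSize, seeds = seeds),
            class = "experimentConfig")
}

#' Read / write experiment configurations as YAML
#'
#' @param path YAML file.
#' @export
readExperimentConfig <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(experimentConfig, y)
}

#' @rdname readExperimentConfig
#' @param cfg an `experimentConfig`.
#' @export
writeExperimentConfig <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Stable hash of a configuration (or any R object)
#'
#' MD5 of the canonical serialisation; stamped on experiment artifacts so
#' outputs can be traced to the configuration that produced them.
#'
#' @param x object to hash.
#' @return hex string.
#' @export
configHash <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(x, f, version = 2, compress = FALSE)
  unname(tools::md5sum(f))
}

#' Run an experiment from a configuration object
#'
#' @param cfg an `experimentConfig` (or path to its YAML).
#' @param outDir output directory for metrics CSVs.
#' @param verbose progress messages.
#' @export
runConfiguredExperiment <- function(cfg, outDir = NULL, verbose = TRUE) {
  if (is.character(cfg)) cfg <- readExperimentConfig(cfg)
  spec <- do.call(cohortSpec, c(cfg$cohort, list(seed = cfg$seeds$cohort)))
  runExperiment(spec, models = cfg$models, arms = cfg$arms,
                padShape = cfg$padShape, nFolds = cfg$nFolds,
                unetDepth = cfg$unetDepth, baseFilters = cfg$baseFilters,
                trainCfg = trainConfig(maxEpochs = cfg$maxEpochs,
                                       batchSize = cfg$batchSize,
                                       seed = cfg$seeds$training),
                foldSeed = cfg$seeds$folds, rdfSeed = cfg$seeds$undersampling,
                outDir = outDir, verbose = verbose)
}
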