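#' @include AllClasses.R io.R metrics.R thresholds.R performance.R fixtures.R
NULL

#' Pipeline run configuration
#'
#' Bundles everything one train-freeze-validate run needs: input tables
#' (paths or in-memory records), the model and pacing settings, the
#' uncertainty-quantification and evaluation sizes, seeds and output
#' locations.
#'
#' @param training drug table path or list of [DrugRecord-class]
#' @param validation optional second table evaluated with the frozen
#'   thresholds
#' @param cellResponses optional per-cell response table (path or data
#'   frame) used to bootstrap Hill parameters
#' @param sampleDir optional directory of precomputed per-drug parameter
#'   sample files (`<drug>.csv`), passed through unchanged
#' @param modelId registered model id
#' @param cycleLength,nBeats,stimAmplitude,stimDuration pacing overrides
#' @param multiples concentration multiples of Cmax
#' @param nUqSamples joint parameter samples per drug (default 2000)
#' @param nEvalIters panel resampling iterations (default 10000)
#' @param hergCv coefficient of variation of the synthetic hERG-parameter
#'   sampling used when no precomputed samples are given
#' @param seed master integer seed; stage seeds are derived from it
#' @param outDir artifact directory (created if needed); `NULL` disables
#'   writing
#' @param datasetId label recorded in every artifact
#' @return a `torsadeRunConfig` list
#' @export
runConfig <- function(training, validation = NULL, cellResponses = NULL,
                      sampleDir = NULL, modelId = "toy",
                      cycleLength = 2000, nBeats = 1000,
                      stimAmplitude = -80, stimDuration = 0.5,
                      multiples = 1:4, nUqSamples = 2000,
                      nEvalIters = 10000, hergCv = 0.15, seed = 1,
                      outDir = NULL, datasetId = "dataset") {
  stopifnot(nUqSamples >= 1, nEvalIters >= 1, seed >= 0, seed < 2^31)
  structure(list(training = training, validation = validation,
                 cellResponses = cellResponses, sampleDir = sampleDir,
                 modelId = modelId,
                 protocol = pacingProtocol(cycleLength, nBeats,
                                           stimAmplitude, stimDuration),
                 multiples = multiples, nUqSamples = nUqSamples,
                 nEvalIters = nEvalIters, hergCv = hergCv,
                 seed = as.integer(seed), outDir = outDir,
                 datasetId = datasetId),
            class = "torsadeRunConfig")
}

.asDrugList <- function(x) {
  if (is.character(x)) readDrugTable(x)
  else if (all(vapply(x, is, TRUE, "DrugRecord"))) x
  else stop("training/validation must be a CSV path or a list of DrugRecord",
            call. = FALSE)
}

.configHash <- function(config) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  ## hash the scientific settings only, not output locations
  cfg <- config[setdiff(names(config), c("training", "validation",
                                         "cellResponses", "outDir"))]
  cfg$protocol <- list(cl = cfg$protocol@cycleLength,
                       n = cfg$protocol@nBeats,
                       amp = cfg$protocol@stimAmplitude,
                       dur = cfg$protocol@stimDuration)
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, force = TRUE)
  unname(tools::md5sum(f))
}

## joint samples for one drug: precomputed file > bootstrap > synthetic jitter
.samplesForDrug <- function(drug, config, responses, seed) {
  if (!is.null(config$sampleDir)) {
    f <- file.path(config$sampleDir, paste0(drug@name, ".csv"))
    if (file.exists(f)) {
      pre <- readSampleSet(f)
      return(assembleSampleSet(drug, n = min(config$nUqSamples,
                                             nrow(pre@samples)),
                               precomputed = pre@samples))
    }
  }
  blockSamples <- list()
  if (!is.null(responses)) {
    sub <- responses[responses$drug == drug@name, , drop = FALSE]
    for (cur in unique(sub$current)) {
      d <- sub[sub$current == cur, c("cell_id", "conc_nM", "frac_block")]
      blockSamples[[cur]] <- bootstrapHillSamples(
        d, config$nUqSamples, seed = seed + match(cur, .blockableCurrents),
        current = cur)
    }
  }
  hergSamples <- generateHergSamples(drug@herg, config$nUqSamples,
                                     cv = config$hergCv, seed = seed + 101)
  assembleSampleSet(drug, hergSamples, blockSamples,
                    n = config$nUqSamples, seed = seed + 202)
}

.scorePanel <- function(drugs, config, responses, seedBase) {
  lapply(seq_along(drugs), function(i) {
    ss <- .samplesForDrug(drugs[[i]], config, responses,
                          seed = seedBase + 1000L * i)
    scoreDistributionFromSamples(ss, modelId = config$modelId,
                                 protocol = config$protocol,
                                 multiples = config$multiples)
  })
}

#' Run the train-freeze-validate pipeline
#'
#' Computes torsade-metric-score distributions for the training drugs,
#' fits the two ordinal-regression thresholds on them, freezes those
#' thresholds, scores the validation drugs and evaluates every
#' prespecified performance measure against the frozen thresholds. When
#' validation drugs lack risk labels the label-dependent measures are
#' skipped with a warning; scores and classifications are still
#' produced. All artifacts (scores, thresholds, report) are written to
#' `config$outDir` together with the config hash and seeds.
#'
#' @param config a [runConfig()] object
#' @return list with elements `trainingScores`, `thresholds`,
#'   `validationScores`, `classification` (per-drug category fractions),
#'   `report` (a [PerformanceReport-class] or `NULL`), `configHash`
#' @export
runPipeline <- function(config) {
  stopifnot(inherits(config, "torsadeRunConfig"))
  training <- .asDrugList(config$training)
  responses <- if (is.character(config$cellResponses))
    readCellResponses(config$cellResponses) else config$cellResponses
  hash <- .configHash(config)

  trainScores <- .scorePanel(training, config, responses,
                             seedBase = config$seed)
  th <- fitOrdinalThresholds(trainScores)

  validation <- if (!is.null(config$validation))
    .asDrugList(config$validation)
  valScores <- NULL; report <- NULL; classification <- NULL
  if (!is.null(validation)) {
    valScores <- .scorePanel(validation, config, responses,
                             seedBase = config$seed + 500000L)
    classification <- t(vapply(valScores, categoryFractions, numeric(3),
                               th = th))
    rownames(classification) <- vapply(valScores, drugName, "")
    labs <- vapply(valScores, riskLabel, "")
    if (anyNA(labs)) {
      warning("validation drugs lack risk labels; ",
              "label-dependent measures skipped")
    } else {
      report <- evaluatePerformance(valScores, th,
                                    nIter = config$nEvalIters,
                                    seed = config$seed + 900000L,
                                    datasetId = config$datasetId)
      report@meta$configHash <- hash
      report@meta$thresholds <- th
    }
  }

  if (!is.null(config$outDir)) {
    dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
    scoresDf <- do.call(rbind, lapply(c(trainScores, valScores), function(d)
      data.frame(drug = d@drug, risk_label = d@riskLabel,
                 sample_index = seq_along(d@scores),
                 score_uC_per_uF = d@scores, n_failures = d@nFailures)))
    scoresDf$config_hash <- hash
    scoresDf$seed <- config$seed
    utils::write.csv(scoresDf,
                     file.path(config$outDir, "scores.csv"),
                     row.names = FALSE)
    writeThresholds(th, file.path(config$outDir, "thresholds.json"),
                    datasetId = config$datasetId)
    if (!is.null(report))
      writeReport(report, file.path(config$outDir, "report.csv"))
  }

  list(trainingScores = trainScores, thresholds = th,
       validationScores = valScores, classification = classification,
       report = report, configHash = hash)
}
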