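#' @include AllClasses.R AllGenerics.R modelRegistry.R pharmacology.R
NULL

.trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' @rdname qnet
#' @export
setMethod("qnet", "ApTrace", function(trace) {
  miss <- setdiff(.qnetCurrents, colnames(trace@currents))
  if (length(miss))
    stop("trace lacks current series required by qNet: ",
         paste(miss, collapse = ", "), call. = FALSE)
  inet <- rowSums(trace@currents[, .qnetCurrents, drop = FALSE])
  .trapz(trace@time, inet) / 1000  # (uA/uF)*ms -> uC/uF
})

.upstroke <- function(trace) {
  dv <- diff(trace@v) / diff(trace@time)
  i <- which.max(dv)
  list(index = i, time = trace@time[i], maxSlope = dv[i])
}

#' @rdname apd
#' @export
setMethod("apd", "ApTrace", function(trace, level = 90) {
  stopifnot(level %in% c(50, 90))
  if (detectDepolarizationFailure(trace)) {
    out <- NA_real_; attr(out, "failure") <- "depolarization"; return(out)
  }
  up <- .upstroke(trace)
  vpeak <- max(trace@v)
  vrest <- trace@v[1]
  target <- vpeak - level / 100 * (vpeak - vrest)
  tt <- trace@time; v <- trace@v
  ipk <- which.max(v)
  below <- which(v < target & seq_along(v) > ipk)
  if (!length(below)) {
    out <- NA_real_; attr(out, "failure") <- "repolarization"; return(out)
  }
  j <- below[1]
  tcross <- tt[j - 1] + (target - v[j - 1]) * (tt[j] - tt[j - 1]) /
    (v[j] - v[j - 1])
  tcross - up$time
})

#' @rdname diastolicCa
#' @export
setMethod("diastolicCa", "ApTrace", function(trace) min(trace@cai))

#' @rdname detectDepolarizationFailure
#' @export
setMethod("detectDepolarizationFailure", "ApTrace", function(trace)
  max(trace@v) < 0)

#' Per-beat electrophysiological metrics
#'
#' Computes qNet, APD90, APD50 and diastolic calcium for one beat,
#' together with depolarization- and repolarization-failure flags. When
#' either failure occurs the beat is not interpretable and qNet (and the
#' affected APDs) are reported as `NA`.
#'
#' @param trace an [ApTrace-class]
#' @return list with elements `qnet`, `apd90`, `apd50`, `diastolicCa`,
#'   `depolFailure`, `repolFailure`
#' @export
beatMetrics <- function(trace) {
  depol <- detectDepolarizationFailure(trace)
  a90 <- apd(trace, 90)
  a50 <- apd(trace, 50)
  repol <- identical(attr(a90, "failure"), "repolarization") ||
    identical(attr(a50, "failure"), "repolarization")
  list(qnet = if (depol || repol) NA_real_ else qnet(trace),
       apd90 = as.numeric(a90), apd50 = as.numeric(a50),
       diastolicCa = diastolicCa(trace),
       depolFailure = depol, repolFailure = repol)
}

#' Torsade metric score for one joint parameter sample
#'
#' Paces the model to steady state at each concentration multiple of Cmax
#' (default the integers 1-4), computes qNet per concentration and
#' averages. A sample whose simulation fails to depolarize or repolarize
#' at any concentration has an undefined score (`NA`) and the failure is
#' counted; such samples are excluded from the score distribution, with
#' the exclusion count reported prominently.
#'
#' @param drug a [DrugRecord-class]
#' @param exposureAt function(conc) returning the [DrugExposure-class]
#'   for this sample at concentration `conc`; defaults to the record's
#'   point estimates
#' @param modelId registered model id
#' @param protocol a [PacingProtocol-class]
#' @param multiples concentration multiples of Cmax
#' @param control solver settings
#' @param metric which per-beat metric to average: "qnet" (the torsade
#'   metric), "apd90", "apd50", or "diastolicCa" (alternative metrics are
#'   used for comparison studies)
#' @return list with elements `drug`, `score` (uC/uF), `perConcentration`
#'   (named qNet per multiple), `nFailures`
#' @export
torsadeMetricScore <- function(drug, exposureAt = NULL, modelId = "toy",
                               protocol = pacingProtocol(),
                               multiples = 1:4, control = simControl(),
                               metric = "qnet") {
  stopifnot(is(drug, "DrugRecord"), drug@cmax > 0)
  if (is.null(exposureAt))
    exposureAt <- function(conc) exposureFromRecord(drug, conc)
  per <- stats::setNames(rep(NA_real_, length(multiples)),
                         paste0(multiples, "x"))
  nf <- 0L
  for (k in seq_along(multiples)) {
    trace <- runToSteadyState(modelId, protocol,
                              exposureAt(multiples[k] * drug@cmax),
                              control = control)
    m <- beatMetrics(trace)
    if (m$depolFailure || m$repolFailure) nf <- nf + 1L
    per[k] <- switch(metric, qnet = m$qnet, apd90 = m$apd90,
                     apd50 = m$apd50, diastolicCa = m$diastolicCa,
                     stop("unknown metric '", metric, "'"))
  }
  list(drug = drug@name,
       score = if (nf > 0 || anyNA(per)) NA_real_ else mean(per),
       perConcentration = per, nFailures = nf)
}

#' Bootstrap distribution of torsade metric scores for one drug
#'
#' Applies [torsadeMetricScore()] to every joint parameter sample of a
#' [DrugSampleSet-class], excluding samples with simulation failures
#' (counted in `nFailures` of the result).
#'
#' @param sampleSet a [DrugSampleSet-class]
#' @inheritParams torsadeMetricScore
#' @param nSamples number of samples to score (default: all)
#' @return a [ScoreDistribution-class]
#' @export
scoreDistributionFromSamples <- function(sampleSet, modelId = "toy",
                                         protocol = pacingProtocol(),
                                         multiples = 1:4,
                                         control = simControl(),
                                         nSamples = NULL, metric = "qnet") {
  stopifnot(is(sampleSet, "DrugSampleSet"))
  n <- nSamples %||% nrow(sampleSet@samples)
  drug <- drugRecord(sampleSet@drug, sampleSet@cmax,
                     riskLabel = sampleSet@riskLabel)
  vals <- rep(NA_real_, n)
  nf <- 0L
  for (i in seq_len(n)) {
    ts <- torsadeMetricScore(
      drug, exposureAt = function(conc) exposureFromSample(sampleSet, i, conc),
      modelId = modelId, protocol = protocol, multiples = multiples,
      control = control, metric = metric)
    if (is.na(ts$score)) nf <- nf + 1L else vals[i] <- ts$score
  }
  scoreDistribution(sampleSet@drug, vals[!is.na(vals)],
                    sampleSet@riskLabel, nf)
}

#' Export a beat trace to CSV
#'
#' Writes columns `time_ms`, `v_mV`, one column per reported current
#' (uA/uF) and `cai_mM`.
#'
#' @param trace an [ApTrace-class]
#' @param path output file
#' @return `path`, invisibly
#' @export
exportTrace <- function(trace, path) {
  df <- data.frame(time_ms = trace@time, v_mV = trace@v,
                   trace@currents, cai_mM = trace@cai,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
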