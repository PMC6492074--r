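#' @import methods
NULL

## currents that may carry Hill-type conductance block
.blockableCurrents <- c("INaL", "INa", "ICaL", "IKs", "IK1", "Ito")
## currents entering the net charge integral
.qnetCurrents <- c("ICaL", "INaL", "IKr", "IKs", "IK1", "Ito")
## currents every trace must report
.traceCurrents <- c("IKr", "INaL", "ICaL", "INa", "IKs", "IK1", "Ito")
.riskLevels <- c("high", "intermediate", "low")

#' Pacing protocol for a simulated myocyte
#'
#' Defines the periodic stimulation applied to an action-potential model:
#' cycle length, number of paced beats before the reported beat, and the
#' stimulus pulse. Defaults follow standard proarrhythmia-simulation
#' practice: 2000 ms cycle length, a -80 uA/uF, 0.5 ms stimulus, and 1000
#' pre-pacing beats to reach steady state.
#'
#' @slot cycleLength pacing cycle length in ms
#' @slot nBeats number of beats paced before the output beat is recorded
#' @slot stimAmplitude stimulus current amplitude in uA/uF (negative =
#'   depolarizing)
#' @slot stimDuration stimulus duration in ms
#' @export
setClass("PacingProtocol",
         representation(cycleLength = "numeric", nBeats = "numeric",
                        stimAmplitude = "numeric", stimDuration = "numeric"),
         validity = function(object) {
           if (length(object@cycleLength) != 1 || !is.finite(object@cycleLength))
             return("cycleLength must be a single finite number")
           if (object@stimDuration <= 0)
             return("stimDuration must be > 0")
           if (object@cycleLength <= object@stimDuration)
             return("cycleLength must exceed stimDuration")
           if (object@nBeats < 1 || object@nBeats != round(object@nBeats))
             return("nBeats must be a positive integer")
           TRUE
         })

#' @rdname PacingProtocol-class
#' @param cycleLength,nBeats,stimAmplitude,stimDuration see slots
#' @return a `PacingProtocol`
#' @examples
#' pacingProtocol(nBeats = 10)
#' @export
pacingProtocol <- function(cycleLength = 2000, nBeats = 1000,
                           stimAmplitude = -80, stimDuration = 0.5) {
  new("PacingProtocol", cycleLength = as.numeric(cycleLength),
      nBeats = as.numeric(nBeats), stimAmplitude = as.numeric(stimAmplitude),
      stimDuration = as.numeric(stimDuration))
}

#' Five-parameter dynamic drug-hERG interaction
#'
#' The drug-IKr interaction is modelled kinetically rather than as static
#' block: drug associates with the open/inactivated-open channel at a
#' concentration-dependent rate, dissociates slowly, and can become trapped
#' in a closed-bound state in a voltage-dependent manner. The five
#' parameters are the ones measured by the dynamic hERG voltage protocol.
#'
#' @slot kmax dimensionless scale of the maximal binding rate
#' @slot ku unbinding rate constant, 1/ms
#' @slot n Hill-like exponent of the concentration dependence of binding
#' @slot halfmax concentration term (nM^n) at which binding is half maximal
#' @slot vhalf voltage (mV) of half-maximal trapping
#' @export
setClass("HergDynamicParams",
         representation(kmax = "numeric", ku = "numeric", n = "numeric",
                        halfmax = "numeric", vhalf = "numeric"),
         validity = function(object) {
           for (s in c("kmax", "ku", "n", "halfmax", "vhalf"))
             if (length(slot(object, s)) != 1 || is.na(slot(object, s)))
               return(sprintf("slot '%s' must be a single non-missing number", s))
           if (object@kmax < 0 || object@ku < 0)
             return("rate parameters kmax and ku must be >= 0")
           if (object@n <= 0) return("exponent n must be > 0")
           if (object@halfmax <= 0) return("halfmax must be > 0")
           TRUE
         })

#' @rdname HergDynamicParams-class
#' @param kmax,ku,n,halfmax,vhalf see slots
#' @export
hergDynamicParams <- function(kmax, ku, n, halfmax, vhalf) {
  new("HergDynamicParams", kmax = as.numeric(kmax), ku = as.numeric(ku),
      n = as.numeric(n), halfmax = as.numeric(halfmax),
      vhalf = as.numeric(vhalf))
}

#' @rdname HergDynamicParams-class
#' @details `inertHerg()` returns parameters with zero binding, i.e. no
#'   drug-hERG interaction at any concentration.
#' @export
inertHerg <- function() hergDynamicParams(0, 1e-5, 1, 1, -1)

#' Hill-equation block of one ionic current
#'
#' Concentration-response of fractional block for a non-hERG current,
#' parameterised by the half-inhibitory concentration (IC50, nM) and the
#' Hill coefficient. An infinite IC50 encodes "no measurable block".
#'
#' @slot current which current is blocked ("INaL", "INa", "ICaL", and
#'   optionally "IKs", "IK1", "Ito")
#' @slot ic50 half-inhibitory concentration in nM (may be `Inf`)
#' @slot hill Hill coefficient (> 0)
#' @export
setClass("ChannelBlock",
         representation(current = "character", ic50 = "numeric",
                        hill = "numeric"),
         validity = function(object) {
           if (!object@current %in% .blockableCurrents)
             return(sprintf("current must be one of %s",
                            paste(.blockableCurrents, collapse = ", ")))
           if (!(object@ic50 > 0)) return("ic50 must be > 0 (Inf allowed)")
           if (!is.finite(object@hill) || object@hill <= 0)
             return("hill must be a finite number > 0")
           TRUE
         })

#' @rdname ChannelBlock-class
#' @param current,ic50,hill see slots
#' @export
channelBlock <- function(current, ic50, hill = 1) {
  new("ChannelBlock", current = as.character(current),
      ic50 = as.numeric(ic50), hill = as.numeric(hill))
}

#' One drug's pharmacology and risk label
#'
#' Bundles everything the metric needs for one compound: the free
#' therapeutic Cmax, the dynamic hERG interaction, Hill block of the other
#' currents, and (when known) the clinical TdP risk category.
#'
#' @slot name drug identifier
#' @slot cmax maximum free therapeutic plasma concentration, nM
#' @slot herg a [HergDynamicParams-class]
#' @slot blocks list of [ChannelBlock-class], at most one per current
#' @slot riskLabel "high", "intermediate", "low", or `NA`
#' @export
setClass("DrugRecord",
         representation(name = "character", cmax = "numeric",
                        herg = "HergDynamicParams", blocks = "list",
                        riskLabel = "character"),
         validity = function(object) {
           if (!(object@cmax > 0)) return("cmax must be > 0")
           if (!all(vapply(object@blocks, is, TRUE, "ChannelBlock")))
             return("blocks must all be ChannelBlock objects")
           cur <- vapply(object@blocks, function(b) b@current, "")
           if (anyDuplicated(cur))
             return("at most one ChannelBlock per current")
           if (!is.na(object@riskLabel) && !object@riskLabel %in% .riskLevels)
             return("riskLabel must be high/intermediate/low or NA")
           TRUE
         })

#' @rdname DrugRecord-class
#' @param name,cmax,herg,blocks,riskLabel see slots
#' @export
drugRecord <- function(name, cmax, herg = inertHerg(), blocks = list(),
                       riskLabel = NA_character_) {
  new("DrugRecord", name = as.character(name), cmax = as.numeric(cmax),
      herg = herg, blocks = blocks, riskLabel = as.character(riskLabel))
}

#' A drug exposure used for a single simulation
#'
#' One joint parameter sample (hERG dynamics plus Hill blocks) together
#' with the free concentration at which the myocyte is exposed. A zero
#' concentration is the null exposure and must reproduce the drug-free
#' simulation exactly.
#'
#' @slot herg a [HergDynamicParams-class]
#' @slot blocks list of [ChannelBlock-class]
#' @slot concentration free drug concentration, nM (>= 0)
#' @export
setClass("DrugExposure",
         representation(herg = "HergDynamicParams", blocks = "list",
                        concentration = "numeric"),
         validity = function(object) {
           if (object@concentration < 0)
             return("concentration must be >= 0")
           if (!all(vapply(object@blocks, is, TRUE, "ChannelBlock")))
             return("blocks must all be ChannelBlock objects")
           TRUE
         })

#' @rdname DrugExposure-class
#' @param herg,blocks,concentration see slots
#' @export
drugExposure <- function(herg = inertHerg(), blocks = list(),
                         concentration = 0) {
  new("DrugExposure", herg = herg, blocks = blocks,
      concentration = as.numeric(concentration))
}

#' @rdname DrugExposure-class
#' @details `noDrug()` is the drug-free exposure.
#' @export
noDrug <- function() drugExposure()

#' One paced beat of a simulated action potential
#'
#' Time series over exactly one pacing cycle: membrane potential, the seven
#' reported ionic currents, and intracellular (myoplasmic) calcium.
#'
#' @slot time time grid, ms, strictly increasing, starting at the stimulus
#' @slot v membrane potential, mV
#' @slot currents numeric matrix, one column per current
#'   (IKr, INaL, ICaL, INa, IKs, IK1, Ito), uA/uF
#' @slot cai intracellular calcium, mM
#' @slot diagnostics list of solver/convergence diagnostics
#' @export
setClass("ApTrace",
         representation(time = "numeric", v = "numeric",
                        currents = "matrix", cai = "numeric",
                        diagnostics = "list"),
         validity = function(object) {
           n <- length(object@time)
           if (n < 2 || any(diff(object@time) <= 0))
             return("time must be strictly increasing with >= 2 points")
           if (length(object@v) != n || length(object@cai) != n)
             return("v and cai must have the same length as time")
           if (nrow(object@currents) != n)
             return("currents must have one row per time point")
           miss <- setdiff(.traceCurrents, colnames(object@currents))
           if (length(miss))
             return(paste("missing current columns:",
                          paste(miss, collapse = ", ")))
           TRUE
         })

apTrace <- function(time, v, currents, cai, diagnostics = list()) {
  new("ApTrace", time = time, v = v, currents = currents, cai = cai,
      diagnostics = diagnostics)
}

#' Joint bootstrap parameter samples for one drug
#'
#' An ordered collection of joint (hERG dynamics, Hill block) parameter
#' samples used to propagate in vitro measurement uncertainty into the
#' torsade metric score. Stored as a data frame with one row per sample;
#' columns `kmax, ku, n, halfmax, vhalf` plus `<current>_ic50` /
#' `<current>_hill` pairs.
#'
#' @slot drug drug name
#' @slot cmax free Cmax, nM
#' @slot samples data.frame of parameter samples
#' @slot riskLabel risk category or NA
#' @export
setClass("DrugSampleSet",
         representation(drug = "character", cmax = "numeric",
                        samples = "data.frame", riskLabel = "character"),
         validity = function(object) {
           req <- c("kmax", "ku", "n", "halfmax", "vhalf")
           miss <- setdiff(req, names(object@samples))
           if (length(miss))
             return(paste("sample columns missing:", paste(miss, collapse = ", ")))
           if (nrow(object@samples) < 1) return("samples must be nonempty")
           TRUE
         })

drugSampleSet <- function(drug, cmax, samples, riskLabel = NA_character_) {
  new("DrugSampleSet", drug = drug, cmax = as.numeric(cmax),
      samples = samples, riskLabel = as.character(riskLabel))
}

#' Distribution of torsade metric scores for one drug
#'
#' The bootstrap distribution (default 2000 values) of the torsade metric
#' score, in uC/uF, with the drug's risk label when known. Lower scores
#' indicate higher predicted TdP risk.
#'
#' @slot drug drug name
#' @slot scores numeric vector of finite scores, uC/uF
#' @slot riskLabel "high", "intermediate", "low" or NA
#' @slot nFailures number of bootstrap samples excluded because a
#'   simulation showed depolarization/repolarization failure
#' @export
setClass("ScoreDistribution",
         representation(drug = "character", scores = "numeric",
                        riskLabel = "character", nFailures = "numeric"),
         validity = function(object) {
           if (length(object@scores) < 1) return("scores must be nonempty")
           if (!all(is.finite(object@scores)))
             return("scores must all be finite")
           if (!is.na(object@riskLabel) && !object@riskLabel %in% .riskLevels)
             return("riskLabel must be high/intermediate/low or NA")
           TRUE
         })

#' @rdname ScoreDistribution-class
#' @param drug,scores,riskLabel,nFailures see slots
#' @export
scoreDistribution <- function(drug, scores, riskLabel = NA_character_,
                              nFailures = 0) {
  new("ScoreDistribution", drug = as.character(drug),
      scores = as.numeric(scores), riskLabel = as.character(riskLabel),
      nFailures = as.numeric(nFailures))
}

#' The two ordinal-regression risk thresholds
#'
#' Cut points on the torsade-metric-score axis. Because lower scores mean
#' higher risk, threshold 2 (high vs intermediate-or-low) lies below
#' threshold 1 (low vs intermediate-or-high).
#'
#' @slot t1 threshold separating low from intermediate/high risk, uC/uF
#' @slot t2 threshold separating high from intermediate/low risk, uC/uF
#' @slot fit list of fit diagnostics (slope, cut points, convergence)
#' @export
setClass("Thresholds",
         representation(t1 = "numeric", t2 = "numeric", fit = "list"),
         validity = function(object) {
           if (!is.finite(object@t1) || !is.finite(object@t2))
             return("thresholds must be finite")
           if (!(object@t2 < object@t1))
             return("t2 must be < t1 (lower score = higher risk)")
           TRUE
         })

#' @rdname Thresholds-class
#' @param t1,t2,fit see slots
#' @export
thresholds <- function(t1, t2, fit = list()) {
  new("Thresholds", t1 = as.numeric(t1), t2 = as.numeric(t2), fit = fit)
}

#' Prespecified performance measures with resampling CIs
#'
#' One row per measure (`auc_roc1`, `auc_roc2`, `pairwise_correct`,
#' `lr_pos_t1`, `lr_neg_t1`, `lr_pos_t2`, `lr_neg_t2`,
#' `mean_class_error`): median and 2.5/97.5 percentile of the measure
#' across resampled drug panels.
#'
#' @slot measures data.frame with columns measure, median, ci_low, ci_high,
#'   n_resamples
#' @slot meta list: dataset id, seed, notes
#' @export
setClass("PerformanceReport",
         representation(measures = "data.frame", meta = "list"),
         validity = function(object) {
           req <- c("measure", "median", "ci_low", "ci_high", "n_resamples")
           miss <- setdiff(req, names(object@measures))
           if (length(miss))
             return(paste("measure columns missing:", paste(miss, collapse = ", ")))
           bad <- with(object@measures, ci_low > median | median > ci_high)
           if (any(bad, na.rm = TRUE))
             return("each measure must satisfy ci_low <= median <= ci_high")
           TRUE
         })

performanceReport <- function(measures, meta = list()) {
  new("PerformanceReport", measures = measures, meta = meta)
}

## ---- show methods -------------------------------------------------------

setMethod("show", "PacingProtocol", function(object) {
  cat(sprintf("PacingProtocol: CL %g ms, %g beat(s), stimulus %g uA/uF x %g ms\n",
              object@cycleLength, object@nBeats, object@stimAmplitude,
              object@stimDuration))
})

setMethod("show", "DrugRecord", function(object) {
  cur <- vapply(object@blocks, function(b)
    sprintf("%s(IC50=%.4g nM, h=%.3g)", b@current, b@ic50, b@hill), "")
  cat(sprintf("DrugRecord '%s': Cmax %g nM, risk %s\n", object@name,
              object@cmax, object@riskLabel))
  cat(sprintf("  hERG: kmax=%.4g ku=%.4g n=%.3g halfmax=%.4g vhalf=%.3g\n",
              object@herg@kmax, object@herg@ku, object@herg@n,
              object@herg@halfmax, object@herg@vhalf))
  if (length(cur)) cat("  block:", paste(cur, collapse = ", "), "\n")
})

setMethod("show", "ApTrace", function(object) {
  cat(sprintf("ApTrace: %d points over %g ms, V in [%.1f, %.1f] mV\n",
              length(object@time), diff(range(object@time)),
              min(object@v), max(object@v)))
})

setMethod("show", "ScoreDistribution", function(object) {
  q <- stats::quantile(object@scores, c(0.025, 0.5, 0.975))
  cat(sprintf(
    "ScoreDistribution '%s' (%s): n=%d, median %.4f [%.4f, %.4f] uC/uF, %d failure(s)\n",
    object@drug, object@riskLabel, length(object@scores), q[2], q[1], q[3],
    object@nFailures))
})

setMethod("show", "Thresholds", function(object) {
  cat(sprintf("Thresholds: t1 = %.4f, t2 = %.4f uC/uF (score < t2: high; > t1: low)\n",
              object@t1, object@t2))
})

setMethod("show", "PerformanceReport", function(object) {
  cat("PerformanceReport\n")
  print(object@measures, row.names = FALSE, digits = 4)
})

setMethod("show", "DrugSampleSet", function(object) {
  cat(sprintf("DrugSampleSet '%s': %d samples, Cmax %g nM\n",
              object@drug, nrow(object@samples), object@cmax))
})
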