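#' @include AllClasses.R
NULL

#' Net charge carried over one beat (qNet)
#'
#' Integrates the net current Inet = ICaL + INaL + IKr + IKs + IK1 + Ito
#' over one paced beat by the trapezoidal rule on the trace's own time
#' grid. Inet is in uA/uF and time in ms, so the integral divided by 1000
#' is in uC/uF.
#'
#' @param trace an [ApTrace-class]
#' @return qNet in uC/uF
#' @export
setGeneric("qnet", function(trace) standardGeneric("qnet"))

#' Action potential duration at a repolarization level
#'
#' Time from the maximum upstroke velocity (max dV/dt) to the point where
#' the membrane potential first crosses peak minus `level`% of the AP
#' amplitude, with linear interpolation between samples.
#'
#' @param trace an [ApTrace-class]
#' @param level repolarization percentage, typically 50 or 90
#' @return duration in ms; `NA` with a failure attribute when the beat
#'   shows depolarization failure (no upstroke) or repolarization failure
#'   (no crossing before the end of the beat)
#' @export
setGeneric("apd", function(trace, level = 90) standardGeneric("apd"))

#' Diastolic intracellular calcium
#'
#' Minimum myoplasmic calcium concentration over the beat.
#'
#' @param trace an [ApTrace-class]
#' @return concentration in mM
#' @export
setGeneric("diastolicCa", function(trace) standardGeneric("diastolicCa"))

#' Detect depolarization failure
#'
#' A beat fails to depolarize when the post-stimulus peak membrane
#' potential never exceeds 0 mV, which cleanly separates full action
#' potentials from stimulus artifacts.
#'
#' @param trace an [ApTrace-class]
#' @return logical flag
#' @export
setGeneric("detectDepolarizationFailure",
           function(trace) standardGeneric("detectDepolarizationFailure"))

## ---- small accessors ----------------------------------------------------

#' Accessors for torsadeRisk objects
#'
#' Slot access for the package's S4 classes: trace components, score
#' vectors, risk labels, threshold values and the measure table of a
#' performance report.
#'
#' @param object an object of the documented classes
#' @param name for `traceCurrent`, one of IKr, INaL, ICaL, INa, IKs, IK1,
#'   Ito
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setGeneric("membranePotential",
           function(object) standardGeneric("membranePotential"))
#' @rdname accessors
#' @export
setGeneric("traceCurrent", function(object, name) standardGeneric("traceCurrent"))
#' @rdname accessors
#' @export
setGeneric("intracellularCa", function(object) standardGeneric("intracellularCa"))
#' @rdname accessors
#' @export
setGeneric("scores", function(object) standardGeneric("scores"))
#' @rdname accessors
#' @export
setGeneric("riskLabel", function(object) standardGeneric("riskLabel"))
#' @rdname accessors
#' @export
setGeneric("drugName", function(object) standardGeneric("drugName"))
#' @rdname accessors
#' @export
setGeneric("threshold1", function(object) standardGeneric("threshold1"))
#' @rdname accessors
#' @export
setGeneric("threshold2", function(object) standardGeneric("threshold2"))
#' @rdname accessors
#' @export
setGeneric("reportMeasures", function(object) standardGeneric("reportMeasures"))

#' @rdname accessors
#' @export
setMethod("traceTime", "ApTrace", function(object) object@time)
#' @rdname accessors
#' @export
setMethod("membranePotential", "ApTrace", function(object) object@v)
#' @rdname accessors
#' @export
setMethod("traceCurrent", "ApTrace", function(object, name) {
  if (!name %in% colnames(object@currents))
    stop("no current series '", name, "' in trace", call. = FALSE)
  object@currents[, name]
})
#' @rdname accessors
#' @export
setMethod("intracellularCa", "ApTrace", function(object) object@cai)
#' @rdname accessors
#' @export
setMethod("scores", "ScoreDistribution", function(object) object@scores)
#' @rdname accessors
#' @export
setMethod("riskLabel", "ScoreDistribution", function(object) object@riskLabel)
#' @rdname accessors
#' @export
setMethod("riskLabel", "DrugRecord", function(object) object@riskLabel)
#' @rdname accessors
#' @export
setMethod("drugName", "ScoreDistribution", function(object) object@drug)
#' @rdname accessors
#' @export
setMethod("drugName", "DrugRecord", function(object) object@name)
#' @rdname accessors
#' @export
setMethod("threshold1", "Thresholds", function(object) object@t1)
#' @rdname accessors
#' @export
setMethod("threshold2", "Thresholds", function(object) object@t2)
#' @rdname accessors
#' @export
setMethod("reportMeasures", "PerformanceReport", function(object) object@measures)
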