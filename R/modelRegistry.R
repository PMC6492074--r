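#' @include AllClasses.R
NULL

.modelRegistry <- new.env(parent = emptyenv())

.configError <- function(msg) {
  stop(structure(class = c("torsadeConfigError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

.simulationError <- function(msg, drug = NA_character_, concentration = NA_real_) {
  stop(structure(class = c("torsadeSimulationError", "error", "condition"),
                 list(message = sprintf("%s [drug=%s, conc=%g nM]", msg, drug,
                                        concentration),
                      call = sys.call(-1), drug = drug,
                      concentration = concentration)))
}

#' Register an action-potential model
#'
#' The metric, uncertainty-quantification and statistics layers are
#' model-agnostic: any model that can (i) provide an initial state,
#' (ii) pace a state forward a number of beats and (iii) produce an
#' [ApTrace-class] for one beat can be plugged in. The package registers
#' two models on load: `"cipaordv1.0"` (the compiled ventricular myocyte
#' model) and `"toy"` (a three-variable analytic caricature for fast
#' pipeline testing).
#'
#' @param id model identifier string
#' @param model a list with function elements `initialState()`,
#'   `runBeats(state, n, protocol, exposure, control)` and
#'   `beatTrace(state, protocol, exposure, control)` (the latter returning
#'   `list(trace =, state =)`)
#' @return `id`, invisibly
#' @export
registerApModel <- function(id, model) {
  stopifnot(is.character(id), length(id) == 1,
            is.function(model$initialState), is.function(model$runBeats),
            is.function(model$beatTrace))
  assign(id, model, envir = .modelRegistry)
  invisible(id)
}

#' @rdname registerApModel
#' @export
registeredApModels <- function() ls(.modelRegistry)

.getModel <- function(id) {
  if (!is.character(id) || length(id) != 1 || !exists(id, .modelRegistry))
    .configError(sprintf("unknown model id '%s'; registered: %s",
                         paste(id, collapse = ","),
                         paste(ls(.modelRegistry), collapse = ", ")))
  get(id, .modelRegistry)
}

#' Solver and output settings for a simulation
#'
#' Relative/absolute tolerances for the stiff solver, the output sampling
#' step of the reported beat, and the solver step cap. The defaults
#' (rtol 1e-6, atol 1e-8) keep qNet stable to well under 0.1% when
#' tolerances are refined further.
#'
#' @param rtol relative tolerance
#' @param atol absolute tolerance
#' @param outputDt output sampling interval of the reported beat, ms
#' @param maxsteps solver step cap per beat
#' @return list of settings
#' @export
simControl <- function(rtol = 1e-6, atol = 1e-8, outputDt = 0.5,
                       maxsteps = 1e5) {
  list(rtol = rtol, atol = atol, outputDt = outputDt, maxsteps = maxsteps)
}

#' Initial state of a registered model
#'
#' @param modelId a registered model identifier ("cipaordv1.0" or "toy")
#' @return named numeric vector of state variables
#' @examples
#' initialState("toy")
#' @export
initialState <- function(modelId) .getModel(modelId)$initialState()

#' Simulate a paced myocyte and return the output beat
#'
#' Paces the model for `protocol@nBeats` beats under a drug exposure and
#' returns the trace of the final beat. Drug effects enter only through
#' the dynamic hERG submodel parameters and static conductance scaling of
#' the other currents.
#'
#' @param modelId registered model id
#' @param protocol a [PacingProtocol-class]
#' @param exposure a [DrugExposure-class]; `noDrug()` for control
#' @param state optional starting state (default: the model's initial
#'   state)
#' @param control solver settings from [simControl()]
#' @return an [ApTrace-class] for the output beat
#' @export
simulatePaced <- function(modelId, protocol = pacingProtocol(),
                          exposure = noDrug(), state = NULL,
                          control = simControl()) {
  model <- .getModel(modelId)
  validObject(protocol); validObject(exposure)
  if (is.null(state)) state <- model$initialState()
  if (protocol@nBeats > 1)
    state <- model$runBeats(state, protocol@nBeats - 1, protocol, exposure,
                            control)
  model$beatTrace(state, protocol, exposure, control)$trace
}

#' Pace to steady state and report a convergence diagnostic
#'
#' Like [simulatePaced()] but additionally measures how settled the
#' preparation is: the maximum relative change of any state variable
#' between the starts of the last two beats is stored in the trace's
#' `diagnostics$convergence`.
#'
#' @inheritParams simulatePaced
#' @return an [ApTrace-class]; `diagnostics(trace)$convergence` holds the
#'   max relative state change between the last two beats
#' @export
runToSteadyState <- function(modelId, protocol = pacingProtocol(),
                             exposure = noDrug(), state = NULL,
                             control = simControl()) {
  model <- .getModel(modelId)
  validObject(protocol); validObject(exposure)
  if (is.null(state)) state <- model$initialState()
  if (protocol@nBeats > 1)
    state <- model$runBeats(state, protocol@nBeats - 1, protocol, exposure,
                            control)
  res <- model$beatTrace(state, protocol, exposure, control)
  conv <- max(abs(res$state - state) / (abs(state) + control$atol))
  trace <- res$trace
  trace@diagnostics$convergence <- conv
  trace
}

#' @rdname accessors
#' @export
traceDiagnostics <- function(object) object@diagnostics
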