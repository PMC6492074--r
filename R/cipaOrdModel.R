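#' @include modelRegistry.R pharmacology.R
NULL

## state layout must match src/cipaord.c
.cipaStateNames <- c(
  "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
  "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
  "a", "iF", "iS", "ap", "iFp", "iSp",
  "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
  "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt",
  "IC1", "IC2", "C1", "C2", "O", "IO", "IObound", "Obound", "Cbound")

.hergStateNames <- c("IC1", "IC2", "C1", "C2", "O", "IO",
                     "IObound", "Obound", "Cbound")

.cipaInitialState <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "cipaordv1_steady_cl2000.txt",
                          package = "torsadeRisk", mustWork = TRUE)
      tab <- utils::read.table(path, header = FALSE,
                               col.names = c("state", "value"),
                               stringsAsFactors = FALSE)
      st <- stats::setNames(tab$value, tab$state)
      if (!identical(names(st), .cipaStateNames))
        .configError("initial-condition file does not match the model state layout")
      cache <<- st
    }
    cache
  }
})

## map a DrugExposure to the compiled model's parameter vector
.cipaParms <- function(protocol, exposure) {
  frac <- stats::setNames(numeric(length(.blockableCurrents)),
                          .blockableCurrents)
  for (b in exposure@blocks)
    frac[b@current] <- hillBlockFraction(exposure@concentration, b)
  h <- exposure@herg
  c(conc = exposure@concentration, kmax = h@kmax, ku = h@ku, npow = h@n,
    halfmax = h@halfmax, vhalf = h@vhalf,
    bNaL = unname(frac["INaL"]), bNa = unname(frac["INa"]),
    bCaL = unname(frac["ICaL"]), bKs = unname(frac["IKs"]),
    bK1 = unname(frac["IK1"]), bto = unname(frac["Ito"]))
}

.cipaSolve <- function(state, times, parms, control, context) {
  out <- tryCatch(
    deSolve::lsoda(state, times = times, func = "cipaord_derivs",
                   dllname = "torsadeRisk", initfunc = "cipaord_initmod",
                   parms = parms, nout = 7, outnames = .traceCurrents,
                   rtol = control$rtol, atol = control$atol,
                   maxsteps = control$maxsteps),
    warning = function(w) w, error = function(e) e)
  if (inherits(out, "condition"))
    .simulationError(paste("stiff solver failed:", conditionMessage(out)),
                     context$drug, context$conc)
  if (nrow(out) < length(times) || anyNA(out[nrow(out), ]))
    .simulationError("stiff solver did not reach the end of the beat",
                     context$drug, context$conc)
  out
}

.makeCipaOrdModel <- function() {
  runBeats <- function(state, n, protocol, exposure, control) {
    cl <- protocol@cycleLength
    parms <- c(.cipaParms(protocol, exposure),
               stim_amp = protocol@stimAmplitude,
               stim_dur = protocol@stimDuration, cl = cl)
    ctx <- list(drug = "exposure", conc = exposure@concentration)
    ## restart the solver at every stimulus so the pulse is never stepped
    ## over; coarse output points, accuracy is set by the tolerances
    times <- c(0, protocol@stimDuration, cl / 2, cl)
    for (b in seq_len(n)) {
      out <- .cipaSolve(state, times, parms, control, ctx)
      state <- out[nrow(out), 1 + seq_along(.cipaStateNames)]
      names(state) <- .cipaStateNames
    }
    state
  }
  beatTrace <- function(state, protocol, exposure, control) {
    cl <- protocol@cycleLength
    parms <- c(.cipaParms(protocol, exposure),
               stim_amp = protocol@stimAmplitude,
               stim_dur = protocol@stimDuration, cl = cl)
    ctx <- list(drug = "exposure", conc = exposure@concentration)
    times <- unique(sort(c(seq(0, cl, by = control$outputDt),
                           protocol@stimDuration, cl)))
    out <- .cipaSolve(state, times, parms, control, ctx)
    newState <- out[nrow(out), 1 + seq_along(.cipaStateNames)]
    names(newState) <- .cipaStateNames
    trace <- apTrace(
      time = out[, "time"], v = out[, "v"],
      currents = out[, .traceCurrents, drop = FALSE],
      cai = out[, "cai"],
      diagnostics = list(model = "cipaordv1.0",
                         occupancySumRange =
                           range(rowSums(out[, .hergStateNames]))))
    list(trace = trace, state = newState)
  }
  list(initialState = .cipaInitialState, runBeats = runBeats,
       beatTrace = beatTrace)
}
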