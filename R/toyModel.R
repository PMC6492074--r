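#' @include modelRegistry.R pharmacology.R
NULL

## Analytic three-variable AP caricature. Everything is closed-form so a
## beat "simulates" in well under a millisecond, and the qNet response to
## hERG-binding potency is provably monotone (see toyQnet below).
.toyPar <- list(
  vrest = -85, vpeak = 35, apd0 = 300, tup = 1, dt = 1,
  gKr = 0.12, gKs = 0.02, gTo = 0.01, gNaL = 0.04, gCaL = 0.05, gK1 = 0.03,
  iNaAmp = 40, stimChargeMin = 20, naBlockFailure = 0.9,
  caiDia = 1e-4, caiAmp = 1.4e-4, caiTau = 150)

## equilibrium bound fraction of the toy hERG site and its relaxation rate
.toyBinding <- function(herg, conc) {
  if (conc <= 0 || herg@kmax <= 0)
    return(list(bstar = 0, rate = herg@ku))
  x <- conc^herg@n / (conc^herg@n + herg@halfmax)
  kon <- herg@kmax * herg@ku * x
  list(bstar = kon / (kon + herg@ku), rate = kon + herg@ku)
}

.toyBlockFractions <- function(exposure) {
  frac <- stats::setNames(numeric(length(.blockableCurrents)),
                          .blockableCurrents)
  for (b in exposure@blocks)
    frac[b@current] <- hillBlockFraction(exposure@concentration, b)
  frac
}

.toyApd <- function(b) .toyPar$apd0 * (1 + 0.5 * b)

#' Closed-form qNet of the toy model
#'
#' The toy beat has piecewise-linear current waveforms whose integrals are
#' known exactly: plateau currents run from the upstroke for one AP
#' duration, the inward-rectifier runs over the remaining diastole. With
#' bound fraction `b` and blocked fractions `f`, the net charge is
#' \deqn{qNet = [gKr(1-b) + gKs(1-f_{Ks}) + gto(1-f_{to}) - gNaL(1-f_{NaL})
#'   - gCaL(1-f_{CaL})](APD - dt)/1000 + gK1(1-f_{K1})(CL - APD - tup - dt)/1000}
#' Its derivative in `b` is `-gKr*APD + (S - gK1)*0.5*apd0` (per 1000 ms)
#' with `S` the plateau sum; the chosen conductances keep both terms
#' negative for all b in \[0,1\], so qNet strictly decreases with binding.
#'
#' @param b bound fraction of the hERG site in \[0,1\]
#' @param frac named vector of blocked fractions per current (as produced
#'   from a [DrugExposure-class])
#' @param cycleLength pacing cycle length, ms
#' @return qNet in uC/uF
#' @export
toyQnet <- function(b, frac = NULL, cycleLength = 2000) {
  p <- .toyPar
  if (is.null(frac))
    frac <- stats::setNames(numeric(length(.blockableCurrents)),
                            .blockableCurrents)
  tEnd <- min(p$tup + .toyApd(b), cycleLength)
  S <- p$gKr * (1 - b) + p$gKs * (1 - frac["IKs"]) +
    p$gTo * (1 - frac["Ito"]) - p$gNaL * (1 - frac["INaL"]) -
    p$gCaL * (1 - frac["ICaL"])
  dia <- max(cycleLength - tEnd, 0)
  unname(S * max(tEnd - p$tup - p$dt, 0) / 1000 +
           p$gK1 * (1 - frac["IK1"]) * max(dia - p$dt, 0) / 1000)
}

## waveform with value amp strictly inside (from, to) and one-grid-step
## ramps at both ends; trapezoidal integral is exactly amp*(to - from - dt)
.rampWave <- function(tt, from, to, amp) {
  w <- numeric(length(tt))
  dt <- .toyPar$dt
  if (to - from < 2 * dt) return(w)
  w[tt > from & tt < to] <- amp
  w[tt == from | tt == to] <- 0
  ramp <- tt > from & tt < from + dt
  w
}

.makeToyModel <- function() {
  p <- .toyPar
  initialState <- function() c(v = p$vrest, w = 0, b = 0)
  advanceB <- function(state, nBeats, protocol, exposure) {
    bd <- .toyBinding(exposure@herg, exposure@concentration)
    b0 <- state[["b"]]
    bd$bstar + (b0 - bd$bstar) * exp(-nBeats * protocol@cycleLength * bd$rate)
  }
  runBeats <- function(state, n, protocol, exposure, control) {
    state[["b"]] <- advanceB(state, n, protocol, exposure)
    state[["v"]] <- p$vrest
    state
  }
  beatTrace <- function(state, protocol, exposure, control) {
    cl <- protocol@cycleLength
    b <- advanceB(state, 1, protocol, exposure)
    frac <- .toyBlockFractions(exposure)
    tt <- seq(0, cl, by = p$dt)
    fires <- abs(protocol@stimAmplitude) * protocol@stimDuration >=
      p$stimChargeMin && (1 - frac[["INa"]]) > (1 - p$naBlockFailure)
    v <- rep(p$vrest, length(tt))
    cur <- matrix(0, length(tt), length(.traceCurrents),
                  dimnames = list(NULL, .traceCurrents))
    cai <- rep(p$caiDia, length(tt))
    if (fires) {
      apd <- .toyApd(b)
      tEnd <- min(p$tup + apd, cl)  # AP may outlast the cycle
      up <- tt >= p$tup & tt <= tEnd
      v[up] <- p$vpeak - (p$vpeak - p$vrest) * (tt[up] - p$tup) / apd
      v[tt < p$tup] <- p$vrest + (p$vpeak - p$vrest) * tt[tt < p$tup] / p$tup
      cur[, "IKr"] <- .rampWave(tt, p$tup, tEnd, p$gKr * (1 - b))
      cur[, "IKs"] <- .rampWave(tt, p$tup, tEnd,
                                p$gKs * (1 - frac[["IKs"]]))
      cur[, "Ito"] <- .rampWave(tt, p$tup, tEnd,
                                p$gTo * (1 - frac[["Ito"]]))
      cur[, "INaL"] <- .rampWave(tt, p$tup, tEnd,
                                 -p$gNaL * (1 - frac[["INaL"]]))
      cur[, "ICaL"] <- .rampWave(tt, p$tup, tEnd,
                                 -p$gCaL * (1 - frac[["ICaL"]]))
      cur[, "IK1"] <- .rampWave(tt, tEnd, cl,
                                p$gK1 * (1 - frac[["IK1"]]))
      cur[tt <= p$tup + 1 & tt >= p$tup, "INa"] <-
        -p$iNaAmp * (1 - frac[["INa"]])
      decay <- tt >= p$tup
      cai[decay] <- p$caiDia + p$caiAmp * (1 - frac[["ICaL"]]) *
        exp(-(tt[decay] - p$tup) / p$caiTau)
    } else if (abs(protocol@stimAmplitude) > 0) {
      ## stimulus artifact only: sub-threshold bump during the pulse
      bump <- min(abs(protocol@stimAmplitude) * protocol@stimDuration,
                  p$stimChargeMin - 1)
      inStim <- tt <= max(protocol@stimDuration, p$dt) & tt > 0
      v[inStim] <- p$vrest + bump
    }
    trace <- apTrace(time = tt, v = v, currents = cur, cai = cai,
                     diagnostics = list(model = "toy", boundFraction = b,
                                        fires = fires))
    state[["b"]] <- b
    state[["v"]] <- p$vrest
    list(trace = trace, state = state)
  }
  list(initialState = initialState, runBeats = runBeats,
       beatTrace = beatTrace)
}

#' Register the toy action-potential model
#'
#' The toy model is a three-variable caricature of a paced ventricular
#' beat (membrane potential, a placeholder gate and the bound fraction of
#' a hERG-like site). Its waveforms are piecewise linear, a beat is
#' constructed analytically in under a millisecond, binding relaxes
#' geometrically to its equilibrium, and qNet is available in closed form
#' ([toyQnet()]) and strictly decreases with hERG-binding potency. It is
#' registered automatically on package load; this function re-registers
#' it (e.g. after tampering with the registry) and returns the model id.
#'
#' @return the model id `"toy"`, invisibly
#' @examples
#' makeToyModel()
#' trace <- simulatePaced("toy", pacingProtocol(nBeats = 2))
#' qnet(trace)
#' @export
makeToyModel <- function() registerApModel("toy", .makeToyModel())
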