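# in-code fixtures shared across test files

# an ApTrace with fully controlled content; currents default to zero
makeTrace <- function(time = seq(0, 2000, by = 1), v = NULL, cai = NULL,
                      ...) {
  n <- length(time)
  cur <- matrix(0, n, 7,
                dimnames = list(NULL, c("IKr", "INaL", "ICaL", "INa",
                                        "IKs", "IK1", "Ito")))
  over <- list(...)
  for (nm in names(over)) cur[, nm] <- over[[nm]]
  if (is.null(v)) v <- rep(-85, n)
  if (is.null(cai)) cai <- rep(1e-4, n)
  new("ApTrace", time = time, v = v, currents = cur, cai = cai,
      diagnostics = list())
}

# a triangular action potential: 1 ms upstroke to vpeak, linear decay of
# the given duration back to rest, then flat diastole
triangleTrace <- function(vpeak = 40, vrest = -85, decay = 400,
                          cl = 2000) {
  tt <- seq(0, cl, by = 1)
  v <- rep(vrest, length(tt))
  v[tt >= 1 & tt <= 1 + decay] <-
    vpeak - (vpeak - vrest) * (tt[tt >= 1 & tt <= 1 + decay] - 1) / decay
  v[tt == 1] <- vpeak
  makeTrace(time = tt, v = v)
}

# point-mass score distribution
pointDist <- function(drug, value, label, n = 50)
  scoreDistribution(drug, rep(value, n), label)

# a cleanly separated three-category panel of point masses
separatedPanel <- function(nPer = 2, vals = c(high = 0.02,
                                              intermediate = 0.06,
                                              low = 0.10)) {
  out <- list()
  for (cat in names(vals))
    for (k in seq_len(nPer))
      out[[length(out) + 1]] <- pointDist(paste0(cat, k), vals[[cat]], cat)
  out
}

# trapezoidal integration of the empirical ROC curve: the independent
# oracle for the pair-counting AUC (positives = lower scores)
trapezoidRocAuc <- function(score, positive) {
  cuts <- c(-Inf, sort(unique(score)), Inf)
  sens <- vapply(cuts, function(c) mean(score[positive] <= c), 0)
  fpr <- vapply(cuts, function(c) mean(score[!positive] <= c), 0)
  sum(diff(fpr) * (sens[-1] + sens[-length(sens)]) / 2)
}

cipaRest <- function() initialState("cipaordv1.0")

# a graded, fast-binding hERG-only exposure for the compiled model
# (kmax = 2 gives ~40-65% equilibrium occupancy over 30-300 nM, keeping
# the AP valid; pass a large kmax to stress-test near-total IKr loss)
hergOnlyExposure <- function(conc, kmax = 2, ku = 5e-4) {
  drugExposure(hergDynamicParams(kmax = kmax, ku = ku, n = 1,
                                 halfmax = 50, vhalf = -10),
               list(), conc)
}
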