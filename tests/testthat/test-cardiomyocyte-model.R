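# paced myocyte model: state sanity, conservation laws, drug-null
# equivalence, solver self-consistency and mechanistic failure modes

test_that("initial states are physiological and registry errors are typed", {
  toy <- initialState("toy")
  expect_named(toy, c("v", "w", "b"))
  expect_equal(unname(toy["b"]), 0)

  st <- cipaRest()
  herg <- c("IC1", "IC2", "C1", "C2", "O", "IO", "IObound", "Obound",
            "Cbound")
  expect_equal(sum(st[herg]), 1, tolerance = 1e-6)
  expect_true(all(st[herg] >= -1e-12))
  expect_true(all(st[c("nai", "ki", "cai", "cansr", "cajsr")] > 0))
  expect_true(st["v"] < -80 && st["v"] > -95)

  expect_error(initialState("no-such-model"), class = "torsadeConfigError")
  expect_error(simulatePaced("no-such-model"), class = "torsadeConfigError")
})

test_that("hERG Markov occupancies stay conserved during drugged pacing", {
  tr <- simulatePaced("cipaordv1.0", pacingProtocol(nBeats = 3),
                      hergOnlyExposure(100, kmax = 1e4), state = cipaRest())
  rng <- traceDiagnostics(tr)$occupancySumRange
  expect_lt(max(abs(rng - 1)), 1e-6)
})

test_that("zero-concentration exposure reproduces the drug-free trace exactly", {
  pr <- pacingProtocol(nBeats = 2)
  free <- simulatePaced("cipaordv1.0", pr, noDrug(), state = cipaRest())
  null <- simulatePaced("cipaordv1.0", pr, hergOnlyExposure(0),
                        state = cipaRest())
  expect_identical(membranePotential(free), membranePotential(null))
  expect_identical(traceCurrent(free, "IKr"), traceCurrent(null, "IKr"))
  expect_identical(intracellularCa(free), intracellularCa(null))

  # and the same holds for the toy model
  t1 <- simulatePaced("toy", pacingProtocol(nBeats = 2), noDrug())
  t2 <- simulatePaced("toy", pacingProtocol(nBeats = 2),
                      drugExposure(hergDynamicParams(5, 0.01, 1, 100, -50),
                                   list(channelBlock("INaL", 500)), 0))
  expect_identical(membranePotential(t1), membranePotential(t2))
  expect_identical(t1@currents, t2@currents)
})

test_that("an unstimulated myocyte rests: < 1 mV drift over one cycle", {
  pr <- pacingProtocol(nBeats = 1, stimAmplitude = 0)
  tr <- simulatePaced("cipaordv1.0", pr, state = cipaRest())
  expect_lt(diff(range(membranePotential(tr))), 1)
})

test_that("qNet is stable under tolerance refinement and extra pacing", {
  pr <- pacingProtocol(nBeats = 10)
  st <- cipaRest()
  q0 <- qnet(simulatePaced("cipaordv1.0", pr, state = st))
  qTight <- qnet(simulatePaced("cipaordv1.0", pr, state = st,
                               control = simControl(rtol = 5e-7,
                                                    atol = 5e-9)))
  expect_lt(abs(qTight - q0) / abs(q0), 1e-3)

  qMore <- qnet(simulatePaced("cipaordv1.0", pacingProtocol(nBeats = 20),
                              state = st))
  expect_lt(abs(qMore - q0) / abs(q0), 1e-3)
})

test_that("steady-state convergence diagnostic is reported and small", {
  tr <- runToSteadyState("cipaordv1.0", pacingProtocol(nBeats = 3),
                         state = cipaRest())
  expect_lt(traceDiagnostics(tr)$convergence, 1e-4)
})

test_that("increasing pure hERG binding never shortens APD90 nor raises qNet", {
  st <- cipaRest()
  pr <- pacingProtocol(nBeats = 40)
  concs <- c(0, 30, 100, 300)
  res <- lapply(concs, function(cc) {
    tr <- simulatePaced("cipaordv1.0", pr, hergOnlyExposure(cc), state = st)
    list(apd90 = as.numeric(apd(tr, 90)), qnet = qnet(tr))
  })
  apds <- vapply(res, `[[`, 0, "apd90")
  qn <- vapply(res, `[[`, 0, "qnet")
  expect_true(all(diff(apds) >= -1e-6))
  expect_true(all(diff(qn) <= 1e-9))
})

test_that("near-total INa block causes depolarization failure", {
  exp_na <- drugExposure(inertHerg(),
                         list(channelBlock("INa", ic50 = 1, hill = 1)),
                         concentration = 1e6)  # ~100% block
  tr <- simulatePaced("cipaordv1.0", pacingProtocol(nBeats = 3), exp_na,
                      state = cipaRest())
  expect_true(detectDepolarizationFailure(tr))
  m <- beatMetrics(tr)
  expect_true(m$depolFailure)
  expect_true(is.na(m$qnet))
})

test_that("trace export writes the documented CSV columns", {
  tr <- simulatePaced("toy", pacingProtocol(nBeats = 1))
  f <- withr::local_tempfile(fileext = ".csv")
  exportTrace(tr, f)
  df <- read.csv(f)
  expect_identical(names(df)[1:2], c("time_ms", "v_mV"))
  expect_true(all(c("IKr", "INaL", "ICaL", "cai_mM") %in% names(df)))
  expect_equal(df$v_mV, membranePotential(tr))
})
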