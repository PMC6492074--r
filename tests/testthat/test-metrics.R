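# per-beat metrics: qNet integration, APD, diastolic calcium, failures

test_that("qNet closed forms: zero currents and constant net current", {
  expect_equal(qnet(makeTrace()), 0)
  tr <- makeTrace(IKr = rep(0.03, 2001))   # 0.03 uA/uF for 2000 ms
  expect_equal(qnet(tr), 0.06, tolerance = 1e-12)
})

test_that("qNet matches fine-grid quadrature on piecewise-linear traces", {
  set.seed(21)
  tt <- sort(c(0, 2000, runif(60, 0, 2000)))
  mk <- function() approx(c(0, runif(8, 0, 2000), 2000),
                          rnorm(10, 0, 0.5), xout = tt)$y
  cur <- list(IKr = mk(), INaL = mk(), ICaL = mk(), IKs = mk(),
              IK1 = mk(), Ito = mk())
  tr <- do.call(makeTrace, c(list(time = tt), cur))
  # oracle: trapezoid on a grid refined 50x; exact for piecewise-linear
  # integrands sampled at their own breakpoints
  fine <- sort(unique(c(tt, seq(0, 2000, length.out = 100001))))
  inetF <- rowSums(vapply(cur, function(y) approx(tt, y, xout = fine)$y,
                          fine))
  oracle <- sum(diff(fine) * (inetF[-1] + inetF[-length(inetF)]) / 2) / 1000
  expect_equal(qnet(tr), oracle, tolerance = 1e-9)
})

test_that("qNet is additive over any partition of the beat", {
  tr <- simulatePaced("toy", pacingProtocol(nBeats = 2))
  tt <- traceTime(tr)
  cut <- sample(2:(length(tt) - 1), 1)
  left <- new("ApTrace", time = tt[1:cut], v = tr@v[1:cut],
              currents = tr@currents[1:cut, ], cai = tr@cai[1:cut],
              diagnostics = list())
  right <- new("ApTrace", time = tt[cut:length(tt)], v = tr@v[cut:length(tt)],
               currents = tr@currents[cut:length(tt), ],
               cai = tr@cai[cut:length(tt)], diagnostics = list())
  expect_equal(qnet(left) + qnet(right), qnet(tr), tolerance = 1e-12)
})

test_that("qNet refuses traces missing a required current", {
  tr <- makeTrace()
  colnames(tr@currents)[colnames(tr@currents) == "IKs"] <- "IKx"
  expect_error(qnet(tr), "IKs")
})

test_that("APD of an idealized square pulse equals its width", {
  tt <- seq(0, 1000, by = 1)
  v <- ifelse(tt >= 10 & tt < 10 + 250, 30, -85)
  tr <- makeTrace(time = tt, v = v)
  expect_equal(as.numeric(apd(tr, 90)), 250, tolerance = 1.01)
  expect_equal(as.numeric(apd(tr, 50)), 250, tolerance = 1.01)
})

test_that("triangular AP crossings match the analytic times", {
  tr <- triangleTrace(vpeak = 40, vrest = -85, decay = 400)
  # decay from +40 at t=1 over 400 ms; level crossings at 1 + f*400
  expect_equal(as.numeric(apd(tr, 90)), 1 + 0.9 * 400, tolerance = 1.01)
  expect_equal(as.numeric(apd(tr, 50)), 1 + 0.5 * 400, tolerance = 1.01)
})

test_that("flat and unrepolarized traces raise the right failure flags", {
  flat <- makeTrace()
  expect_true(detectDepolarizationFailure(flat))
  expect_true(is.na(apd(flat, 90)))
  expect_identical(attr(apd(flat, 90), "failure"), "depolarization")

  tt <- seq(0, 500, by = 1)
  stuck <- makeTrace(time = tt, v = c(-85, rep(30, length(tt) - 1)))
  a <- apd(stuck, 90)
  expect_identical(attr(a, "failure"), "repolarization")
  m <- beatMetrics(stuck)
  expect_true(m$repolFailure)
  expect_true(is.na(m$qnet))
})

test_that("normal APs are not flagged and APD50 <= APD90 on simulations", {
  expect_false(detectDepolarizationFailure(triangleTrace()))
  for (mult in c(0, 1, 4)) {
    e <- drugExposure(hergDynamicParams(2, 0.01, 1, 100, -50), list(),
                      100 * mult)
    tr <- simulatePaced("toy", pacingProtocol(nBeats = 30), e)
    m <- beatMetrics(tr)
    expect_lte(m$apd50, m$apd90)
  }
  trC <- simulatePaced("cipaordv1.0", pacingProtocol(nBeats = 2),
                       state = cipaRest())
  mC <- beatMetrics(trC)
  expect_lte(mC$apd50, mC$apd90)
})

test_that("diastolic calcium: constant, decaying, and simulated beats", {
  expect_equal(diastolicCa(makeTrace(cai = rep(1e-4, 2001))), 1e-4)
  tt <- seq(0, 100, 1)
  dec <- makeTrace(time = tt, cai = 5e-4 * exp(-tt / 30))
  expect_equal(diastolicCa(dec), 5e-4 * exp(-100 / 30))
  trC <- simulatePaced("cipaordv1.0", pacingProtocol(nBeats = 2),
                       state = cipaRest())
  expect_gt(diastolicCa(trC), 1e-5)
  expect_lt(diastolicCa(trC), 5e-4)
})

test_that("torsade metric score is the mean over concentration multiples", {
  drug <- drugRecord("null", cmax = 500)   # inert: no block, inert hERG
  pr <- pacingProtocol(nBeats = 3)
  ts <- torsadeMetricScore(drug, modelId = "toy", protocol = pr)
  q0 <- qnet(simulatePaced("toy", pr))
  expect_equal(unname(ts$perConcentration), rep(q0, 4))
  expect_equal(ts$score, q0)
  expect_equal(ts$score, mean(ts$perConcentration))
})
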