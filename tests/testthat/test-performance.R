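# resampled ranking and classification performance measures

test_that("panel draws are reproducible and distributed like the source", {
  pan <- separatedPanel()
  expect_identical(drawPanel(pan, seed = 4), drawPanel(pan, seed = 4))
  expect_equal(unname(drawPanel(pan)),
               vapply(pan, function(d) d@scores[1], 0))  # point masses

  set.seed(9)
  src <- scoreDistribution("d", rnorm(400, 0.06, 0.01), "low")
  draws <- replicate(10000, drawPanel(list(src)))
  ks <- suppressWarnings(ks.test(draws, src@scores))
  expect_lt(unname(ks$statistic), 0.03)
})

test_that("pair-counting AUC matches its closed forms", {
  expect_equal(rocAuc(c(0.01, 0.02, 0.08, 0.09),
                      c(TRUE, TRUE, FALSE, FALSE)), 1)
  expect_equal(rocAuc(rep(0.05, 6), rep(c(TRUE, FALSE), 3)), 0.5)
  expect_equal(rocAuc(c(0.03, 0.07, 0.05, 0.09),
                      c(TRUE, TRUE, FALSE, FALSE)), 0.75)
  expect_error(rocAuc(1:3, rep(TRUE, 3)),
               class = "torsadeUndefinedMeasure")
})

test_that("pair counting equals the trapezoidal ROC oracle on random panels", {
  set.seed(42)
  for (i in 1:120) {
    n <- sample(4:30, 1)
    score <- round(rnorm(n, 0.06, 0.02), sample(2:4, 1))  # force some ties
    pos <- runif(n) < 0.5
    if (all(pos) || !any(pos)) pos[1:2] <- c(TRUE, FALSE)
    expect_equal(rocAuc(score, pos), trapezoidRocAuc(score, pos),
                 tolerance = 1e-12)
  }
})

test_that("label swap maps AUC to its complement", {
  set.seed(14)
  for (i in 1:30) {
    score <- rnorm(12, 0.06, 0.02)
    pos <- runif(12) < 0.5
    if (all(pos) || !any(pos)) pos[1:2] <- c(TRUE, FALSE)
    expect_equal(rocAuc(score, pos), 1 - rocAuc(score, !pos),
                 tolerance = 1e-12)
  }
})

test_that("ROC analyses on separated point masses are perfect", {
  pan <- separatedPanel()
  r1 <- rocAnalysis(pan, "roc1", nIter = 50, seed = 1)
  expect_equal(c(r1$median, r1$ci_low, r1$ci_high), c(1, 1, 1))
  r2 <- rocAnalysis(pan, "roc2", nIter = 50, seed = 1)
  expect_equal(r2$median, 1)
  onlyLow <- Filter(function(d) riskLabel(d) == "low", pan)
  expect_error(rocAnalysis(onlyLow, "roc1", 10),
               class = "torsadeUndefinedMeasure")
})

test_that("pairwise comparison matches hand enumeration and reversals", {
  pan <- list(pointDist("h", 0.02, "high"),
              pointDist("i", 0.06, "intermediate"),
              pointDist("l", 0.10, "low"))
  pc <- pairwiseCorrectRate(pan, nIter = 20, seed = 3)
  expect_equal(pc$median, 1)   # all 3 ordered pairs concordant

  rev <- list(pointDist("h", 0.10, "high"),
              pointDist("i", 0.06, "intermediate"),
              pointDist("l", 0.02, "low"))
  expect_equal(pairwiseCorrectRate(rev, nIter = 20, seed = 3)$median, 0)

  # one discordant pair out of three: 2/3, plus a tie counts one half
  mix <- list(pointDist("h", 0.06, "high"),
              pointDist("i", 0.02, "intermediate"),
              pointDist("l", 0.10, "low"))
  expect_equal(pairwiseCorrectRate(mix, nIter = 20, seed = 3)$median, 2 / 3)
  tie <- list(pointDist("h", 0.06, "high"),
              pointDist("i", 0.06, "intermediate"),
              pointDist("l", 0.10, "low"))
  expect_equal(pairwiseCorrectRate(tie, nIter = 20, seed = 3)$median,
               (0.5 + 1 + 1) / 3)
})

test_that("likelihood ratios reproduce closed forms and protection magnitudes", {
  th <- thresholds(t1 = 0.07, t2 = 0.05)
  # sens 0.8 (4 of 5 positives below t1), spec 0.8 (4 of 5 negatives above)
  pan <- c(lapply(1:4, function(k) pointDist(paste0("p", k), 0.06, "high")),
           list(pointDist("p5", 0.08, "high")),
           lapply(1:4, function(k) pointDist(paste0("n", k), 0.09, "low")),
           list(pointDist("n5", 0.06, "low")))
  lr <- likelihoodRatios(pan, th, "t1", nIter = 10, seed = 1)
  expect_equal(lr$median[lr$measure == "lr_pos_t1"], 0.8 / 0.2)
  expect_equal(lr$median[lr$measure == "lr_neg_t1"], 0.2 / 0.8)

  # sens 0.75, spec 1: LR+ hits the 1e-6 protection: 7.5e5
  pan2 <- c(lapply(1:3, function(k) pointDist(paste0("p", k), 0.06, "high")),
            list(pointDist("p4", 0.08, "high")),
            lapply(1:4, function(k) pointDist(paste0("n", k), 0.09, "low")))
  lr2 <- likelihoodRatios(pan2, th, "t1", nIter = 10, seed = 1)
  expect_equal(lr2$median[lr2$measure == "lr_pos_t1"], 7.5e5)

  # sens 1, spec 0.885 (177/200): LR- = 1e-6 / 0.885 = 1.13e-6
  pan3 <- c(lapply(1:4, function(k) pointDist(paste0("p", k), 0.06, "high")),
            lapply(1:177, function(k) pointDist(paste0("n", k), 0.09, "low")),
            lapply(1:23, function(k) pointDist(paste0("m", k), 0.06, "low")))
  lr3 <- likelihoodRatios(pan3, th, "t1", nIter = 5, seed = 1)
  expect_equal(lr3$median[lr3$measure == "lr_neg_t1"], 1e-6 / 0.885,
               tolerance = 1e-9)
})

test_that("mean classification error: exact cases and the Gaussian oracle", {
  th <- thresholds(t1 = 0.07, t2 = 0.05)
  perfect <- separatedPanel(nPer = 2, vals = c(high = 0.03,
                                               intermediate = 0.06,
                                               low = 0.09))
  mce <- meanClassificationError(perfect, th, nIter = 30, seed = 6)
  expect_equal(mce$median, 0)

  # 16 drugs, one with 75% off-category mass: error 0.75/16
  set.seed(10)
  pan16 <- c(lapply(1:15, function(k)
    pointDist(paste0("d", k), 0.06, "intermediate")),
    list(scoreDistribution("odd", c(rep(0.08, 1500), rep(0.06, 500)),
                           "intermediate")))
  mce16 <- meanClassificationError(pan16, th, nIter = 4000, seed = 7)
  expect_lt(abs(mce16$median - 0.75 / 16), 0.002)

  # Gaussian synthetic panel: error matches normal tail masses
  pan <- generateScorePanel(nDrugs = c(high = 4, intermediate = 4, low = 4),
                            nSamples = 500, seed = 17)
  ana <- mean(vapply(pan, function(d) {
    mu <- c(high = 0.025, intermediate = 0.058, low = 0.078)[riskLabel(d)]
    sd <- c(high = 0.008, intermediate = 0.006, low = 0.004)[riskLabel(d)]
    switch(riskLabel(d),
           high = 1 - pnorm(th@t2, mu, sd),
           intermediate = pnorm(th@t2, mu, sd) + 1 - pnorm(th@t1, mu, sd),
           low = pnorm(th@t1, mu, sd))
  }, 0))
  # the resampling median centres on the empirical off-mass of the 500
  # stored samples per drug, which sits within finite-sample error of
  # the analytic tail mass
  mceG <- meanClassificationError(pan, th, nIter = 4000, seed = 8)
  expect_lt(abs(mceG$median - ana), 0.015)
})

test_that("measure medians are stable when the iteration count grows 10x", {
  pan <- generateScorePanel(nDrugs = c(high = 3, intermediate = 3, low = 3),
                            nSamples = 300, seed = 23)
  a <- rocAnalysis(pan, "roc1", nIter = 300, seed = 1)
  b <- rocAnalysis(pan, "roc1", nIter = 3000, seed = 2)
  expect_lt(abs(a$median - b$median), 0.03)
  expect_true(a$ci_low <= a$median && a$median <= a$ci_high)
})

test_that("the assembled report carries every prespecified measure", {
  pan <- generateScorePanel(nDrugs = c(high = 2, intermediate = 2, low = 2),
                            nSamples = 200, seed = 3)
  th <- fitOrdinalThresholds(pan)
  rep <- evaluatePerformance(pan, th, nIter = 200, seed = 11,
                             datasetId = "unit")
  m <- reportMeasures(rep)
  expect_setequal(m$measure,
                  c("auc_roc1", "auc_roc2", "pairwise_correct", "lr_pos_t1",
                    "lr_neg_t1", "lr_pos_t2", "lr_neg_t2",
                    "mean_class_error"))
  expect_true(all(m$ci_low <= m$median & m$median <= m$ci_high))
  expect_true(all(m$median[grepl("auc|pairwise", m$measure)] >= 0 &
                    m$median[grepl("auc|pairwise", m$measure)] <= 1))
  expect_true(all(m$median[grepl("lr_", m$measure)] >= 0))
})
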