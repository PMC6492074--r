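# ordinal thresholds, classification and leave-one-out evaluation

test_that("thresholds bracket cleanly separated categories", {
  th <- fitOrdinalThresholds(separatedPanel())
  expect_gt(threshold2(th), 0.02); expect_lt(threshold2(th), 0.06)
  expect_gt(threshold1(th), 0.06); expect_lt(threshold1(th), 0.10)
  expect_lt(threshold2(th), threshold1(th))
})

test_that("a missing category is a typed fit error", {
  pan <- separatedPanel()
  noLow <- Filter(function(d) riskLabel(d) != "low", pan)
  expect_error(fitOrdinalThresholds(noLow), class = "torsadeFitError")
})

test_that("thresholds are scale-equivariant", {
  pan <- generateScorePanel(nDrugs = c(high = 3, intermediate = 3, low = 3),
                            nSamples = 300, seed = 5)
  th <- fitOrdinalThresholds(pan)
  for (c in c(0.5, 3)) {
    sc <- lapply(pan, function(d)
      scoreDistribution(d@drug, d@scores * c, d@riskLabel))
    thc <- fitOrdinalThresholds(sc)
    expect_equal(threshold1(thc), threshold1(th) * c, tolerance = 1e-3)
    expect_equal(threshold2(thc), threshold2(th) * c, tolerance = 1e-3)
  }
})

test_that("thresholds follow the labels, not the drug identities", {
  # symmetric synthetic drugs: permuting which drug carries which label
  # must permute nothing but the labels
  vals <- list(a = 0.02, b = 0.06, c = 0.10)
  mk <- function(assign) {
    mapply(function(nm, lab) pointDist(nm, vals[[nm]], lab),
           names(assign), assign, SIMPLIFY = FALSE)
  }
  th1 <- fitOrdinalThresholds(mk(c(a = "high", b = "intermediate",
                                   c = "low")))
  th2 <- fitOrdinalThresholds(mk(c(c = "low", a = "high",
                                   b = "intermediate")))
  expect_equal(threshold1(th1), threshold1(th2), tolerance = 1e-6)
  expect_equal(threshold2(th1), threshold2(th2), tolerance = 1e-6)
})

test_that("pooled fit weights drugs equally regardless of sample count", {
  pan <- generateScorePanel(nDrugs = c(high = 3, intermediate = 3, low = 3),
                            nSamples = 300, seed = 41)
  ref <- fitOrdinalThresholds(pan)
  # inflate one drug's sample count 20x; weighting keeps it one vote
  pan[[1]] <- scoreDistribution(pan[[1]]@drug,
                                rep(pan[[1]]@scores, 20),
                                pan[[1]]@riskLabel)
  th <- fitOrdinalThresholds(pan)
  expect_equal(threshold1(th), threshold1(ref), tolerance = 1e-4)
  expect_equal(threshold2(th), threshold2(ref), tolerance = 1e-4)
})

test_that("classification respects thresholds and boundary convention", {
  th <- thresholds(t1 = 0.0689, t2 = 0.0579)
  expect_identical(classifyScore(0.05, th), "high")
  expect_identical(classifyScore(0.065, th), "intermediate")
  expect_identical(classifyScore(0.09, th), "low")
  # exact boundary ties go to intermediate
  expect_identical(classifyScore(0.0689, th), "intermediate")
  expect_identical(classifyScore(0.0579, th), "intermediate")
})

test_that("category fractions partition the distribution exactly", {
  th <- thresholds(t1 = 0.07, t2 = 0.05)
  allHigh <- scoreDistribution("h", runif(500, 0.01, 0.049), "high")
  expect_equal(unname(categoryFractions(allHigh, th)), c(1, 0, 0))
  allInt <- scoreDistribution("i", runif(500, 0.0501, 0.0699), "intermediate")
  expect_equal(unname(categoryFractions(allInt, th)), c(0, 1, 0))
  set.seed(8)
  mix <- scoreDistribution("m", c(rnorm(4000, 0.04, 0.004),
                                  rnorm(4000, 0.08, 0.004)), "low")
  fr <- categoryFractions(mix, th)
  expect_equal(sum(fr), 1)
  anaHigh <- 0.5 * (pnorm(0.05, 0.04, 0.004) + pnorm(0.05, 0.08, 0.004))
  expect_equal(unname(fr["high"]), anaHigh, tolerance = 0.02)
})

test_that("leave-one-out cross-validation matches brute-force recomputation", {
  pan <- separatedPanel(nPer = 2)
  rep0 <- looCrossValidate(pan, nIter = 50, seed = 2)
  mce <- reportMeasures(rep0)[reportMeasures(rep0)$measure ==
                                "mean_class_error", ]
  expect_equal(mce$median, 0)

  # one drug entirely in the wrong category contributes its full mass
  # (fixed thresholds: the misplaced drug must not corrupt the fit)
  pan2 <- pan
  pan2[[1]] <- pointDist(pan2[[1]]@drug, 0.10, "high")  # scores like low
  th0 <- thresholds(t1 = 0.08, t2 = 0.04)
  mce2 <- meanClassificationError(pan2, th0, nIter = 50, seed = 2)
  expect_equal(mce2$median, 1 / length(pan2))

  # brute force on an overlapping synthetic panel: expected error equals
  # the mean off-category mass under each drug's own fold thresholds
  pan3 <- generateScorePanel(nDrugs = c(high = 3, intermediate = 3, low = 3),
                             nSamples = 400, seed = 31)
  rep3 <- looCrossValidate(pan3, nIter = 4000, seed = 13)
  folds <- rep3@meta$foldThresholds
  offMass <- mean(vapply(seq_along(pan3), function(i) {
    fr <- categoryFractions(pan3[[i]], folds[[i]])
    1 - fr[[riskLabel(pan3[[i]])]]
  }, 0))
  mce3 <- reportMeasures(rep3)[reportMeasures(rep3)$measure ==
                                 "mean_class_error", ]
  expect_equal(mce3$median, offMass, tolerance = 0.03)
})
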