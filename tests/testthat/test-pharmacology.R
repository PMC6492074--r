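# Hill block, concentration averaging, fitting and bootstrap UQ

test_that("Hill block fraction matches its closed forms", {
  b <- channelBlock("INaL", ic50 = 1000, hill = 2.3)
  expect_equal(hillBlockFraction(1000, b), 0.5)
  expect_equal(hillBlockFraction(0, b), 0)
  expect_equal(hillBlockFraction(4000, channelBlock("INaL", 1000, 1)), 0.8)
  expect_equal(hillBlockFraction(1e9, channelBlock("INaL", Inf, 1)), 0)
})

test_that("Hill block fraction is monotone nondecreasing in concentration", {
  set.seed(11)
  for (i in 1:25) {
    b <- channelBlock("ICaL", ic50 = 10^runif(1, 0, 5),
                      hill = runif(1, 0.2, 5))
    cc <- sort(10^runif(40, -2, 7))
    expect_true(all(diff(hillBlockFraction(cc, b)) >= 0))
  }
})

test_that("mean block over 1-4x Cmax matches a hand-built grid average", {
  cmax <- 750
  b <- channelBlock("INaL", ic50 = cmax, hill = 1)
  grid <- exp(seq(log(cmax), log(4 * cmax), length.out = 10))
  expect_equal(meanBlockOverRange(b, cmax),
               mean(1 / (1 + cmax / grid)), tolerance = 1e-12)
  expect_equal(meanBlockOverRange(channelBlock("INaL", Inf, 1), cmax), 0)
  expect_gt(meanBlockOverRange(channelBlock("INaL", cmax / 1e6, 1), cmax),
            0.999)
  # the 10-point log grid is within 1% of dense quadrature of the
  # closed form over the same range
  dense <- exp(seq(log(cmax), log(4 * cmax), length.out = 20001))
  expect_equal(meanBlockOverRange(b, cmax, nGrid = 2000),
               mean(hillBlockFraction(dense, b)), tolerance = 1e-4)
})

test_that("fitHill recovers exact parameters from noise-free data", {
  truth <- channelBlock("INaL", ic50 = 1000, hill = 1)
  cc <- rep(c(100, 300, 1000, 3000, 10000), 3)
  d <- data.frame(conc = cc, frac = hillBlockFraction(cc, truth))
  fit <- fitHill(d)$block
  expect_equal(fit@ic50, 1000, tolerance = 1e-3)
  expect_equal(fit@hill, 1, tolerance = 1e-3)
})

test_that("fitHill handles degenerate inputs as specified", {
  expect_error(fitHill(data.frame(conc = c(100, 100), frac = c(0.4, 0.5))),
               class = "torsadeFitError")
  z <- fitHill(data.frame(conc = c(100, 1000), frac = c(0, 0)))
  expect_identical(z$block@ic50, Inf)
})

test_that("bootstrap is seeded-deterministic and empty at n = 0", {
  truth <- channelBlock("ICaL", 500, 1.5)
  panel <- generatePatchClampPanel(list(d1 = list(truth)), nCells = 6,
                                   noiseSd = 0.05, seed = 42)
  d <- panel[, c("cell_id", "conc_nM", "frac_block")]
  expect_identical(bootstrapHillSamples(d, 0), list())
  b1 <- bootstrapHillSamples(d, 25, seed = 9, current = "ICaL")
  b2 <- bootstrapHillSamples(d, 25, seed = 9, current = "ICaL")
  expect_identical(vapply(b1, slot, 0, "ic50"), vapply(b2, slot, 0, "ic50"))
  expect_length(b1, 25)
  expect_true(all(vapply(b1, slot, 0, "hill") <= 5))
})

test_that("bootstrap medians converge to the truth as cells grow", {
  truth <- channelBlock("INaL", 800, 1.2)
  err <- vapply(c(4, 16, 64), function(nc) {
    panel <- generatePatchClampPanel(list(d = list(truth)), nCells = nc,
                                     noiseSd = 0.08, seed = 100 + nc)
    d <- panel[, c("cell_id", "conc_nM", "frac_block")]
    bs <- bootstrapHillSamples(d, 60, seed = 5, current = "INaL")
    abs(log(median(vapply(bs, slot, 0, "ic50")) / truth@ic50))
  }, 0)
  expect_lt(err[3], err[1] + 0.05)   # shrinking log-error, noise allowance
  expect_lt(err[3], 0.15)
})

test_that("joint sample assembly pairs channels independently", {
  drug <- drugRecord("x", cmax = 200,
                     herg = hergDynamicParams(2, 0.01, 1, 200, -50),
                     blocks = list(channelBlock("INaL", 400),
                                   channelBlock("ICaL", 900)))
  mkBlocks <- function(cur, seed) {
    set.seed(seed)
    lapply(10^rnorm(500, 3, 0.3), function(ic) channelBlock(cur, ic))
  }
  ss <- assembleSampleSet(drug,
                          blockSamples = list(INaL = mkBlocks("INaL", 1),
                                              ICaL = mkBlocks("ICaL", 2)),
                          n = 2000, seed = 77)
  expect_equal(nrow(ss@samples), 2000)
  r <- cor(log(ss@samples$INaL_ic50), log(ss@samples$ICaL_ic50))
  expect_lt(abs(r), 0.05)
})

test_that("single samples and precomputed tables pass through unchanged", {
  drug <- drugRecord("y", cmax = 100)
  hs <- data.frame(kmax = 3, ku = 0.02, n = 1.1, halfmax = 150, vhalf = -40)
  ss <- assembleSampleSet(drug, hergSamples = hs,
                          blockSamples = list(INaL = list(
                            channelBlock("INaL", 1234, 1.7))),
                          n = 1, seed = 3)
  expect_equal(ss@samples$kmax, 3)
  expect_equal(ss@samples$INaL_ic50, 1234)
  expect_equal(ss@samples$INaL_hill, 1.7)

  pre <- ss@samples
  ss2 <- assembleSampleSet(drug, n = 1, precomputed = pre)
  expect_identical(ss2@samples, pre[1, , drop = FALSE])
  expect_error(assembleSampleSet(drug, n = 5, precomputed = pre), "rows")
})
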