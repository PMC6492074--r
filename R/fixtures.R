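#' @include AllClasses.R pharmacology.R toyModel.R
NULL

#' Synthetic per-cell concentration-response panel
#'
#' Emulates a patch-clamp block-potency experiment: for each drug/current
#' the fractional block at each test concentration follows the true Hill
#' curve plus additive Gaussian noise, truncated to \[0, 1\]. The output
#' uses the same table dialect consumed by [fitHill()] and
#' [readCellResponses()].
#'
#' @param trueBlocks named list (by drug) of lists of
#'   [ChannelBlock-class] giving the generating parameters
#' @param nCells cells per drug/current
#' @param concs test concentrations, nM; default a 5-point log series
#' @param noiseSd additive Gaussian noise SD on the fractional block
#' @param seed integer seed (generation is a pure function of seed and
#'   arguments)
#' @return data.frame with columns drug, current, cell_id, conc_nM,
#'   frac_block
#' @examples
#' tb <- list(drugA = list(channelBlock("INaL", 1000, 1)))
#' head(generatePatchClampPanel(tb, nCells = 3, seed = 1))
#' @export
generatePatchClampPanel <- function(trueBlocks, nCells = 8, concs = NULL,
                                    noiseSd = 0.05, seed = NULL) {
  stopifnot(noiseSd >= 0)
  .withSeed(seed, {
    rows <- list()
    for (drug in names(trueBlocks)) {
      for (blk in trueBlocks[[drug]]) {
        cc <- concs %||% (blk@ic50 * c(0.1, 0.3, 1, 3, 10))
        if (!all(is.finite(cc))) cc <- c(100, 300, 1000, 3000, 10000)
        for (cell in seq_len(nCells)) {
          f <- hillBlockFraction(cc, blk) + stats::rnorm(length(cc), 0, noiseSd)
          rows[[length(rows) + 1]] <- data.frame(
            drug = drug, current = blk@current,
            cell_id = sprintf("%s_%s_c%02d", drug, blk@current, cell),
            conc_nM = cc, frac_block = pmin(pmax(f, 0), 1))
        }
      }
    }
    do.call(rbind, rows)
  })
}

#' Synthetic score panel with known category structure
#'
#' Gaussian torsade-metric-score distributions per drug with
#' category-level means and SDs, so off-category masses and therefore
#' the classification measures have closed forms (normal tail masses)
#' against which the resampling estimators can be checked. Real score
#' distributions are skewed; only the full model path exercises that.
#'
#' @param nDrugs named counts per category (high, intermediate, low);
#'   the defaults are the panel sizes of a 16-drug validation set
#' @param means,sds named per-category score means/SDs, uC/uF; means
#'   must be ordered high < intermediate < low
#' @param nSamples scores per drug
#' @param seed integer seed
#' @return list of [ScoreDistribution-class]
#' @export
generateScorePanel <- function(nDrugs = c(high = 4, intermediate = 7, low = 5),
                               means = c(high = 0.025, intermediate = 0.058,
                                         low = 0.078),
                               sds = c(high = 0.008, intermediate = 0.006,
                                       low = 0.004),
                               nSamples = 2000, seed = NULL) {
  stopifnot(all(sds > 0),
            means[["high"]] < means[["intermediate"]],
            means[["intermediate"]] < means[["low"]])
  .withSeed(seed, {
    out <- list()
    for (cat in .riskLevels) {
      for (k in seq_len(nDrugs[[cat]])) {
        out[[length(out) + 1]] <- scoreDistribution(
          sprintf("synth_%s_%d", cat, k),
          stats::rnorm(nSamples, means[[cat]], sds[[cat]]), cat)
      }
    }
    out
  })
}

#' Synthetic drug panel with known mechanism and risk structure
#'
#' Generates labelled [DrugRecord-class] objects whose parameters are
#' chosen so that, on the toy model, the three categories produce
#' separated but overlapping torsade-metric-score bands: high-risk drugs
#' are strong hERG binders without offsetting block, low-risk drugs are
#' weak binders with protective ICaL block, intermediates sit between.
#' All names are synthetic; this panel emulates the *structure* of a
#' training/validation drug table, not any real compound.
#'
#' @param nPerCategory named counts (high, intermediate, low); defaults
#'   are the category sizes of a 12-drug training set
#' @param seed integer seed
#' @param prefix name prefix for the synthetic drugs
#' @return list of [DrugRecord-class]
#' @export
generateDrugTable <- function(nPerCategory = c(high = 4, intermediate = 4,
                                               low = 4),
                              seed = NULL, prefix = "synth") {
  ## adjacent category ranges touch, so panels overlap at the margins
  ## the way real risk panels do
  kmaxRange <- list(high = c(2.2, 6), intermediate = c(0.7, 2.2),
                    low = c(0.05, 0.7))
  icalMult <- list(high = c(Inf, Inf), intermediate = c(4, 9),
                   low = c(1, 3))
  .withSeed(seed, {
    out <- list()
    for (cat in .riskLevels) {
      for (k in seq_len(nPerCategory[[cat]])) {
        cmax <- exp(stats::runif(1, log(50), log(2000)))
        kmax <- stats::runif(1, kmaxRange[[cat]][1], kmaxRange[[cat]][2])
        herg <- hergDynamicParams(kmax = kmax, ku = 0.005, n = 1,
                                  halfmax = cmax, vhalf = -50)
        im <- icalMult[[cat]]
        ## every drug carries some late-sodium block, independent of its
        ## category: a cross-cutting protective effect that scatters
        ## scores within categories and lets borderline drugs invert
        blocks <- list(channelBlock("INa", 50 * cmax, 1),
                       channelBlock("INaL",
                                    exp(stats::runif(1, log(3), log(30))) *
                                      cmax, 1))
        if (is.finite(im[1]))
          blocks <- c(blocks, channelBlock(
            "ICaL", stats::runif(1, im[1], im[2]) * cmax, 1))
        out[[length(out) + 1]] <- drugRecord(
          sprintf("%s_%s_%d", prefix, cat, k), cmax, herg, blocks, cat)
      }
    }
    out
  })
}

#' Synthetic bootstrap samples of the dynamic hERG parameters
#'
#' Emulates the sampling variability of the five dynamic parameters with
#' multiplicative lognormal noise on the binding-rate scale (kmax) and
#' the potency term (halfmax); the remaining parameters are measured
#' much more precisely and are kept fixed.
#'
#' @param herg a [HergDynamicParams-class] (the truth)
#' @param n number of samples
#' @param cv coefficient of variation of the lognormal noise
#' @param seed integer seed
#' @return data.frame with columns kmax, ku, n, halfmax, vhalf
#' @export
generateHergSamples <- function(herg, n = 2000, cv = 0.15, seed = NULL) {
  sdlog <- sqrt(log(1 + cv^2))
  .withSeed(seed, {
    data.frame(
      kmax = herg@kmax * stats::rlnorm(n, -sdlog^2 / 2, sdlog),
      ku = herg@ku, n = herg@n,
      halfmax = herg@halfmax * stats::rlnorm(n, -sdlog^2 / 2, sdlog),
      vhalf = herg@vhalf)
  })
}
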