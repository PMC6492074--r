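#' @include AllClasses.R
NULL

## run expr with a private, restorable RNG stream
.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.null(seed) && (seed >= 2^31 || seed < 0))
    stop("seed must be a non-negative integer below 2^31", call. = FALSE)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  expr
}

.fitError <- function(msg) {
  stop(structure(class = c("torsadeFitError", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Fractional block of a current from the Hill equation
#'
#' `1 / (1 + (IC50 / C)^h)`: 0 at zero concentration, 0.5 at the IC50,
#' approaching 1 at saturating concentration. The conductance multiplier
#' applied to the current is one minus this fraction. An infinite IC50
#' (the "no measurable block" sentinel) gives 0 at any concentration.
#'
#' @param conc free concentration, nM (vectorised, >= 0)
#' @param block a [ChannelBlock-class], or a numeric IC50 in nM
#' @param hill Hill coefficient, used when `block` is numeric
#' @return fraction blocked in \[0, 1\]
#' @examples
#' hillBlockFraction(1000, channelBlock("INaL", ic50 = 1000)) # 0.5
#' @export
hillBlockFraction <- function(conc, block, hill = 1) {
  if (is(block, "ChannelBlock")) {
    ic50 <- block@ic50; hill <- block@hill
  } else ic50 <- block
  stopifnot(all(conc >= 0))
  out <- numeric(length(conc))
  pos <- conc > 0 & is.finite(ic50)
  out[pos] <- 1 / (1 + (ic50 / conc[pos])^hill)
  out
}

#' Mean fractional block over a concentration range
#'
#' Average of the Hill block fraction over a log-spaced concentration grid
#' spanning a multiple range of Cmax (default 1-4x, 10 grid points), as
#' used to summarise concentration-response curves over the exposure
#' window of the torsade metric.
#'
#' @param block a [ChannelBlock-class]
#' @param cmax free Cmax, nM
#' @param loMult,hiMult lower/upper multiples of Cmax (loMult < hiMult)
#' @param nGrid number of log-spaced grid points
#' @return mean blocked fraction in \[0, 1\]
#' @export
meanBlockOverRange <- function(block, cmax, loMult = 1, hiMult = 4,
                               nGrid = 10) {
  stopifnot(loMult < hiMult, cmax > 0)
  grid <- exp(seq(log(loMult * cmax), log(hiMult * cmax), length.out = nGrid))
  mean(hillBlockFraction(grid, block))
}

#' Fit a Hill concentration-response curve
#'
#' Least-squares fit of `frac_block = 1 / (1 + (IC50 / C)^h)` to per-cell
#' fractional-block measurements for one drug and one current. The IC50 is
#' fitted on the log scale and the Hill coefficient is constrained to
#' (0, 5\]; unconstrained fits on sparse noisy patch-clamp data are
#' unstable. Responses that are all (numerically) zero return the
#' `IC50 = Inf` no-block sentinel.
#'
#' @param data data.frame with columns `conc` (nM, > 0) and `frac`
#'   (fractional block); a `cell` column is carried along for
#'   bootstrapping. Columns named `conc_nM` / `frac_block` / `cell_id`
#'   (the table dialect) are accepted too.
#' @param current current id stored in the returned block
#' @return list with elements `block` (a [ChannelBlock-class]),
#'   `residualSd`, `converged` and `n`
#' @examples
#' d <- data.frame(conc = c(100, 300, 1000, 3000, 10000),
#'                 frac = c(0.09, 0.23, 0.5, 0.75, 0.91))
#' fitHill(d, "INaL")$block
#' @export
fitHill <- function(data, current = "INaL") {
  data <- .normResponseCols(data)
  if (length(unique(data$conc)) < 2)
    .fitError("need responses at >= 2 distinct concentrations to fit a Hill curve")
  if (any(data$conc <= 0)) .fitError("concentrations must be > 0")
  if (all(abs(data$frac) < 1e-3))
    return(list(block = channelBlock(current, Inf, 1), residualSd = 0,
                converged = TRUE, n = nrow(data)))
  ## start IC50 at the concentration closest to half block
  start_ic50 <- data$conc[which.min(abs(data$frac - 0.5))]
  fit <- tryCatch(
    minpack.lm::nlsLM(
      frac ~ 1 / (1 + (10^lic50 / conc)^hill), data = data,
      start = list(lic50 = log10(start_ic50), hill = 1),
      lower = c(lic50 = -6, hill = 1e-3), upper = c(lic50 = 12, hill = 5),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    .fitError(paste("Hill fit did not converge:", conditionMessage(fit)))
  cf <- stats::coef(fit)
  list(block = channelBlock(current, 10^cf[["lic50"]], cf[["hill"]]),
       residualSd = stats::sigma(fit),
       converged = fit$convInfo$isConv %||% TRUE, n = nrow(data))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.normResponseCols <- function(data) {
  nm <- names(data)
  ren <- c(conc_nM = "conc", frac_block = "frac", cell_id = "cell",
           concentration = "conc", fractional_block = "frac")
  for (i in seq_along(ren))
    if (names(ren)[i] %in% nm) names(data)[nm == names(ren)[i]] <- ren[i]
  if (!all(c("conc", "frac") %in% names(data)))
    .fitError("response data must have columns conc/conc_nM and frac/frac_block")
  if (!"cell" %in% names(data)) data$cell <- seq_len(nrow(data))
  data
}

#' Nonparametric bootstrap of Hill parameters
#'
#' Resamples cells with replacement and refits the Hill curve for each
#' replicate, propagating between-cell variability into the (IC50, Hill)
#' estimate. Replicates whose fit fails are redrawn, up to a cap.
#'
#' @inheritParams fitHill
#' @param n number of bootstrap replicates (0 returns an empty list)
#' @param seed integer seed; the same seed reproduces the same output
#' @param maxRedraw redraw cap per replicate before giving up
#' @return list of `n` [ChannelBlock-class] objects
#' @export
bootstrapHillSamples <- function(data, n, seed = NULL, current = "INaL",
                                 maxRedraw = 20) {
  data <- .normResponseCols(data)
  if (n == 0) return(list())
  cells <- unique(data$cell)
  .withSeed(seed, {
    lapply(seq_len(n), function(i) {
      for (k in seq_len(maxRedraw)) {
        pick <- sample(cells, length(cells), replace = TRUE)
        boot <- do.call(rbind, lapply(pick, function(cl)
          data[data$cell == cl, , drop = FALSE]))
        fit <- tryCatch(fitHill(boot, current), torsadeFitError = function(e) NULL)
        if (!is.null(fit)) return(fit$block)
      }
      .fitError(sprintf("bootstrap replicate %d failed %d redraws", i, maxRedraw))
    })
  })
}

#' Assemble joint parameter samples for uncertainty quantification
#'
#' Builds a [DrugSampleSet-class] of `n` joint (hERG dynamics, Hill
#' block) samples by pairing independent draws (with replacement) from
#' the per-channel bootstrap collections; the channels are measured in
#' separate experiments, so no cross-channel correlation is imposed.
#' When a precomputed sample table is supplied it is passed through
#' unchanged (taking its first `n` rows), so externally generated
#' parameter-sample files can be used directly.
#'
#' @param drug a [DrugRecord-class] (supplies name, Cmax, risk label and
#'   point estimates for channels without samples)
#' @param hergSamples data.frame of columns kmax, ku, n, halfmax, vhalf
#'   (one row per available hERG sample); `NULL` to reuse the record's
#'   point estimate
#' @param blockSamples named list (by current) of lists of
#'   [ChannelBlock-class] as from [bootstrapHillSamples()]
#' @param n number of joint samples
#' @param seed integer seed
#' @param precomputed optional data.frame of ready-made joint samples
#'   (as read by [readSampleSet()]); passed through unchanged
#' @return a [DrugSampleSet-class]
#' @export
assembleSampleSet <- function(drug, hergSamples = NULL, blockSamples = list(),
                              n = 2000, seed = NULL, precomputed = NULL) {
  stopifnot(is(drug, "DrugRecord"))
  if (!is.null(precomputed)) {
    if (n > nrow(precomputed))
      stop("requested ", n, " samples but the precomputed table has only ",
           nrow(precomputed), " rows", call. = FALSE)
    return(drugSampleSet(drug@name, drug@cmax,
                         precomputed[seq_len(n), , drop = FALSE],
                         drug@riskLabel))
  }
  .withSeed(seed, {
    if (is.null(hergSamples)) {
      h <- drug@herg
      hergSamples <- data.frame(kmax = h@kmax, ku = h@ku, n = h@n,
                                halfmax = h@halfmax, vhalf = h@vhalf)
    }
    idx <- sample.int(nrow(hergSamples), n, replace = TRUE)
    out <- hergSamples[idx, , drop = FALSE]
    rownames(out) <- NULL
    pointBlocks <- stats::setNames(drug@blocks,
                                   vapply(drug@blocks, slot, "", "current"))
    for (cur in union(names(blockSamples), names(pointBlocks))) {
      bs <- blockSamples[[cur]]
      if (is.null(bs) || !length(bs)) {
        pb <- pointBlocks[[cur]]
        ic <- rep(pb@ic50, n); hl <- rep(pb@hill, n)
      } else {
        j <- sample.int(length(bs), n, replace = TRUE)
        ic <- vapply(bs[j], slot, 0, "ic50")
        hl <- vapply(bs[j], slot, 0, "hill")
      }
      out[[paste0(cur, "_ic50")]] <- ic
      out[[paste0(cur, "_hill")]] <- hl
    }
    drugSampleSet(drug@name, drug@cmax, out, drug@riskLabel)
  })
}

#' Turn one sample-set row into a drug exposure
#'
#' @param sampleSet a [DrugSampleSet-class]
#' @param i row index
#' @param concentration free concentration, nM
#' @return a [DrugExposure-class]
#' @export
exposureFromSample <- function(sampleSet, i, concentration) {
  row <- sampleSet@samples[i, , drop = FALSE]
  herg <- hergDynamicParams(row$kmax, row$ku, row$n, row$halfmax, row$vhalf)
  blocks <- list()
  for (cur in .blockableCurrents) {
    ic <- row[[paste0(cur, "_ic50")]]
    if (!is.null(ic) && !is.na(ic) && is.finite(row[[paste0(cur, "_hill")]]))
      blocks <- c(blocks, channelBlock(cur, ic, row[[paste0(cur, "_hill")]]))
  }
  drugExposure(herg, blocks, concentration)
}

#' Drug exposure from a record's point estimates
#'
#' @param drug a [DrugRecord-class]
#' @param concentration free concentration, nM
#' @return a [DrugExposure-class]
#' @export
exposureFromRecord <- function(drug, concentration) {
  drugExposure(drug@herg, drug@blocks, concentration)
}
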