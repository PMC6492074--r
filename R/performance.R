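#' @include AllClasses.R pharmacology.R
NULL

.undefinedMeasure <- function(msg) {
  stop(structure(class = c("torsadeUndefinedMeasure", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Draw one resampled score per drug
#'
#' One iteration of the panel resampling scheme: for every drug an
#' independent uniform draw (with replacement) from its torsade metric
#' score distribution.
#'
#' @param dists list of [ScoreDistribution-class]
#' @param seed optional integer seed (used once; for repeated draws seed
#'   the session and call repeatedly)
#' @return named numeric vector, one score per drug
#' @export
drawPanel <- function(dists, seed = NULL) {
  .withSeed(seed, {
    stats::setNames(vapply(dists, function(d)
      d@scores[sample.int(length(d@scores), 1)], 0),
      vapply(dists, drugName, ""))
  })
}

#' ROC area under the curve by pair counting
#'
#' The Mann-Whitney form of the AUC: the probability that a positive
#' (higher-risk) drug scores lower than a negative one, ties counted 0.5.
#' Lower torsade metric score means higher predicted risk, so positives
#' are expected to lie below negatives.
#'
#' @param score numeric scores
#' @param positive logical, TRUE for the higher-risk class
#' @return AUC in \[0, 1\]
#' @examples
#' rocAuc(c(0.03, 0.07, 0.05, 0.09), c(TRUE, TRUE, FALSE, FALSE)) # 0.75
#' @export
rocAuc <- function(score, positive) {
  stopifnot(length(score) == length(positive))
  pos <- score[positive]
  neg <- score[!positive]
  if (!length(pos) || !length(neg))
    .undefinedMeasure("ROC AUC needs both classes in the panel")
  cmp <- outer(pos, neg, "<") + 0.5 * outer(pos, neg, "==")
  mean(cmp)
}

.groupPositive <- function(labels, grouping) {
  switch(grouping,
         roc1 = labels %in% c("high", "intermediate"),
         roc2 = labels == "high",
         stop("grouping must be 'roc1' or 'roc2'"))
}

.measureRecord <- function(id, values, nIter) {
  q <- stats::quantile(values, c(0.025, 0.5, 0.975), names = FALSE,
                       na.rm = TRUE)
  data.frame(measure = id, median = q[2], ci_low = q[1], ci_high = q[3],
             n_resamples = nIter)
}

#' Resampled ROC analysis over a drug panel
#'
#' Repeats [drawPanel()] + [rocAuc()] `nIter` times (default 10,000) and
#' summarises the AUC as median and 2.5/97.5 percentiles. ROC1 groups
#' high-or-intermediate vs low risk; ROC2 groups high vs
#' intermediate-or-low.
#'
#' @param dists list of labelled [ScoreDistribution-class]
#' @param grouping "roc1" or "roc2"
#' @param nIter number of resampled panels
#' @param seed integer seed
#' @return one-row data.frame (measure, median, ci_low, ci_high,
#'   n_resamples)
#' @export
rocAnalysis <- function(dists, grouping = c("roc1", "roc2"), nIter = 10000,
                        seed = NULL) {
  grouping <- match.arg(grouping)
  labs <- vapply(dists, riskLabel, "")
  pos <- .groupPositive(labs, grouping)
  if (all(pos) || !any(pos))
    .undefinedMeasure(paste(grouping, "grouping yields a single class"))
  .withSeed(seed, {
    aucs <- vapply(seq_len(nIter), function(i)
      rocAuc(drawPanel(dists), pos), 0)
    .measureRecord(paste0("auc_", grouping), aucs, nIter)
  })
}

.pairwiseRate <- function(score, rank) {
  ij <- which(outer(rank, rank, ">"), arr.ind = TRUE)  # i riskier than j
  if (!nrow(ij)) .undefinedMeasure("no cross-category drug pairs")
  si <- score[ij[, 1]]; sj <- score[ij[, 2]]
  mean((si < sj) + 0.5 * (si == sj))
}

#' Pairwise comparison correct rate
#'
#' Rank performance across all three risk classes without category
#' combining: the fraction of cross-category drug pairs whose sampled
#' scores are concordant with the risk order (higher risk implies lower
#' score), ties counted 0.5; resampled like the ROC measures.
#'
#' @inheritParams rocAnalysis
#' @return one-row measure data.frame
#' @export
pairwiseCorrectRate <- function(dists, nIter = 10000, seed = NULL) {
  labs <- vapply(dists, riskLabel, "")
  rank <- c(high = 3, intermediate = 2, low = 1)[labs]
  if (length(unique(labs[!is.na(labs)])) < 2)
    .undefinedMeasure("pairwise comparison needs >= 2 categories")
  .withSeed(seed, {
    vals <- vapply(seq_len(nIter), function(i)
      .pairwiseRate(drawPanel(dists), rank), 0)
    .measureRecord("pairwise_correct", vals, nIter)
  })
}

## sens/spec of threshold classification of one drawn panel; thresholds may
## be per-drug (leave-one-out folds) or a single Thresholds object
.sensSpec <- function(score, labs, th, which) {
  if (is(th, "Thresholds")) th <- rep(list(th), length(score))
  pred <- vapply(seq_along(score), function(i)
    classifyScore(score[i], th[[i]]), "")
  truthPos <- .groupPositive(labs, if (which == "t1") "roc1" else "roc2")
  predPos <- if (which == "t1") pred != "low" else pred == "high"
  c(sens = mean(predPos[truthPos]), spec = mean(!predPos[!truthPos]))
}

#' Likelihood ratios of threshold classification
#'
#' For a threshold (t1: positives are high-or-intermediate risk; t2:
#' positives are high risk) computes per resampled panel the sensitivity
#' and specificity of the threshold classification and the likelihood
#' ratios LR+ = sens/(1-spec), LR- = (1-sens)/spec. Zero probabilities in
#' a numerator or denominator are replaced by `protect` (default 1e-6) so
#' perfectly classified panels yield large finite LR+ (order 1e5-1e6) and
#' tiny LR- instead of infinities.
#'
#' @inheritParams rocAnalysis
#' @param th a [Thresholds-class], or a list of per-drug thresholds (one
#'   per distribution, e.g. leave-one-out folds)
#' @param which "t1" or "t2"
#' @param protect zero-cell protection constant
#' @return two-row measure data.frame (lr_pos_*, lr_neg_*)
#' @export
likelihoodRatios <- function(dists, th, which = c("t1", "t2"),
                             nIter = 10000, seed = NULL, protect = 1e-6) {
  which <- match.arg(which)
  labs <- vapply(dists, riskLabel, "")
  pos <- .groupPositive(labs, if (which == "t1") "roc1" else "roc2")
  if (all(pos) || !any(pos))
    .undefinedMeasure("likelihood ratios need both classes")
  shield <- function(p) ifelse(p <= 0, protect, p)
  .withSeed(seed, {
    lrp <- numeric(nIter); lrn <- numeric(nIter)
    for (i in seq_len(nIter)) {
      ss <- .sensSpec(drawPanel(dists), labs, th, which)
      lrp[i] <- shield(ss["sens"]) / shield(1 - ss["spec"])
      lrn[i] <- shield(1 - ss["sens"]) / shield(ss["spec"])
    }
    rbind(.measureRecord(paste0("lr_pos_", which), lrp, nIter),
          .measureRecord(paste0("lr_neg_", which), lrn, nIter))
  })
}

#' Mean classification error over a drug panel
#'
#' The mean over drugs of the probability mass of each drug's score
#' distribution falling outside its true risk category. Per iteration
#' every drug's score distribution is bootstrap-resampled (with
#' replacement, at its own size) and its off-category fraction computed;
#' the per-iteration panel mean is summarised as median and 95% CI, so a
#' drug with 75% off-category mass in a 16-drug panel contributes
#' 0.75/16 to the error.
#'
#' @inheritParams likelihoodRatios
#' @return one-row measure data.frame
#' @export
meanClassificationError <- function(dists, th, nIter = 10000, seed = NULL) {
  labs <- vapply(dists, riskLabel, "")
  if (anyNA(labs)) .undefinedMeasure("all drugs need risk labels")
  thl <- if (is(th, "Thresholds")) rep(list(th), length(dists)) else th
  ## per-drug 0/1 off-category indicator of every stored sample
  off <- lapply(seq_along(dists), function(k)
    classifyScore(dists[[k]]@scores, thl[[k]]) != labs[k])
  .withSeed(seed, {
    vals <- vapply(seq_len(nIter), function(i)
      mean(vapply(off, function(o)
        mean(o[sample.int(length(o), length(o), replace = TRUE)]), 0)), 0)
    .measureRecord("mean_class_error", vals, nIter)
  })
}

#' All prespecified performance measures with resampling CIs
#'
#' Computes the full prespecified measure set: ROC1/ROC2 AUC, pairwise
#' comparison correct rate, LR+/LR- at both thresholds, and mean
#' classification error, each summarised as median and 95% CI over
#' `nIter` resampled panels.
#'
#' @inheritParams rocAnalysis
#' @param th a [Thresholds-class] used for the classification measures
#' @param foldThresholds optional list of per-drug thresholds (e.g.
#'   leave-one-out folds) used instead of `th` for classification
#' @param datasetId label stored in the report metadata
#' @return a [PerformanceReport-class]
#' @export
evaluatePerformance <- function(dists, th, nIter = 10000, seed = NULL,
                                foldThresholds = NULL, datasetId = NA) {
  clTh <- foldThresholds %||% th
  seeds <- if (is.null(seed)) vector("list", 6) else as.list(seed + 0:5)
  measures <- rbind(
    rocAnalysis(dists, "roc1", nIter, seeds[[1]]),
    rocAnalysis(dists, "roc2", nIter, seeds[[2]]),
    pairwiseCorrectRate(dists, nIter, seeds[[3]]),
    likelihoodRatios(dists, clTh, "t1", nIter, seeds[[4]]),
    likelihoodRatios(dists, clTh, "t2", nIter, seeds[[5]]),
    meanClassificationError(dists, clTh, nIter, seeds[[6]]))
  rownames(measures) <- NULL
  performanceReport(measures,
                    meta = list(datasetId = datasetId, seed = seed,
                                nIter = nIter,
                                drugs = vapply(dists, drugName, "")))
}
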