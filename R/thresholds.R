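#' @include AllClasses.R performance.R
NULL

#' Fit the two risk thresholds by ordinal logistic regression
#'
#' Pools the torsade-metric-score samples of the training drugs and fits
#' a proportional-odds cumulative-logit model with the score as the
#' single covariate, each drug's samples weighted 1/n so every drug
#' contributes equally regardless of its number of bootstrap samples.
#' With risk ordered high < intermediate < low along increasing score,
#' the fitted cut points divided by the slope are the score values at
#' which adjacent cumulative category probabilities equal 0.5: threshold
#' 2 separates high from intermediate-or-low and threshold 1 separates
#' low from intermediate-or-high.
#'
#' @param training list of labelled [ScoreDistribution-class] objects;
#'   all three risk categories must be represented
#' @param useMedians fit on the per-drug median scores only instead of
#'   the pooled weighted samples
#' @param reltol convergence tolerance of the maximum-likelihood
#'   optimiser
#' @return a [Thresholds-class]; `@fit` carries slope, cut points and
#'   convergence information
#' @examples
#' pan <- generateScorePanel(nDrugs = c(high = 2, intermediate = 2, low = 2),
#'                           nSamples = 200, seed = 7)
#' fitOrdinalThresholds(pan)
#' @export
fitOrdinalThresholds <- function(training, useMedians = FALSE,
                                 reltol = 1e-8) {
  stopifnot(length(training) > 0,
            all(vapply(training, is, TRUE, "ScoreDistribution")))
  labs <- vapply(training, riskLabel, "")
  if (!all(.riskLevels %in% labs))
    .fitError(paste("ordinal fit needs all three risk categories; got:",
                    paste(sort(unique(labs)), collapse = ", ")))
  if (useMedians) {
    df <- data.frame(score = vapply(training, function(d)
      stats::median(d@scores), 0), label = labs, w = 1)
  } else {
    df <- do.call(rbind, lapply(training, function(d)
      data.frame(score = d@scores, label = d@riskLabel,
                 w = 1 / length(d@scores))))
  }
  df$label <- factor(df$label, levels = .riskLevels, ordered = TRUE)
  ## fit on standardized scores: the optimiser is scale-sensitive while
  ## the model (and hence the back-transformed thresholds) is not
  mu <- mean(df$score); sdv <- stats::sd(df$score)
  if (!is.finite(sdv) || sdv <= 0)
    .fitError("scores are constant; ordinal fit is degenerate")
  df$z <- (df$score - mu) / sdv
  med <- vapply(split(df$z, df$label), stats::median, 0)
  spread <- max(med["low"] - med["high"], 0.1)
  b0 <- 4 / spread
  start <- c(b0, b0 * (med["high"] + med["intermediate"]) / 2,
             b0 * (med["intermediate"] + med["low"]) / 2)
  doFit <- function(...)
    suppressWarnings(MASS::polr(label ~ z, data = df, weights = df$w,
                                method = "logistic", Hess = FALSE,
                                control = list(reltol = reltol), ...))
  fit <- tryCatch(doFit(), error = function(e) {
    tryCatch(doFit(start = start), error = function(e2)
      .fitError(paste("ordinal regression failed:",
                      conditionMessage(e2))))
  })
  beta <- unname(stats::coef(fit)["z"])
  zeta <- fit$zeta
  if (!is.finite(beta) || beta <= 0)
    .fitError("ordinal fit produced a non-positive score slope; scores are not ordered low risk = high score")
  t2 <- unname(mu + sdv * zeta[["high|intermediate"]] / beta)
  t1 <- unname(mu + sdv * zeta[["intermediate|low"]] / beta)
  thresholds(t1, t2, fit = list(slope = beta / sdv, zeta = unname(zeta),
                                converged = fit$convergence == 0,
                                pooled = !useMedians,
                                nDrugs = length(training)))
}

#' Classify a score against the two thresholds
#'
#' Scores below threshold 2 are high risk, above threshold 1 low risk,
#' and intermediate in between; boundary ties go to the intermediate
#' category (a measure-zero convention for continuous scores).
#'
#' @param score numeric vector of torsade metric scores, uC/uF
#' @param th a [Thresholds-class]
#' @return character vector of "high"/"intermediate"/"low"
#' @export
classifyScore <- function(score, th) {
  stopifnot(is(th, "Thresholds"))
  out <- rep("intermediate", length(score))
  out[score < th@t2] <- "high"
  out[score > th@t1] <- "low"
  out
}

#' Fraction of a score distribution in each risk category
#'
#' @param dist a [ScoreDistribution-class]
#' @param th a [Thresholds-class]
#' @return named numeric vector (high, intermediate, low) summing to 1
#' @export
categoryFractions <- function(dist, th) {
  cls <- classifyScore(dist@scores, th)
  vapply(.riskLevels, function(l) mean(cls == l), 0)
}

#' Leave-one-out cross-validated performance over a drug panel
#'
#' For every drug the thresholds are refit on the remaining drugs and the
#' held-out drug is classified with those fold thresholds; the
#' classification measures (likelihood ratios at both thresholds, mean
#' classification error) aggregate the held-out results, while the
#' ranking measures (ROC AUCs, pairwise comparison) use the full panel's
#' score distributions and need no thresholds. Folds missing a risk
#' category are skipped with a warning and the affected drug keeps the
#' full-panel thresholds.
#'
#' @param panel list of labelled [ScoreDistribution-class] objects
#'   (>= 3, all categories present)
#' @param nIter resampling iterations for the performance measures
#' @param seed integer seed
#' @param useMedians passed to [fitOrdinalThresholds()]
#' @return a [PerformanceReport-class]; `@meta$foldThresholds` holds the
#'   per-drug fold thresholds and `@meta$skippedFolds` any skipped drugs
#' @export
looCrossValidate <- function(panel, nIter = 10000, seed = NULL,
                             useMedians = FALSE) {
  stopifnot(length(panel) >= 3)
  labs <- vapply(panel, riskLabel, "")
  if (!all(.riskLevels %in% labs))
    .fitError("panel must contain all three risk categories")
  full <- fitOrdinalThresholds(panel, useMedians = useMedians)
  folds <- vector("list", length(panel))
  skipped <- character(0)
  for (i in seq_along(panel)) {
    rest <- panel[-i]
    if (!all(.riskLevels %in% vapply(rest, riskLabel, ""))) {
      warning("fold for drug '", panel[[i]]@drug,
              "' lacks a risk category; using full-panel thresholds")
      skipped <- c(skipped, panel[[i]]@drug)
      folds[[i]] <- full
    } else {
      folds[[i]] <- fitOrdinalThresholds(rest, useMedians = useMedians)
    }
  }
  rep <- evaluatePerformance(panel, full, nIter = nIter, seed = seed,
                             foldThresholds = folds)
  rep@meta$foldThresholds <- folds
  rep@meta$skippedFolds <- skipped
  rep@meta$thresholds <- full
  rep
}
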