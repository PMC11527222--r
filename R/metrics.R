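## Evaluation metrics for six-class ordinal and binary CDT coding.

.checkPairs <- function(pred, truth) {
  if (length(pred) != length(truth) || length(pred) < 1L)
    csError("InvalidPairs", "pred and truth must be non-empty and equal length")
  if (any(pred < 0 | pred > 5 | truth < 0 | truth > 5))
    csError("InvalidScore", "scores must lie in 0..5")
  list(pred = as.integer(pred), truth = as.integer(truth))
}

#' 6x6 confusion matrix of CDT scores
#'
#' @param pred,truth integer score vectors in 0..5.
#' @return 6x6 integer matrix, rows = truth (0..5), columns = prediction.
#' @export
scoreConfusion <- function(pred, truth) {
  p <- .checkPairs(pred, truth)
  m <- table(factor(p$truth, levels = 0:5), factor(p$pred, levels = 0:5))
  matrix(as.integer(m), 6, 6, dimnames = list(truth = 0:5, pred = 0:5))
}

#' Exact and off-by-one accuracies
#'
#' \code{accuracy}: fraction predicted exactly right. \code{accRPlus1}:
#' fraction predicted as the true score r or as r + 1. \code{accRPm1}:
#' fraction predicted within r +/- 1.
#'
#' @param pred,truth integer score vectors in 0..5.
#' @return named numeric vector (accuracy, accRPlus1, accRPm1).
#' @export
accuracySuite <- function(pred, truth) {
  p <- .checkPairs(pred, truth)
  d <- p$pred - p$truth
  c(accuracy = mean(d == 0L),
    accRPlus1 = mean(d == 0L | d == 1L),
    accRPm1 = mean(abs(d) <= 1L))
}

#' Root mean squared error of predicted scores
#'
#' @param pred,truth integer score vectors in 0..5.
#' @return scalar RMSE.
#' @export
rmseScore <- function(pred, truth) {
  p <- .checkPairs(pred, truth)
  sqrt(mean((p$pred - p$truth)^2))
}

#' Goodman-Kruskal gamma
#'
#' (C - D) / (C + D) over all sample pairs, where C counts concordant and D
#' discordant pairs; pairs tied on either variable contribute to neither.
#'
#' @param pred,truth integer score vectors in 0..5.
#' @return gamma in \[-1, 1\]; errors with class \code{UndefinedGamma} when
#'   every pair is tied.
#' @export
gammaStat <- function(pred, truth) {
  p <- .checkPairs(pred, truth)
  cm <- scoreConfusion(p$pred, p$truth)
  C <- 0; D <- 0
  for (i in 1:6) for (j in 1:6) {
    nij <- cm[i, j]
    if (nij == 0L) next
    if (i < 6 && j < 6) C <- C + nij * sum(cm[(i + 1):6, (j + 1):6])
    if (i < 6 && j > 1) D <- D + nij * sum(cm[(i + 1):6, 1:(j - 1)])
  }
  if (C + D == 0) csError("UndefinedGamma", "all pairs are tied")
  (C - D) / (C + D)
}

#' Weighted kappa for ordinal agreement
#'
#' Chance-corrected agreement 1 - sum(w * O) / sum(w * E) with disagreement
#' weights |i - j| / (K - 1) (linear) or ((i - j) / (K - 1))^2 (quadratic),
#' expected counts E from the marginal products.
#'
#' @param pred,truth integer score vectors in 0..5.
#' @param scheme "quadratic" (default, usual choice for ordinal clinical
#'   scales) or "linear".
#' @return kappa; errors with class \code{UndefinedKappa} when the expected
#'   disagreement is zero.
#' @export
weightedKappa <- function(pred, truth, scheme = c("quadratic", "linear")) {
  scheme <- match.arg(scheme)
  p <- .checkPairs(pred, truth)
  if (length(p$pred) < 2L) csError("InvalidPairs", "need at least 2 pairs")
  O <- scoreConfusion(p$pred, p$truth) / length(p$pred)
  E <- outer(rowSums(O), colSums(O))
  d <- abs(outer(0:5, 0:5, `-`)) / 5
  w <- if (scheme == "quadratic") d^2 else d
  eDis <- sum(w * E)
  if (eDis == 0) csError("UndefinedKappa", "zero expected disagreement")
  1 - sum(w * O) / eDis
}

#' Score overestimation rate
#'
#' Fraction of samples whose predicted score exceeds the reference score —
#' i.e. predicted as less impaired than the reference coding.
#'
#' @param pred,truth integer score vectors in 0..5.
#' @return rate in \[0, 1\].
#' @export
overestimationRate <- function(pred, truth) {
  p <- .checkPairs(pred, truth)
  mean(p$pred > p$truth)
}

#' Likelihood ratios from sensitivity and specificity
#'
#' LR+ = sensitivity / (1 - specificity); LR- = (1 - sensitivity) /
#' specificity. LR+ is \code{Inf} at specificity 1.
#'
#' @param sensitivity,specificity rates in \[0, 1\].
#' @return named numeric vector (lrPos, lrNeg).
#' @export
likelihoodRatios <- function(sensitivity, specificity) {
  lrPos <- if (specificity >= 1) Inf else sensitivity / (1 - specificity)
  lrNeg <- if (specificity <= 0) NaN else (1 - sensitivity) / specificity
  c(lrPos = lrPos, lrNeg = lrNeg)
}

#' Binary screening report
#'
#' Accuracy, sensitivity, specificity and likelihood ratios for binary
#' (impaired vs. non-impaired) labels, with the positive class stated
#' explicitly.
#'
#' @param pred,truth factors or character vectors with values "impaired" /
#'   "non-impaired" (as from \code{\link{binarizeScores}}).
#' @param positiveClass the class counted as positive; default
#'   "non-impaired".
#' @return list with \code{metrics} (accuracy, sensitivity, specificity,
#'   lrPos, lrNeg) and \code{confusion} (2x2, rows = truth).
#' @export
binaryReport <- function(pred, truth, positiveClass = "non-impaired") {
  lev <- c("impaired", "non-impaired")
  pred <- factor(as.character(pred), levels = lev)
  truth <- factor(as.character(truth), levels = lev)
  if (anyNA(pred) || anyNA(truth))
    csError("InvalidPairs", "labels must be 'impaired' or 'non-impaired'")
  if (length(unique(truth)) < 2L)
    csError("InvalidPairs", "both classes must be present in truth")
  stopifnot(positiveClass %in% lev)
  cm <- table(truth = truth, pred = pred)
  pos <- positiveClass; neg <- setdiff(lev, pos)
  tp <- cm[pos, pos]; fn <- cm[pos, neg]; tn <- cm[neg, neg]; fp <- cm[neg, pos]
  sens <- tp / (tp + fn); spec <- tn / (tn + fp)
  lr <- likelihoodRatios(sens, spec)
  list(metrics = c(accuracy = (tp + tn) / sum(cm), sensitivity = sens,
                   specificity = spec, lr),
       confusion = matrix(as.numeric(cm), 2, 2, dimnames = dimnames(cm)),
       positiveClass = positiveClass)
}

#' Full metrics report for predicted vs. reference scores
#'
#' Computes every ordinal metric, the 6x6 confusion matrix, and the binary
#' screening report obtained by grouping scores 0-3 as impaired and 4-5 as
#' non-impaired.
#'
#' @param pred,truth integer score vectors in 0..5.
#' @param kappaScheme weighting scheme for \code{\link{weightedKappa}}.
#' @param positiveClass positive class for the binary report.
#' @return a \linkS4class{MetricsReport}.
#' @export
metricsReport <- function(pred, truth, kappaScheme = "quadratic",
                          positiveClass = "non-impaired") {
  p <- .checkPairs(pred, truth)
  acc <- accuracySuite(p$pred, p$truth)
  gam <- tryCatch(gammaStat(p$pred, p$truth), clockscoreError = function(e) NA_real_)
  kap <- tryCatch(weightedKappa(p$pred, p$truth, kappaScheme),
                  clockscoreError = function(e) NA_real_)
  bin <- tryCatch(binaryReport(binarizeScores(p$pred), binarizeScores(p$truth),
                               positiveClass),
                  clockscoreError = function(e) NULL)
  new("MetricsReport",
      ordinal = c(acc, rmse = rmseScore(p$pred, p$truth), gamma = gam,
                  weightedKappa = kap,
                  overestimationRate = overestimationRate(p$pred, p$truth)),
      confusion = scoreConfusion(p$pred, p$truth),
      binary = if (is.null(bin)) numeric(0) else bin$metrics,
      binaryConfusion = if (is.null(bin)) matrix(0, 0, 0) else bin$confusion,
      kappaScheme = kappaScheme, positiveClass = positiveClass,
      n = length(p$pred))
}

#' Serialize a metrics report to a plain list / JSON
#'
#' @param report a \linkS4class{MetricsReport}.
#' @param path optional path; when given the report is written as JSON.
#' @return the list, invisibly when writing.
#' @export
reportAsList <- function(report, path = NULL) {
  x <- list(n = report@n,
            ordinal = as.list(report@ordinal),
            confusion = unclass(report@confusion),
            binary = as.list(report@binary),
            binaryConfusion = unclass(report@binaryConfusion),
            kappaScheme = report@kappaScheme,
            positiveClass = report@positiveClass)
  if (!is.null(path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
    return(invisible(x))
  }
  x
}
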