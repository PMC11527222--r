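## Rank-consistent ordinal classification core.
##
## A six-class ordinal score k in {0..5} is decomposed into five binary
## "rank > j" problems, j = 0..4. All five classifiers share one weight
## vector over the backbone features and differ only in their bias, which
## guarantees that the predicted exceedance probabilities are ordered
## whenever the biases are.

.EPS <- 1e-7

#' Encode an ordinal CDT score as a rank vector
#'
#' Score k in 0..K-1 becomes K-1 binary indicators, bit j = 1 iff k > j.
#' Valid rank vectors are non-increasing: all 1s precede all 0s.
#'
#' @param k integer score(s) in 0..K-1.
#' @param K number of ordered classes (default 6).
#' @return for scalar \code{k} a length K-1 0/1 vector; for a vector of
#'   scores, a matrix with one row per score.
#' @examples
#' encodeRankLabels(1)  # 1 0 0 0 0
#' encodeRankLabels(5)  # 1 1 1 1 1
#' @export
encodeRankLabels <- function(k, K = 6L) {
  if (any(is.na(k)) || any(k != floor(k)) || any(k < 0) || any(k > K - 1L))
    csError("InvalidScore", sprintf("scores must be integers in 0..%d", K - 1L))
  m <- outer(as.integer(k), 0:(K - 2L), function(s, j) as.integer(s > j))
  if (length(k) == 1L) drop(m) else m
}

#' Rank exceedance probabilities from backbone features
#'
#' Computes the shared logit a.w and the per-rank probabilities
#' sigma(a.w + b_j), j = 0..K-2. The shared weight vector is what makes the
#' head rank-consistent: with non-increasing biases the probabilities are
#' non-increasing for every input.
#'
#' @param a numeric feature vector, or a matrix with one feature vector per
#'   row.
#' @param w shared weight vector, length = feature dimension.
#' @param b per-rank biases, length K-1.
#' @return probabilities: a length K-1 vector, or an n x (K-1) matrix.
#' @export
rankProbs <- function(a, w, b) {
  if (is.null(dim(a))) a <- matrix(a, nrow = 1L)
  if (ncol(a) != length(w))
    csError("ShapeError", sprintf("feature dim %d != weight dim %d",
                                  ncol(a), length(w)))
  z <- drop(a %*% w)
  p <- stats::plogis(outer(z, b, `+`))
  if (nrow(a) == 1L) drop(p) else p
}

#' Decode rank probabilities to a score
#'
#' Default rule: the score is the number of exceedance probabilities above
#' the threshold. For non-monotone probability vectors (possible only with
#' unsorted biases) every exceedance is counted, which keeps the rule
#' deterministic. The alternative "expected" rule sums the probabilities and
#' rounds.
#'
#' @param probs length K-1 vector or n x (K-1) matrix of exceedance
#'   probabilities.
#' @param threshold decision threshold (default 0.5).
#' @param rule "count" (default) or "expected".
#' @return integer score(s) in 0..K-1.
#' @export
decodeScore <- function(probs, threshold = 0.5, rule = c("count", "expected")) {
  rule <- match.arg(rule)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  s <- if (rule == "count") rowSums(probs > threshold)
       else pmin(ncol(probs), pmax(0, round(rowSums(probs))))
  as.integer(s)
}

#' Asymmetric ordinal cross-entropy loss
#'
#' Mean over the batch of the negated sum over ranks of
#' (1 - alpha) * y * log(p) + alpha * (1 - y) * log(1 - p).
#' At alpha = 0.5 this is half the summed binary cross-entropy over the five
#' rank classifiers. Raising alpha penalises false "rank > j" positives —
#' i.e. score overestimation, which in screening terms is under-detection of
#' impairment — more heavily than false negatives.
#'
#' @param probs n x (K-1) matrix (or length K-1 vector) of predicted
#'   exceedance probabilities.
#' @param labels matching 0/1 rank-label matrix/vector
#'   (see \code{\link{encodeRankLabels}}).
#' @param alpha trade-off weight in (0, 1).
#' @return scalar loss (natural log; probabilities clamped at 1e-7).
#' @export
ordinalLoss <- function(probs, labels, alpha = 0.5) {
  if (alpha <= 0 || alpha >= 1)
    csError("InvalidAlpha", "alpha must lie strictly between 0 and 1")
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1L)
  stopifnot(all(dim(probs) == dim(labels)))
  p <- pmin(pmax(probs, .EPS), 1 - .EPS)
  terms <- (1 - alpha) * labels * log(p) + alpha * (1 - labels) * log(1 - p)
  -sum(terms) / nrow(probs)
}

#' Multi-category cross-entropy loss
#'
#' Standard nominal-classification loss: minus the mean log-probability of
#' the true class.
#'
#' @param probs n x K matrix of class probabilities; rows must sum to 1.
#' @param labels n x K one-hot matrix, or an integer vector of class indices
#'   in 0..K-1.
#' @return scalar loss (natural log).
#' @export
nominalLoss <- function(probs, labels) {
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1L)
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    csError("NormalizationError", "probability rows must sum to 1")
  if (is.null(dim(labels))) {
    oh <- matrix(0, nrow(probs), ncol(probs))
    oh[cbind(seq_len(nrow(probs)), as.integer(labels) + 1L)] <- 1
    labels <- oh
  }
  p <- pmin(pmax(probs, .EPS), 1 - .EPS)
  -sum(labels * log(p)) / nrow(probs)
}

#' Map six-point CDT scores to the binary screening classes
#'
#' Scores 0-3 are grouped as "impaired", scores 4-5 as "non-impaired".
#'
#' @param scores integer vector of scores in 0..5.
#' @return factor with levels c("impaired", "non-impaired").
#' @export
binarizeScores <- function(scores) {
  if (any(scores < 0 | scores > 5))
    csError("InvalidScore", "scores must lie in 0..5")
  factor(ifelse(scores <= 3, "impaired", "non-impaired"),
         levels = c("impaired", "non-impaired"))
}

#' Write ordinal predictions to CSV
#'
#' @param probs n x 5 matrix of exceedance probabilities.
#' @param ids image identifiers.
#' @param path output CSV path.
#' @param truth optional true scores.
#' @param threshold decode threshold.
#' @return the written data.frame, invisibly.
#' @export
writePredictions <- function(probs, ids, path, truth = NULL, threshold = 0.5) {
  df <- data.frame(image_id = ids)
  colnames(probs) <- NULL
  for (j in seq_len(ncol(probs))) df[[paste0("p_gt", j - 1L)]] <- probs[, j]
  df$decoded_score <- decodeScore(probs, threshold)
  if (!is.null(truth)) df$true_score <- as.integer(truth)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(df)
}
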