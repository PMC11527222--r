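test_that("rank-label encoding matches the rank>k convention and round-trips", {
  expect_equal(encodeRankLabels(1), c(1, 0, 0, 0, 0))
  expect_equal(encodeRankLabels(5), c(1, 1, 1, 1, 1))
  expect_equal(encodeRankLabels(0), c(0, 0, 0, 0, 0))
  for (k in 0:5) {
    bits <- encodeRankLabels(k)
    expect_true(all(diff(bits) <= 0))              # rank consistency of labels
    expect_identical(decodeScore(bits, threshold = 0.5), k)
  }
  expect_equal(dim(encodeRankLabels(c(0, 3, 5))), c(3, 5))
  expect_error(encodeRankLabels(6), class = "InvalidScore")
  expect_error(encodeRankLabels(-1), class = "InvalidScore")
})

test_that("rank probabilities are shared-logit sigmoids with per-rank biases", {
  expect_equal(rankProbs(c(0, 0), w = c(1, 1), b = rep(0, 5)), rep(0.5, 5))
  ## a.w = 1 with staggered biases: plain scalar sigmoid evaluations
  expect_equal(rankProbs(1, w = 1, b = c(1, 0, -1, -2, -3)),
               plogis(c(2, 1, 0, -1, -2)))
  ## monotone biases give monotone probabilities for any input
  set.seed(42)
  for (rep in 1:20) {
    a <- rnorm(8); w <- rnorm(8); b <- sort(rnorm(5), decreasing = TRUE)
    expect_true(all(diff(rankProbs(a, w, b)) <= 0))
  }
  expect_error(rankProbs(rnorm(3), w = rnorm(4), b = rep(0, 5)),
               class = "ShapeError")
})

test_that("score decoding counts threshold exceedances", {
  expect_identical(decodeScore(rep(0.9, 5)), 5L)
  expect_identical(decodeScore(c(0.9, 0.8, 0.2, 0.1, 0.1)), 2L)
  expect_identical(decodeScore(c(0.4, 0.6, 0.3, 0.2, 0.1)), 1L)  # non-monotone: count all
  expect_identical(decodeScore(c(0.9, 0.8, 0.6, 0.2, 0.1), rule = "expected"), 3L)
})

test_that("ordinal loss reproduces hand-computed values and the alpha=0.5 identity", {
  probs <- c(0.9, 0.8, 0.2, 0.1, 0.1)
  labels <- encodeRankLabels(2)
  ## hand-summed: -0.5 * (log .9 + log .8 + log .8 + log .9 + log .9)
  hand <- -0.5 * (log(0.9) + log(0.8) + log(0.8) + log(0.9) + log(0.9))
  expect_equal(ordinalLoss(probs, labels, alpha = 0.5), hand, tolerance = 1e-12)
  expect_equal(round(ordinalLoss(probs, labels, alpha = 0.5), 4), 0.3812)
  expect_lt(abs(ordinalLoss(probs, labels, alpha = 0.5) - 0.3811), 1e-4)
  ## alpha = 0.5 is half the summed binary cross-entropy over the 5 ranks
  set.seed(1)
  P <- matrix(runif(40, 0.05, 0.95), 8, 5)
  L <- encodeRankLabels(sample(0:5, 8, replace = TRUE))
  bce <- -mean(rowSums(L * log(P) + (1 - L) * log(1 - P)))
  expect_equal(ordinalLoss(P, L, 0.5), 0.5 * bce, tolerance = 1e-10)
  ## perfect hard predictions: loss vanishes up to the clamp
  expect_lt(ordinalLoss(encodeRankLabels(3), encodeRankLabels(3), 0.5), 1e-5)
  expect_error(ordinalLoss(P, L, alpha = 0), class = "InvalidAlpha")
  expect_error(ordinalLoss(P, L, alpha = 1.2), class = "InvalidAlpha")
})

test_that("ordinal loss is minimised at probs = labels, for any fixed alpha", {
  grid <- seq(0.01, 0.99, by = 0.01)
  for (alpha in c(0.3, 0.5, 0.75)) for (k in c(0, 2, 5)) {
    lab <- encodeRankLabels(k)
    ## separable: optimise each rank independently by grid search
    best <- vapply(seq_len(5), function(j) {
      losses <- vapply(grid, function(p) {
        pr <- lab; pr[j] <- p
        ordinalLoss(pmin(pmax(pr, 0.01), 0.99), lab, alpha)
      }, 1)
      grid[which.min(losses)]
    }, 1)
    expect_equal(best, ifelse(lab == 1, 0.99, 0.01))
  }
})

test_that("raising alpha raises the penalty on false rank exceedances", {
  lab <- encodeRankLabels(1)      # ranks 1..4 are 0
  eps <- 1e-6
  grad <- function(alpha, p) {
    pr1 <- c(0.9, p + eps, 0.1, 0.1, 0.1)
    pr0 <- c(0.9, p - eps, 0.1, 0.1, 0.1)
    (ordinalLoss(pr1, lab, alpha) - ordinalLoss(pr0, lab, alpha)) / (2 * eps)
  }
  g5 <- grad(0.5, 0.4); g75 <- grad(0.75, 0.4)
  expect_gt(g5, 0)                # predicting rank>1 is penalised...
  expect_gt(g75, g5)              # ...more under a larger alpha
  expect_equal(g75 / g5, 0.75 / 0.5, tolerance = 1e-5)
})

test_that("nominal loss matches closed forms and a direct oracle", {
  uni <- matrix(1 / 6, 1, 6)
  expect_equal(nominalLoss(uni, 3L), log(6), tolerance = 1e-12)
  P <- rbind(c(0.7, 0.06, 0.06, 0.06, 0.06, 0.06),
             c(0.1, 0.18, 0.18, 0.18, 0.18, 0.18))
  expect_equal(nominalLoss(P, c(0L, 0L)), -(log(0.7) + log(0.1)) / 2,
               tolerance = 1e-12)
  expect_equal(round(nominalLoss(P, c(0L, 0L)), 4), 1.3296)
  set.seed(2)
  for (r in 1:5) {
    Z <- matrix(rexp(30), 5, 6); Z <- Z / rowSums(Z)
    y <- sample(0:5, 5, replace = TRUE)
    oracle <- -mean(log(Z[cbind(1:5, y + 1)]))
    expect_equal(nominalLoss(Z, y), oracle, tolerance = 1e-10)
  }
  expect_error(nominalLoss(matrix(0.5, 2, 6), c(0L, 1L)),
               class = "NormalizationError")
})

test_that("binary grouping splits 0-3 impaired from 4-5 non-impaired", {
  expect_equal(as.character(binarizeScores(c(3, 4))),
               c("impaired", "non-impaired"))
  expect_equal(as.character(binarizeScores(0:5)),
               c(rep("impaired", 4), rep("non-impaired", 2)))
  expect_error(binarizeScores(7), class = "InvalidScore")
})
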