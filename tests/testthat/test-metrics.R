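test_that("confusion matrix tallies truth rows against prediction columns", {
  p <- c(0, 1, 2, 3, 4, 5); t <- p
  expect_equal(scoreConfusion(p, t), diag(1L, 6),
               ignore_attr = TRUE)
  m <- scoreConfusion(5, 3)
  expect_equal(m["3", "5"], 1L)
  expect_equal(sum(m), 1L)
  set.seed(3)
  pred <- sample(0:5, 100, replace = TRUE); truth <- sample(0:5, 100, replace = TRUE)
  m <- scoreConfusion(pred, truth)
  for (i in 0:5) for (j in 0:5)
    expect_equal(m[i + 1, j + 1], sum(truth == i & pred == j))
})

test_that("accuracy suite counts exact, r+1 and r+/-1 hits", {
  expect_equal(unname(accuracySuite(0:5, 0:5)), c(1, 1, 1))
  expect_equal(unname(accuracySuite(c(2, 3, 1, 5), c(2, 2, 2, 2))),
               c(0.25, 0.50, 0.75))
  truth <- c(0, 1, 2, 3, 4); pred <- truth + 1
  a <- accuracySuite(pred, truth)
  expect_equal(unname(a), c(0, 1, 1))
})

test_that("rmse matches closed forms and an explicit-summation oracle", {
  expect_equal(rmseScore(0:5, 0:5), 0)
  expect_equal(rmseScore(c(5, 0), c(0, 5)), 5)
  set.seed(4)
  pred <- sample(0:5, 1000, replace = TRUE); truth <- sample(0:5, 1000, replace = TRUE)
  expect_equal(rmseScore(pred, truth), oracleRmse(pred, truth), tolerance = 1e-12)
})

test_that("gamma counts concordant and discordant pairs, excluding ties", {
  expect_equal(gammaStat(0:5, 0:5), 1)
  expect_equal(gammaStat(5:0, 0:5), -1)
  expect_equal(gammaStat(c(0, 2, 1), c(0, 1, 2)), 1 / 3)  # C=2, D=1
  expect_error(gammaStat(rep(2, 5), rep(2, 5)), class = "UndefinedGamma")
})

test_that("weighted kappa agrees with a per-sample oracle and its endpoints", {
  expect_equal(weightedKappa(0:5, 0:5), 1)
  ## independence: a full factorial table has kappa exactly 0
  grid <- expand.grid(t = 0:5, p = 0:5)
  expect_equal(weightedKappa(grid$p, grid$t), 0, tolerance = 1e-12)
  set.seed(5)
  for (r in 1:5) {
    pred <- sample(0:5, 60, replace = TRUE); truth <- sample(0:5, 60, replace = TRUE)
    for (scheme in c("quadratic", "linear"))
      expect_equal(weightedKappa(pred, truth, scheme),
                   oracleKappa(pred, truth, scheme), tolerance = 1e-10)
  }
})

test_that("overestimation rate partitions with underestimation and accuracy", {
  expect_equal(overestimationRate(0:5, 0:5), 0)
  expect_equal(overestimationRate(c(3, 3, 1, 2), c(2, 2, 2, 2)), 0.5)
  set.seed(6)
  pred <- sample(0:5, 200, replace = TRUE); truth <- sample(0:5, 200, replace = TRUE)
  over <- overestimationRate(pred, truth)
  under <- overestimationRate(truth, pred)
  expect_equal(over + under + accuracySuite(pred, truth)[["accuracy"]], 1)
})

test_that("metrics are invariant to permuting the sample order", {
  set.seed(7)
  pred <- sample(0:5, 80, replace = TRUE); truth <- sample(0:5, 80, replace = TRUE)
  perm <- sample(80)
  expect_equal(gammaStat(pred, truth), gammaStat(pred[perm], truth[perm]))
  expect_equal(weightedKappa(pred, truth), weightedKappa(pred[perm], truth[perm]))
  expect_equal(rmseScore(pred, truth), rmseScore(pred[perm], truth[perm]))
  expect_equal(accuracySuite(pred, truth), accuracySuite(pred[perm], truth[perm]))
})

test_that("accuracy <= accRPlus1 <= accRPm1 on arbitrary inputs", {
  set.seed(8)
  for (r in 1:50) {
    pred <- sample(0:5, 30, replace = TRUE); truth <- sample(0:5, 30, replace = TRUE)
    a <- accuracySuite(pred, truth)
    expect_lte(a[["accuracy"]], a[["accRPlus1"]])
    expect_lte(a[["accRPlus1"]], a[["accRPm1"]])
  }
})

test_that("likelihood ratios follow their definitions", {
  lr <- likelihoodRatios(0.994, 0.762)
  expect_equal(unname(lr["lrPos"]), 0.994 / 0.238, tolerance = 1e-12)
  lr <- likelihoodRatios(1, 1)
  expect_equal(unname(lr["lrPos"]), Inf)
  expect_equal(unname(lr["lrNeg"]), 0)
})

test_that("binary report computes the five statistics and is a fixed point", {
  truth <- binarizeScores(c(0, 1, 2, 3, 4, 5, 5, 4, 1, 0))
  pred <- binarizeScores(c(0, 1, 5, 3, 4, 5, 2, 4, 1, 5))
  rep1 <- binaryReport(pred, truth, positiveClass = "non-impaired")
  cm <- rep1$confusion
  sens <- cm["non-impaired", "non-impaired"] / sum(cm["non-impaired", ])
  spec <- cm["impaired", "impaired"] / sum(cm["impaired", ])
  expect_equal(unname(rep1$metrics["sensitivity"]), sens)
  expect_equal(unname(rep1$metrics["specificity"]), spec)
  expect_equal(unname(rep1$metrics["lrPos"]), sens / (1 - spec))
  ## round trip: rebuild pairs from the confusion matrix and recompute
  lev <- c("impaired", "non-impaired")
  t2 <- rep(rep(lev, each = 2), as.vector(t(cm)))
  p2 <- rep(rep(lev, times = 2), as.vector(t(cm)))
  rep2 <- binaryReport(factor(p2, lev), factor(t2, lev), "non-impaired")
  expect_equal(rep1$metrics, rep2$metrics)
  ## degenerate truth rejected
  expect_error(binaryReport(factor(c("impaired", "impaired"), lev),
                            factor(c("impaired", "impaired"), lev)),
               class = "InvalidPairs")
})

test_that("metricsReport assembles consistent ordinal and binary views", {
  set.seed(9)
  pred <- sample(0:5, 120, replace = TRUE); truth <- sample(0:5, 120, replace = TRUE)
  rp <- metricsReport(pred, truth)
  o <- ordinalMetrics(rp)
  expect_equal(o[["accuracy"]], mean(pred == truth))
  expect_equal(sum(confusionMatrix6(rp)), 120)
  expect_equal(o[["gamma"]], oracleGamma(pred, truth), tolerance = 1e-12)
  b <- binaryMetrics(rp)
  expect_true(all(b[c("accuracy", "sensitivity", "specificity")] >= 0 &
                  b[c("accuracy", "sensitivity", "specificity")] <= 1))
  lst <- reportAsList(rp)
  expect_equal(lst$n, 120)
  expect_equal(lst$ordinal$rmse, o[["rmse"]])
})
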