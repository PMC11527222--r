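## Independent brute-force oracles used to cross-check the metric and loss
## implementations. These deliberately avoid the code paths of the package
## (no confusion matrices, no vectorized identities).

## gamma by enumerating all sample pairs and classifying each as
## concordant/discordant/tied
oracleGamma <- function(pred, truth) {
  dP <- sign(outer(pred, pred, "-"))
  dT <- sign(outer(truth, truth, "-"))
  prod <- dP * dT
  C <- sum(prod == 1) / 2
  D <- sum(prod == -1) / 2
  if (C + D == 0) return(NA_real_)
  (C - D) / (C + D)
}

## weighted kappa by per-sample weight summation and explicit double loop
## over the expected table
oracleKappa <- function(pred, truth, scheme = "quadratic") {
  n <- length(pred)
  wfun <- function(i, j) {
    d <- abs(i - j) / 5
    if (scheme == "quadratic") d^2 else d
  }
  obs <- 0
  for (s in seq_len(n)) obs <- obs + wfun(pred[[s]], truth[[s]])
  obs <- obs / n
  exp <- 0
  for (i in 0:5) for (j in 0:5)
    exp <- exp + wfun(i, j) * mean(truth == i) * mean(pred == j)
  if (exp == 0) return(NA_real_)
  1 - obs / exp
}

oracleRmse <- function(pred, truth) {
  s <- 0
  for (i in seq_along(pred)) s <- s + (pred[[i]] - truth[[i]])^2
  sqrt(s / length(pred))
}

oracleAccuracySuite <- function(pred, truth) {
  a <- 0; a1 <- 0; apm <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == truth[i]) a <- a + 1
    if (pred[i] == truth[i] || pred[i] == truth[i] + 1) a1 <- a1 + 1
    if (abs(pred[i] - truth[i]) <= 1) apm <- apm + 1
  }
  c(a, a1, apm) / length(pred)
}

oracleOverestimation <- function(pred, truth) {
  k <- 0
  for (i in seq_along(pred)) if (pred[i] > truth[i]) k <- k + 1
  k / length(pred)
}

## 8-connected flood fill labeling, the oracle for link_radius = 1 clustering
oracleFloodFill <- function(binary) {
  lab <- matrix(0L, nrow(binary), ncol(binary))
  cur <- 0L
  for (r0 in seq_len(nrow(binary))) for (c0 in seq_len(ncol(binary))) {
    if (binary[r0, c0] == 1L && lab[r0, c0] == 0L) {
      cur <- cur + 1L
      queue <- list(c(r0, c0)); lab[r0, c0] <- cur
      while (length(queue)) {
        p <- queue[[1]]; queue <- queue[-1]
        for (dr in -1:1) for (dc in -1:1) {
          rr <- p[1] + dr; cc <- p[2] + dc
          if (rr >= 1 && rr <= nrow(binary) && cc >= 1 && cc <= ncol(binary) &&
              binary[rr, cc] == 1L && lab[rr, cc] == 0L) {
            lab[rr, cc] <- cur
            queue[[length(queue) + 1L]] <- c(rr, cc)
          }
        }
      }
    }
  }
  lab
}

## canonical partition signature: map of sorted pixel-index groups
partitionSignature <- function(labels) {
  idx <- which(labels > 0L)
  split(idx, labels[idx]) |> lapply(sort) |> unname() |>
    (\(g) g[order(vapply(g, min, 1L))])()
}

## small helper: an InkComponents built straight from given stats
makeComponents <- function(stats) {
  new("InkComponents", labels = matrix(0L, 1, 1), stats = stats)
}
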