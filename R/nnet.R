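## Desk-scale convolutional backbone and two-phase trainer.
##
## The toy_cnn backbone is three blocks of (3x3 conv, ReLU, 2x2 average
## pool) followed by global average pooling; convolutions are evaluated as
## vectorized im2col matrix products, with exact analytic gradients.
## Heads: ordinal6 (shared weight vector + 5 per-rank biases, see
## rankProbs), nominal6 and binary (softmax). Training is plain SGD with
## momentum in two phases: phase 1 updates only the head; phase 2 unfreezes
## the backbone with separate learning rates for early and late blocks.

## ---- im2col convolution engine ----------------------------------------

.convIdx <- function(H, W) {
  i <- rep(seq_len(H), W); j <- rep(seq_len(W), each = H)
  idx <- matrix(0L, H * W, 9L)
  for (o in 1:9) {
    di <- (o - 1L) %% 3L; dj <- (o - 1L) %/% 3L
    idx[, o] <- (j + dj - 1L) * (H + 2L) + (i + di)
  }
  idx
}

## im2col per image: G[, , b] is the [H*W, 9*Cin] patch matrix (offset
## fastest, matching the [3, 3, Cin, Cout] weight flattening), so the batch
## never needs transposing
.convForward <- function(A, Wmat, bias, idx) {
  d <- dim(A); H <- d[1]; W <- d[2]; Cin <- d[3]; B <- d[4]
  Cout <- length(bias)
  HW <- H * W
  Ap <- array(0, c(H + 2L, W + 2L, Cin, B))
  Ap[2:(H + 1L), 2:(W + 1L), , ] <- A
  dim(Ap) <- c((H + 2L) * (W + 2L), Cin, B)
  iv <- as.vector(idx)
  G <- array(0, c(HW, 9L * Cin, B))
  Y <- array(0, c(HW, Cout, B))
  badd <- rep(bias, each = HW)
  for (b in seq_len(B)) {
    Gb <- matrix(Ap[, , b], ncol = Cin)[iv, , drop = FALSE]  # [HW*9, Cin]
    dim(Gb) <- c(HW, 9L * Cin)
    G[, , b] <- Gb
    Y[, , b] <- Gb %*% Wmat + badd
  }
  dim(Y) <- c(H, W, Cout, B)
  list(Y = Y, G = G, dims = c(H, W, Cin, B, Cout))
}

.poolForward <- function(A) {
  d <- dim(A); H <- d[1]; W <- d[2]; C <- d[3]; B <- d[4]
  X <- A; dim(X) <- c(2L, H %/% 2L, W * C * B)
  X <- colSums(X)                       # sum row pairs -> [H/2, W*C*B]
  dim(X) <- c(H %/% 2L, 2L, (W %/% 2L) * C * B)
  X <- X[, 1L, ] + X[, 2L, ]            # sum col pairs
  dim(X) <- c(H %/% 2L, W %/% 2L, C, B)
  X / 4
}

.poolBackward <- function(dY, inDim) {
  H <- inDim[1]; W <- inDim[2]; C <- inDim[3]; B <- inDim[4]
  q <- dY / 4
  up <- array(0, c(2L, H %/% 2L, 2L, W %/% 2L, C, B))
  up[1L, , 1L, , , ] <- q; up[2L, , 1L, , , ] <- q
  up[1L, , 2L, , , ] <- q; up[2L, , 2L, , , ] <- q
  dim(up) <- c(H, W, C, B)
  up
}

.softmaxRows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

## full forward pass; keepCache=TRUE retains intermediates for backprop
.forwardPass <- function(params, X, head, keepCache = FALSE, idxList) {
  B <- dim(X)[3]
  A <- X; dim(A) <- c(dim(X)[1], dim(X)[2], 1L, B)
  caches <- list()
  for (l in 1:3) {
    p <- params[[paste0("conv", l)]]
    cf <- .convForward(A, p$Wmat, p$b, idxList[[l]])
    mask <- cf$Y > 0
    R <- cf$Y * mask
    Anew <- .poolForward(R)
    if (keepCache) caches[[l]] <- list(conv = cf[c("G", "dims")], mask = mask,
                                       reluDim = dim(R))
    A <- Anew
  }
  d <- dim(A)
  feats <- t(colSums(array(A, c(d[1] * d[2], d[3], d[4])))) / (d[1] * d[2])
  hp <- params$head
  if (head == "ordinal6") {
    z <- drop(feats %*% hp$W)
    probs <- stats::plogis(outer(z, hp$b, `+`))
  } else {
    logits <- feats %*% hp$W + rep(hp$b, each = B)
    probs <- .softmaxRows(logits)
  }
  list(probs = probs, feats = feats, caches = caches, gapDim = d)
}

## backward pass given d(loss)/d(pre-sigmoid or softmax shortcut terms);
## returns gradient list with the same shapes as params
.backwardPass <- function(params, fw, dHead, head, idxList) {
  feats <- fw$feats; B <- nrow(feats)
  grads <- list()
  if (head == "ordinal6") {
    ## dHead: [B, 5] gradient wrt (z + b_k)
    db <- colSums(dHead)
    dz <- rowSums(dHead)
    dW <- crossprod(feats, dz)
    dFeats <- outer(dz, drop(params$head$W))
  } else {
    ## dHead: [B, K] gradient wrt logits
    db <- colSums(dHead)
    dW <- crossprod(feats, dHead)
    dFeats <- dHead %*% t(params$head$W)
  }
  grads$head <- list(W = dW, b = db)
  d <- fw$gapDim
  dA <- array(rep(as.vector(t(dFeats)), each = d[1] * d[2]) / (d[1] * d[2]), d)
  for (l in 3:1) {
    ch <- fw$caches[[l]]
    dR <- .poolBackward(dA, ch$reluDim)
    dR <- dR * ch$mask
    p <- params[[paste0("conv", l)]]
    dimd <- ch$conv$dims
    H <- dimd[1]; W <- dimd[2]; Cin <- dimd[3]; B <- dimd[4]; Cout <- dimd[5]
    HW <- H * W
    dim(dR) <- c(HW, Cout, B)
    G <- ch$conv$G
    idx <- idxList[[l]]
    dW <- matrix(0, 9L * Cin, Cout); db <- rep(0, Cout)
    Wt <- t(p$Wmat)
    if (l > 1) dA <- array(0, c(H, W, Cin, B))
    for (b in seq_len(B)) {
      dYb <- dR[, , b]
      dW <- dW + crossprod(G[, , b], dYb)
      db <- db + colSums(dYb)
      if (l > 1) {
        dGb <- dYb %*% Wt                 # [HW, 9*Cin]
        dim(dGb) <- c(HW, 9L, Cin)
        dMb <- matrix(0, (H + 2L) * (W + 2L), Cin)
        for (o in 1:9) dMb[idx[, o], ] <- dMb[idx[, o], ] + dGb[, o, ]
        dim(dMb) <- c(H + 2L, W + 2L, Cin)
        dA[, , , b] <- dMb[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
      }
    }
    grads[[paste0("conv", l)]] <- list(Wmat = dW, b = db)
  }
  grads
}

## ---- model construction ------------------------------------------------

#' Build a clock scoring model
#'
#' Only the in-repo \code{toy_cnn} backbone can be constructed offline; the
#' full-scale backbones (resnet101, efficientnet_b0, vit_b16) are declared
#' in the model specification but require pretrained weights that must be
#' supplied externally, and constructing them without weights raises
#' \code{PretrainedUnavailable} rather than silently initialising at random.
#'
#' @param backbone one of "toy_cnn", "resnet101", "efficientnet_b0",
#'   "vit_b16".
#' @param head "ordinal6", "nominal6" or "binary".
#' @param inputSide square input side in pixels; must be divisible by 8.
#' @param channels widths of the three conv blocks.
#' @param seed optional seed for reproducible initialisation.
#' @param pretrained logical; \code{TRUE} is unavailable for toy_cnn.
#' @return a \linkS4class{ClockModel}.
#' @export
buildClockModel <- function(backbone = "toy_cnn", head = c("ordinal6", "nominal6", "binary"),
                            inputSide = 48L, channels = c(6L, 12L, 24L),
                            seed = NULL, pretrained = FALSE) {
  head <- match.arg(head)
  if (backbone != "toy_cnn" || isTRUE(pretrained))
    csError("PretrainedUnavailable",
            sprintf("backbone '%s' with pretrained=%s requires externally supplied weights",
                    backbone, pretrained))
  if (inputSide %% 8L != 0L)
    csError("ShapeError", "inputSide must be divisible by 8 (three 2x2 pools)")
  nout <- switch(head, ordinal6 = 5L, nominal6 = 6L, binary = 2L)
  init <- function() {
    cin <- c(1L, channels[1], channels[2])
    params <- list()
    for (l in 1:3) {
      fanIn <- 9L * cin[l]
      params[[paste0("conv", l)]] <- list(
        Wmat = matrix(stats::rnorm(fanIn * channels[l], 0, sqrt(2 / fanIn)),
                      fanIn, channels[l]),
        b = rep(0, channels[l]))
    }
    C3 <- channels[3]
    wcols <- if (head == "ordinal6") 1L else nout
    params$head <- list(W = matrix(stats::rnorm(C3 * wcols, 0, sqrt(1 / C3)), C3, wcols),
                        b = rep(0, nout))
    params
  }
  params <- if (is.null(seed)) init() else .withSeed(seed, init())
  new("ClockModel", backbone = backbone, head = head,
      inputSide = as.integer(inputSide), channels = as.integer(channels),
      params = params, trained = FALSE)
}

.idxListFor <- function(side) {
  s <- side
  out <- list()
  for (l in 1:3) { out[[l]] <- .convIdx(s, s); s <- s %/% 2L }
  out
}

#' Predict rank/class probabilities
#'
#' Deterministic in evaluation: two calls on the same input give identical
#' output.
#'
#' @param model a \linkS4class{ClockModel}.
#' @param images side x side x n array, a single matrix, or a list of
#'   \linkS4class{ClockImage}.
#' @return n x 5 matrix of exceedance probabilities (ordinal6) or n x K
#'   class-probability matrix.
#' @export
predictProbs <- function(model, images) {
  X <- .asImageArray(images)
  if (dim(X)[1] != model@inputSide || dim(X)[2] != model@inputSide)
    csError("ShapeError", sprintf("model expects %dx%d input, got %dx%d",
                                  model@inputSide, model@inputSide, dim(X)[1], dim(X)[2]))
  fw <- .forwardPass(model@params, X, model@head, keepCache = FALSE,
                     idxList = .idxListFor(model@inputSide))
  fw$probs
}

#' Predict integer CDT scores
#'
#' @param model a \linkS4class{ClockModel}.
#' @param images as in \code{\link{predictProbs}}.
#' @param threshold decode threshold for the ordinal head.
#' @return integer vector of scores (0..5 for six-class heads, 0/1 for
#'   binary where 1 = non-impaired).
#' @export
predictScores <- function(model, images, threshold = 0.5) {
  probs <- predictProbs(model, images)
  if (model@head == "ordinal6") decodeScore(probs, threshold)
  else as.integer(max.col(probs) - 1L)
}

.asImageArray <- function(images) {
  if (is.list(images)) {
    mats <- lapply(images, clockPixels)
    X <- array(0, c(nrow(mats[[1]]), ncol(mats[[1]]), length(mats)))
    for (i in seq_along(mats)) X[, , i] <- mats[[i]]
    X
  } else if (length(dim(images)) == 2L) array(images, c(dim(images), 1L))
  else images
}

## ---- training ----------------------------------------------------------

#' Default training configuration
#'
#' @param epochsPhase1 epochs with the backbone frozen (M).
#' @param epochsPhase2 epochs with the backbone unfrozen.
#' @param lrHead,lrBackboneLate,lrBackboneEarly learning rates for the three
#'   parameter groups (head, late conv blocks, early conv blocks); must
#'   satisfy early <= late <= head.
#' @param batchSize mini-batch size N.
#' @param alpha ordinal-loss trade-off weight.
#' @param momentum SGD momentum.
#' @param seed seed for shuffling.
#' @param earlyBlocks number of conv blocks counted as "early" (default 1
#'   of 3).
#' @return named list.
#' @export
trainConfig <- function(epochsPhase1 = 2L, epochsPhase2 = 10L,
                        lrHead = 0.1, lrBackboneLate = 0.02,
                        lrBackboneEarly = 0.005, batchSize = 32L,
                        alpha = 0.5, momentum = 0.9, seed = 1L,
                        earlyBlocks = 1L) {
  cfg <- list(epochsPhase1 = as.integer(epochsPhase1),
              epochsPhase2 = as.integer(epochsPhase2),
              lrHead = lrHead, lrBackboneLate = lrBackboneLate,
              lrBackboneEarly = lrBackboneEarly,
              batchSize = as.integer(batchSize), alpha = alpha,
              momentum = momentum, seed = as.integer(seed),
              earlyBlocks = as.integer(earlyBlocks))
  if (!(cfg$lrBackboneEarly <= cfg$lrBackboneLate &&
        cfg$lrBackboneLate <= cfg$lrHead))
    csError("InvalidConfig", "need lrBackboneEarly <= lrBackboneLate <= lrHead")
  if (cfg$epochsPhase1 < 0L || cfg$epochsPhase2 < 0L)
    csError("InvalidConfig", "epoch counts must be non-negative")
  cfg
}

## per-sample targets for the head's loss, from integer scores 0..5
.headTargets <- function(head, scores) {
  switch(head,
    ordinal6 = encodeRankLabels(scores),
    nominal6 = { oh <- matrix(0, length(scores), 6L)
                 oh[cbind(seq_along(scores), scores + 1L)] <- 1; oh },
    binary = { cls <- as.integer(scores >= 4L)   # 1 = non-impaired
               oh <- matrix(0, length(scores), 2L)
               oh[cbind(seq_along(cls), cls + 1L)] <- 1; oh })
}

.batchLossGrad <- function(head, probs, targets, alpha) {
  B <- nrow(probs)
  if (head == "ordinal6") {
    loss <- ordinalLoss(probs, targets, alpha)
    dHead <- (-(1 - alpha) * targets * (1 - probs) +
                alpha * (1 - targets) * probs) / B
  } else {
    loss <- nominalLoss(probs, targets)
    dHead <- (probs - targets) / B
  }
  list(loss = loss, dHead = dHead)
}

#' Two-phase transfer-learning schedule
#'
#' Phase 1 freezes the backbone and updates only the head for
#' \code{epochsPhase1} epochs; phase 2 unfreezes everything with three
#' parameter groups (early conv blocks, late conv blocks, head) at their
#' configured learning rates. Optimiser is SGD with momentum.
#'
#' @param model an untrained or trained \linkS4class{ClockModel}.
#' @param images side x side x n training array.
#' @param scores integer CDT scores 0..5 for each image.
#' @param valImages,valScores optional validation split, used to log
#'   per-epoch validation accuracy/gamma.
#' @param config list from \code{\link{trainConfig}}.
#' @return list with elements \code{model} (trained) and \code{history}
#'   (data.frame: epoch, phase, loss, valAccuracy, valGamma) carrying a
#'   \code{"paramGroups"} attribute describing the learning-rate groups.
#' @export
trainTwoPhase <- function(model, images, scores, valImages = NULL,
                          valScores = NULL, config = trainConfig()) {
  X <- .asImageArray(images)
  n <- dim(X)[3]
  if (n == 0L) csError("EmptyDataset", "no training images")
  stopifnot(length(scores) == n)
  params <- model@params
  idxList <- .idxListFor(model@inputSide)
  vel <- rapply(params, function(x) x * 0, how = "replace")
  groups <- list(early = paste0("conv", seq_len(config$earlyBlocks)),
                 late = paste0("conv", setdiff(1:3, seq_len(config$earlyBlocks))),
                 head = "head")
  lrOf <- function(name, phase) {
    if (name == "head") return(config$lrHead)
    if (phase == 1L) return(0)
    if (name %in% groups$early) config$lrBackboneEarly else config$lrBackboneLate
  }
  history <- NULL
  epochTotal <- 0L
  runEpochs <- function(nep, phase) {
    for (ep in seq_len(nep)) {
      ord <- sample(n)
      epochLoss <- 0; nb <- 0L
      for (start in seq(1L, n, by = config$batchSize)) {
        take <- ord[start:min(n, start + config$batchSize - 1L)]
        Xb <- X[, , take, drop = FALSE]
        fw <- .forwardPass(params, Xb, model@head, keepCache = TRUE, idxList)
        tg <- .headTargets(model@head, scores[take])
        lg <- .batchLossGrad(model@head, fw$probs, tg, config$alpha)
        if (!is.finite(lg$loss))
          csError("DivergenceError", "loss is not finite", history = history)
        grads <- .backwardPass(params, fw, lg$dHead, model@head, idxList)
        for (nm in names(grads)) {
          lr <- lrOf(nm, phase)
          if (lr == 0) next
          for (pn in names(grads[[nm]])) {
            vel[[nm]][[pn]] <<- config$momentum * vel[[nm]][[pn]] - lr * grads[[nm]][[pn]]
            params[[nm]][[pn]] <<- params[[nm]][[pn]] + vel[[nm]][[pn]]
          }
        }
        epochLoss <- epochLoss + lg$loss; nb <- nb + 1L
      }
      epochTotal <<- epochTotal + 1L
      valAcc <- NA_real_; valGam <- NA_real_
      if (!is.null(valImages)) {
        m2 <- model; m2@params <- params
        vp <- predictScores(m2, valImages)
        if (model@head == "binary") {
          valAcc <- mean(vp == as.integer(valScores >= 4L))
        } else {
          valAcc <- mean(vp == valScores)
          valGam <- tryCatch(gammaStat(vp, valScores), clockscoreError = function(e) NA_real_)
        }
      }
      history <<- rbind(history, data.frame(epoch = epochTotal, phase = phase,
                                            loss = epochLoss / nb,
                                            valAccuracy = valAcc, valGamma = valGam))
    }
  }
  .withSeed(config$seed, {
    runEpochs(config$epochsPhase1, 1L)
    runEpochs(config$epochsPhase2, 2L)
  })
  model@params <- params
  model@trained <- TRUE
  attr(history, "paramGroups") <-
    list(early = list(members = groups$early, lr = config$lrBackboneEarly),
         late = list(members = groups$late, lr = config$lrBackboneLate),
         head = list(members = "head", lr = config$lrHead),
         phase1 = list(frozen = c(groups$early, groups$late), lr = 0))
  list(model = model, history = history)
}

#' Stratified train/test split
#'
#' Per class, \code{round(testFraction * classSize)} samples go to the test
#' set; the split is seeded and reproducible.
#'
#' @param scores integer class labels (e.g. CDT scores).
#' @param testFraction fraction per class held out (default 0.1).
#' @param seed integer seed.
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
stratifiedSplit <- function(scores, testFraction = 0.1, seed = 1L) {
  stopifnot(testFraction >= 0, testFraction <= 1)
  tab <- table(scores)
  if (any(tab < 2L))
    csError("StratifyError", "every class needs at least 2 members")
  test <- integer(0)
  .withSeed(seed, {
    for (cl in names(tab)) {
      idx <- which(scores == utils::type.convert(cl, as.is = TRUE))
      nTest <- round(testFraction * length(idx))
      if (nTest > 0L) test <- c(test, sample(idx, nTest))
    }
  })
  test <- sort(test)
  list(train = setdiff(seq_along(scores), test), test = test)
}

#' Save / load a model checkpoint
#'
#' Single-file serialized checkpoint holding the model and a content hash of
#' the training configuration.
#'
#' @param model a \linkS4class{ClockModel}.
#' @param path checkpoint path.
#' @param config optional training config stored alongside.
#' @return \code{saveClockModel}: the path, invisibly. \code{loadClockModel}:
#'   a list with \code{model}, \code{config}, \code{configHash}.
#' @export
saveClockModel <- function(model, path, config = NULL) {
  saveRDS(list(backbone = model@backbone, head = model@head,
               inputSide = model@inputSide, channels = model@channels,
               params = model@params, trained = model@trained,
               config = config,
               configHash = if (is.null(config)) NA_character_ else configHash(config)),
          path)
  invisible(path)
}

#' @rdname saveClockModel
#' @export
loadClockModel <- function(path) {
  x <- readRDS(path)
  model <- new("ClockModel", backbone = x$backbone, head = x$head,
               inputSide = x$inputSide, channels = x$channels,
               params = x$params, trained = x$trained)
  list(model = model, config = x$config, configHash = x$configHash)
}
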