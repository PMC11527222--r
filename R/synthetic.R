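## Seeded synthetic clock-drawing generator.
##
## Emulates the six-point CDT rubric (0 = not recognizable .. 5 = accurate
## clock showing 11:10) with a graded distortion ladder: as the score
## decreases, the circle opens and wobbles more, numerals drop out and
## scatter, and the hands stray further from the 11:10 targets. Score 0 is
## scribble only, with no circle. Scanned pages add ruled lines and a masked
## ID text block, with the ground truth (clock bounding box, rule-pixel
## mask) recorded for use as segmentation oracles.

## ---- raster primitives ------------------------------------------------

## stamp discs of radius `rad` at (rows, cols); vectorized over points
.stamp <- function(img, rows, cols, rad) {
  n <- nrow(img); m <- ncol(img)
  r <- max(0L, floor(rad))
  off <- expand.grid(dr = -r:r, dc = -r:r)
  off <- off[off$dr^2 + off$dc^2 <= rad^2 + 0.25, , drop = FALSE]
  ri <- rep(round(rows), each = nrow(off)) + off$dr
  ci <- rep(round(cols), each = nrow(off)) + off$dc
  ok <- ri >= 1 & ri <= n & ci >= 1 & ci <= m
  img[cbind(ri[ok], ci[ok])] <- 1
  img
}

## polyline between consecutive points, densely resampled
.strokeLine <- function(img, r0, c0, r1, c1, width) {
  len <- max(abs(r1 - r0), abs(c1 - c0), 1)
  t <- seq(0, 1, length.out = ceiling(len) * 2 + 2)
  .stamp(img, r0 + t * (r1 - r0), c0 + t * (c1 - c0), width / 2)
}

## ---- distortion ladder ------------------------------------------------

#' Distortion parameters for a given CDT score
#'
#' Returns the (seeded) drawing parameters for one clock at the requested
#' score. Severity — circle closure gap, eccentricity, wobble, numeral
#' drop-out and angular jitter, hand angle error — increases monotonically
#' as the score decreases. Score 5 draws a closed circle with 12 numerals
#' and both hands within 5 degrees of the 11:10 targets; score 0 draws
#' scribble with no circle.
#'
#' Hand angles are measured in degrees clockwise from 12 o'clock: the
#' minute hand target is 60 (pointing at 2) and the hour hand target 335
#' (11 advanced by 10/60 of an hour spacing).
#'
#' @param score integer 0..5.
#' @param seed integer seed.
#' @param side image side in pixels (>= 32).
#' @return named list of drawing parameters.
#' @export
clockParams <- function(score, seed = 1L, side = 48L) {
  if (side < 32L) csError("TooSmall", "clock side must be at least 32 pixels")
  if (!score %in% 0:5) csError("InvalidScore", "score must be an integer in 0..5")
  ## per-score severity bands (gap is a fraction of the circumference,
  ## angles in degrees)
  ladder <- list(
    `5` = list(gap = 0,    ecc = 0.02, wobble = 0.010, nNum = 12L, jit = 3,  handErr = 3,   nHands = 2L),
    `4` = list(gap = 0.02, ecc = 0.04, wobble = 0.030, nNum = 11L, jit = 8,  handErr = 10,  nHands = 2L),
    `3` = list(gap = 0.06, ecc = 0.07, wobble = 0.070, nNum = 9L,  jit = 15, handErr = 25,  nHands = 2L),
    `2` = list(gap = 0.14, ecc = 0.10, wobble = 0.130, nNum = 6L,  jit = 30, handErr = 60,  nHands = 2L),
    `1` = list(gap = 0.30, ecc = 0.15, wobble = 0.220, nNum = 3L,  jit = 50, handErr = 120, nHands = 1L),
    `0` = list(gap = 1,    ecc = 0,    wobble = 0,     nNum = 0L,  jit = 0,  handErr = 0,   nHands = 0L))
  base <- ladder[[as.character(score)]]
  .withSeed(seed, {
    nNum <- if (score %in% c(0L, 5L)) base$nNum else
      max(0L, base$nNum + sample(-1:1, 1L))
    list(score = as.integer(score), seed = as.integer(seed), side = as.integer(side),
         gap = base$gap * stats::runif(1, 0.8, 1.2),
         ecc = base$ecc * stats::runif(1, 0.7, 1.3),
         wobble = base$wobble * stats::runif(1, 0.7, 1.3),
         nNum = nNum,
         jit = base$jit, handErr = base$handErr, nHands = base$nHands,
         strokeWidth = max(1.6, side / 40),
         scribbleDensity = if (score == 0L) stats::runif(1, 0.6, 1.2) else 0,
         drawSeed = sample.int(.Machine$integer.max, 1L))
  })
}

## wobble profile: smooth pseudo-random radial modulation
.wobbleFun <- function(amp) {
  a <- stats::runif(3, 0.3, 1); ph <- stats::runif(3, 0, 2 * pi)
  a <- a / sum(a)
  function(theta) amp * (a[1] * sin(2 * theta + ph[1]) +
                         a[2] * sin(3 * theta + ph[2]) +
                         a[3] * sin(5 * theta + ph[3]))
}

#' Generate one synthetic clock drawing
#'
#' Deterministic for a fixed parameter set (same seed, same raster).
#'
#' @param params list from \code{\link{clockParams}}, or a score in 0..5
#'   (convenience; then \code{seed} and \code{side} apply).
#' @param seed,side used when \code{params} is a bare score.
#' @return a \linkS4class{ClockImage} with binary pixels (ink = 1) and a
#'   \code{"drawList"} attribute recording what was drawn (center, radius,
#'   arc, numeral positions, hand angles) for use as a test oracle.
#' @export
generateClock <- function(params, seed = 1L, side = 48L) {
  if (!is.list(params)) params <- clockParams(params, seed = seed, side = side)
  p <- params
  .withSeed(p$drawSeed, {
    s <- p$side
    img <- matrix(0, s, s)
    cr <- s / 2 + stats::runif(1, -0.02, 0.02) * s
    cc <- s / 2 + stats::runif(1, -0.02, 0.02) * s
    R <- s * stats::runif(1, 0.36, 0.41)
    drawList <- list(score = p$score, center = c(cr, cc), radius = R)
    if (p$score >= 1L) {
      ## circle: arc of (1 - gap) of the circumference, elliptic + wobbly
      th0 <- stats::runif(1, 0, 2 * pi)
      arc <- 2 * pi * (1 - p$gap)
      theta <- seq(th0, th0 + arc, length.out = 720)
      wob <- .wobbleFun(p$wobble)
      phi <- stats::runif(1, 0, pi)
      rad <- R * (1 + p$ecc * cos(2 * (theta - phi))) * (1 + wob(theta))
      rows <- cr - rad * cos(theta); cols <- cc + rad * sin(theta)
      img <- .stamp(img, rows, cols, p$strokeWidth / 2)
      drawList$arc <- c(start = th0, length = arc)
      ## numerals: glyph blobs at jittered hour positions
      present <- if (p$nNum >= 12L) 1:12 else if (p$nNum > 0L) sort(sample(1:12, p$nNum)) else integer(0)
      numerals <- NULL
      for (h in present) {
        ang <- (h %% 12) * 30 + stats::rnorm(1, 0, p$jit / 2)
        a <- ang * pi / 180
        nr <- cr - 0.76 * R * cos(a); nc <- cc + 0.76 * R * sin(a)
        g <- max(2, 0.05 * s)
        for (q in seq_len(2L + (h %% 2))) {  # 2-3 tiny strokes per glyph
          dr <- stats::runif(2, -g, g); dc <- stats::runif(2, -g, g)
          img <- .strokeLine(img, nr + dr[1], nc + dc[1], nr + dr[2], nc + dc[2],
                             p$strokeWidth * 0.8)
        }
        numerals <- rbind(numerals, c(hour = h, angle = ang, row = nr, col = nc))
      }
      drawList$numerals <- numerals
      ## hands at 11:10: minute at 60 deg, hour at 335 deg (clockwise from 12)
      hands <- NULL
      targets <- c(minute = 60, hour = 335)
      lens <- c(minute = 0.72, hour = 0.45)
      use <- names(targets)[seq_len(p$nHands)]
      for (hd in use) {
        err <- sample(c(-1, 1), 1) * stats::runif(1, 0.2, 1) * p$handErr
        if (p$score == 5L) err <- sample(c(-1, 1), 1) * stats::runif(1, 0, 5)
        ang <- (targets[[hd]] + err) * pi / 180
        r1 <- cr - lens[[hd]] * R * cos(ang); c1 <- cc + lens[[hd]] * R * sin(ang)
        img <- .strokeLine(img, cr, cc, r1, c1, p$strokeWidth)
        hands <- rbind(hands, c(angle = targets[[hd]] + err, length = lens[[hd]] * R))
      }
      if (!is.null(hands)) rownames(hands) <- use
      drawList$hands <- hands
    } else {
      ## score 0: horizontal-ish scribble band, no circle
      nPass <- 2L + stats::rpois(1, p$scribbleDensity)
      band <- 0.16 * s
      for (q in seq_len(nPass)) {
        x <- seq(0.08 * s, 0.92 * s, length.out = 60)
        y0 <- s / 2 + stats::runif(1, -0.08, 0.08) * s
        y <- y0 + cumsum(stats::rnorm(60, 0, 0.015 * s))
        y <- pmin(pmax(y, s / 2 - band), s / 2 + band)
        for (i in seq_len(59)) img <- .strokeLine(img, y[i], x[i], y[i + 1], x[i + 1],
                                                  p$strokeWidth)
      }
      drawList$scribblePasses <- nPass
    }
    out <- new("ClockImage", pixels = img, source = sprintf("synthetic_s%d_seed%d", p$score, p$seed))
    attr(out, "drawList") <- drawList
    attr(out, "params") <- p
    out
  })
}

#' Compose a synthetic scanned page around a clock drawing
#'
#' Places the clock on a larger page, overlays full-width ruled lines and a
#' masked-ID text block, and records the ground-truth clock bounding box
#' (tight ink bounds of the placed drawing) plus the mask of rule pixels not
#' overlapping clock ink.
#'
#' @param clock a \linkS4class{ClockImage} (binary pixels).
#' @param seed integer seed for placement jitter.
#' @param pageHeight,pageWidth page size in pixels.
#' @param nRules number of horizontal ruled lines.
#' @param idMark logical, draw the masked-ID text block.
#' @return a \linkS4class{ScannedPage} with \code{clockBox} and
#'   \code{ruleMask} filled in.
#' @export
generatePage <- function(clock, seed = 1L, pageHeight = 300L, pageWidth = 240L,
                         nRules = 4L, idMark = TRUE) {
  cpx <- clockPixels(clock)
  cs <- nrow(cpx)
  stopifnot(cs < pageHeight - 40L, cs < pageWidth - 20L)
  .withSeed(seed, {
    page <- matrix(0, pageHeight, pageWidth)
    ## clock placement, lower two-thirds of the page
    top <- round(stats::runif(1, 0.22 * pageHeight, pageHeight - cs - 8))
    left <- round(stats::runif(1, 8, pageWidth - cs - 8))
    page[top:(top + cs - 1), left:(left + cs - 1)] <- cpx
    ink <- which(page > 0, arr.ind = TRUE)
    clockBox <- if (nrow(ink)) c(min(ink[, 1]), min(ink[, 2]),
                                 diff(range(ink[, 1])) + 1L, diff(range(ink[, 2])) + 1L)
                else c(top, left, cs, cs)
    ## ruled lines, full width
    ruleMask <- matrix(FALSE, pageHeight, pageWidth)
    ys <- round(seq(0.15, 0.92, length.out = max(1L, nRules)) * pageHeight) +
      round(stats::runif(nRules, -3, 3))
    for (y in ys) {
      rows <- y:min(pageHeight, y + 1L)          # 2 px thick
      ruleMask[rows, ] <- TRUE
    }
    clockInk <- page > 0
    page[ruleMask] <- 1
    ruleMask <- ruleMask & !clockInk             # oracle: rule-only pixels
    ## masked-ID block: rows of short dashes, top strip
    if (idMark) {
      it <- round(stats::runif(1, 6, 14)); il <- round(stats::runif(1, 6, 20))
      for (line in 0:1) {
        yy <- it + line * 7L
        xx <- il
        while (xx < il + 52L) {
          wdash <- sample(3:7, 1L)
          page[yy:(yy + 2L), xx:min(pageWidth, xx + wdash)] <- 1
          xx <- xx + wdash + sample(2:3, 1L)
        }
      }
    }
    new("ScannedPage", pixels = page,
        id = sprintf("synthetic_page_seed%d", seed),
        clockBox = as.integer(clockBox), ruleMask = ruleMask)
  })
}

#' Generate a class-balanced synthetic clock dataset
#'
#' @param nPerClass images per score class (scores 0..5).
#' @param seed master seed; per-image seeds are drawn from it.
#' @param side image side in pixels.
#' @param dir optional directory; when given, images are written as PNG and
#'   the manifest gains a \code{path} column.
#' @return list with \code{images} (side x side x 6*nPerClass array),
#'   \code{manifest} (data.frame: id, score, seed, optionally path) and the
#'   per-image \code{drawLists}.
#' @export
generateClockDataset <- function(nPerClass, seed = 1L, side = 48L, dir = NULL) {
  n <- 6L * nPerClass
  seeds <- .withSeed(seed, sample.int(2^30, n))
  images <- array(0, c(side, side, n))
  score <- rep(0:5, each = nPerClass)
  ids <- sprintf("clock_%04d_s%d", seq_len(n), score)
  drawLists <- vector("list", n)
  for (i in seq_len(n)) {
    ci <- generateClock(score[i], seed = seeds[i], side = side)
    images[, , i] <- clockPixels(ci)
    drawLists[[i]] <- attr(ci, "drawList")
  }
  manifest <- data.frame(id = ids, score = score, seed = seeds,
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    manifest$path <- file.path(dir, paste0(ids, ".png"))
    for (i in seq_len(n))
      writeClockImage(new("ClockImage", pixels = images[, , i]), manifest$path[i])
    utils::write.csv(manifest[, c("path", "score")],
                     file.path(dir, "manifest.csv"), row.names = FALSE)
  }
  list(images = images, manifest = manifest, drawLists = drawLists)
}

#' Generate a corpus of synthetic scanned pages
#'
#' @param n number of pages.
#' @param seed master seed.
#' @param scores score classes to draw from (default 2:5, i.e. pages that
#'   contain a recognisable clock).
#' @param clockSide side of the clock drawing placed on the page.
#' @param ... forwarded to \code{\link{generatePage}}.
#' @return list of \linkS4class{ScannedPage}.
#' @export
generatePageCorpus <- function(n, seed = 1L, scores = 2:5, clockSide = 140L, ...) {
  info <- .withSeed(seed, list(seeds = sample.int(2^30, 2L * n),
                               sc = sample(scores, n, replace = TRUE)))
  lapply(seq_len(n), function(i) {
    ck <- generateClock(info$sc[i], seed = info$seeds[i], side = clockSide)
    pg <- generatePage(ck, seed = info$seeds[n + i], ...)
    attr(pg, "score") <- info$sc[i]
    pg
  })
}
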