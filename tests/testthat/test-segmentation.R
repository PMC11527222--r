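mkPage <- function(px, id = "test") new("ScannedPage", pixels = px, id = id)

test_that("binarization separates ink from background and flags degenerate pages", {
  px <- matrix(0, 32, 32)
  expect_error(binarizeImage(mkPage(px)), class = "DegenerateImage")
  expect_error(binarizeImage(mkPage(px + 1)), class = "DegenerateImage")
  ## a grey disc on white at a fixed threshold: exact identity
  px[10:20, 10:20] <- 0.8
  bin <- binarizeImage(mkPage(px), method = "fixed", threshold = 0.5)
  expect_equal(bin, matrix(as.integer(px > 0.5), 32, 32))
  ## Otsu on a realistic page recovers close to the drawn ink fraction
  pg <- generatePage(generateClock(5, seed = 2, side = 140), seed = 2)
  drawn <- mean(clockPixels(pg) > 0)
  got <- mean(binarizeImage(pg) == 1L)
  expect_lt(abs(got - drawn) / drawn, 0.2)
})

test_that("line removal erases long runs but preserves other ink", {
  px <- matrix(0L, 64, 64)
  px[30, ] <- 1L                                  # full-width rule
  expect_equal(sum(removeLines(px, lineMinLen = 32)), 0)
  ## a line-free drawing passes through unchanged
  ck <- matrix(as.integer(clockPixels(generateClock(5, seed = 4, side = 64)) > 0), 64, 64)
  expect_equal(removeLines(ck, lineMinLen = 32), ck)
  ## ruled page: residual rule ink outside the clock box is < 2% of total
  pg <- generatePage(generateClock(4, seed = 5, side = 140), seed = 5)
  bin <- binarizeImage(pg)
  cleaned <- removeLines(bin)
  residual <- cleaned == 1L & pg@ruleMask
  ## rule remnants outside the clock box (crossing pixels next to clock
  ## strokes are deliberately restored inside it)
  bx <- pg@clockBox
  residual[bx[1]:(bx[1] + bx[3] - 1), bx[2]:(bx[2] + bx[4] - 1)] <- FALSE
  expect_lt(sum(residual) / sum(bin), 0.02)
})

test_that("component clustering respects the link radius", {
  px <- matrix(0L, 40, 40)
  px[10:12, 10:12] <- 1L
  px[10:12, 14:16] <- 1L                          # 1 px gap between discs
  expect_equal(nrow(componentStats(findComponents(px, linkRadius = 2))), 1)
  px2 <- matrix(0L, 80, 80)
  px2[5:7, 5:7] <- 1L; px2[60:62, 60:62] <- 1L    # far apart
  expect_equal(nrow(componentStats(findComponents(px2, linkRadius = 2))), 2)
  expect_equal(nrow(componentStats(findComponents(matrix(0L, 20, 20)))), 0)
})

test_that("radius-1 clustering equals 8-connected flood fill on random rasters", {
  set.seed(11)
  for (r in 1:8) {
    px <- matrix(rbinom(400, 1, 0.35), 20, 20)
    if (!any(px == 1L)) next
    got <- findComponents(px, linkRadius = 1)
    expect_equal(partitionSignature(got@labels),
                 partitionSignature(oracleFloodFill(px)))
    ## partition property: components cover all ink, disjointly
    expect_equal(sort(which(got@labels > 0L)), sort(which(px == 1L)))
    s <- componentStats(got)
    expect_equal(sum(s$npix), sum(px))
    expect_true(all(s$density > 0 & s$density <= 1))
  }
})

test_that("component stats describe tight boxes, densities and ratios", {
  px <- matrix(0L, 30, 30)
  px[5:10, 5:16] <- 1L                            # 6 x 12 solid block
  s <- componentStats(findComponents(px))
  expect_equal(s$height, 6); expect_equal(s$width, 12)
  expect_equal(s$density, 1); expect_equal(s$ratio, 2)
})

test_that("clock selection enforces the density and aspect thresholds", {
  circle <- data.frame(label = 1L, npix = 500L, top = 1L, left = 1L,
                       height = 70L, width = 70L, density = 0.12, ratio = 1.0)
  sel <- selectClock(makeComponents(circle))
  expect_equal(sel$label, 1L)
  solid <- data.frame(label = 1L, npix = 4900L, top = 1L, left = 1L,
                      height = 70L, width = 70L, density = 1.0, ratio = 1.0)
  expect_error(selectClock(makeComponents(solid)), class = "NoClockFound")
  trio <- rbind(circle,
                data.frame(label = 2L, npix = 900L, top = 1L, left = 1L,
                           height = 4L, width = 36L, density = 0.9, ratio = 9),
                data.frame(label = 3L, npix = 700L, top = 1L, left = 1L,
                           height = 30L, width = 33L, density = 0.7, ratio = 1.1))
  sel <- selectClock(makeComponents(trio))
  expect_equal(sel$label, 1L)                     # only the hollow circle qualifies
  ## the winner never violates the printed thresholds
  expect_lt(sel$density, 0.6)
  expect_lt(abs(sel$ratio - 1), 0.4)
})

test_that("extraction crops the clock accurately and propagates failures", {
  pg <- generatePage(generateClock(5, seed = 31, side = 140), seed = 31)
  ck <- extractClock(pg, side = 64)
  expect_s4_class(ck, "ClockImage")
  expect_equal(dim(clockPixels(ck)), c(64, 64))
  expect_gte(bboxIoU(attr(ck, "componentBox"), pg@clockBox), 0.8)
  ## a page holding only ruled lines has no clock
  px <- matrix(0, 64, 64); px[c(20, 40), ] <- 1
  expect_error(extractClock(mkPage(px), side = 32), class = "NoClockFound")
  ## pre-cropped clock: extraction is (near) idempotent
  solo <- clockPixels(generateClock(5, seed = 32, side = 140))
  e1 <- extractClock(mkPage(solo), side = 96)
  e2 <- extractClock(mkPage(clockPixels(e1)), side = 96)
  expect_lt(mean(abs(clockPixels(e1) - clockPixels(e2))), 0.05)
})

test_that("batch extraction writes a per-page report", {
  dir <- tempfile("pages"); outDir <- tempfile("clocks")
  dir.create(dir)
  pgs <- generatePageCorpus(3, seed = 41)
  for (i in seq_along(pgs))
    EBImage::writeImage(EBImage::Image(t(1 - clockPixels(pgs[[i]]))),
                        file.path(dir, sprintf("p%d.png", i)))
  rep <- extractClockBatch(dir, outDir, reportPath = file.path(outDir, "report.csv"),
                           side = 64)
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$status %in% c("ok", "no_clock", "degenerate")))
  expect_true(file.exists(file.path(outDir, "report.csv")))
})
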