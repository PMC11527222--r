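## Clock extraction from scanned pages.
##
## Pipeline: binarize -> remove ruled lines (1xL / Lx1 morphological openings)
## -> cluster ink pixels into components (link radius in Chebyshev distance)
## -> select the clock component by bounding-box ink density and width/height
## aspect ratio -> crop, pad square, resize.

#' Read a scanned page from a PNG/TIFF file
#'
#' Images on disk follow the scanner convention (white paper, dark ink);
#' they are inverted on load so that ink is high internally.
#'
#' @param path path to a PNG or TIFF file.
#' @param id identifier stored with the page; defaults to the file name.
#' @param inkLow logical; set \code{FALSE} if the file already stores ink as
#'   high values.
#' @return a \linkS4class{ScannedPage}.
#' @export
readPage <- function(path, id = basename(path), inkLow = TRUE) {
  img <- EBImage::readImage(path)
  d <- dim(img)
  if (length(d) == 3L) img <- img[, , 1L]
  px <- t(matrix(EBImage::imageData(img), d[1], d[2]))  # EBImage is (x, y); we keep (row, col)
  px <- pmin(pmax(px, 0), 1)
  if (inkLow) px <- 1 - px
  new("ScannedPage", pixels = px, id = id)
}

#' Write a page or clock image to PNG
#'
#' @param x a \linkS4class{ScannedPage} or \linkS4class{ClockImage}.
#' @param path output path (PNG).
#' @param inkLow logical; write with the scanner convention (ink dark).
#' @return invisibly, \code{path}.
#' @export
writeClockImage <- function(x, path, inkLow = TRUE) {
  px <- clockPixels(x)
  if (inkLow) px <- 1 - px
  EBImage::writeImage(EBImage::Image(t(px)), path)
  invisible(path)
}

#' Binarize a scanned page
#'
#' @param page a \linkS4class{ScannedPage}.
#' @param method "otsu" (default) or "fixed".
#' @param threshold fixed threshold in \[0, 1\], used when
#'   \code{method = "fixed"}.
#' @return an integer matrix with ink = 1, background = 0.
#' @export
binarizeImage <- function(page, method = c("otsu", "fixed"), threshold = 0.5) {
  method <- match.arg(method)
  px <- page@pixels
  thr <- if (method == "otsu") {
    rng <- range(px)
    if (diff(rng) < 1e-8) 0.5 else EBImage::otsu(EBImage::Image(t(px)), range = rng)
  } else threshold
  bin <- matrix(0L, nrow(px), ncol(px))
  bin[px > thr] <- 1L
  n1 <- sum(bin)
  if (n1 == 0L || n1 == length(bin))
    csError("DegenerateImage", "page is entirely ink or entirely background")
  bin
}

## run-length opening along rows: zero out every horizontal run of 1s shorter
## than minLen, keep runs >= minLen (exact 1xL binary opening)
.lineRuns <- function(binary, minLen) {
  out <- matrix(0L, nrow(binary), ncol(binary))
  for (i in seq_len(nrow(binary))) {
    r <- rle(binary[i, ])
    keep <- r$values == 1L & r$lengths >= minLen
    if (any(keep)) {
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      for (j in which(keep)) out[i, starts[j]:ends[j]] <- 1L
    }
  }
  out
}

#' Remove ruled lines from a binarized page
#'
#' Horizontal and vertical ink runs of at least \code{lineMinLen} pixels are
#' detected with 1xL and Lx1 morphological openings and erased. Erased pixels
#' are restored where they fall next to surviving (non-line) ink, so clock
#' strokes that cross a ruled line keep their crossing pixels.
#'
#' @param binary integer matrix (ink = 1), as from \code{\link{binarizeImage}}.
#' @param lineMinLen minimum run length, in pixels, for a line; defaults to
#'   half the page width.
#' @param restoreRadius radius, in pixels, of the neighbourhood of surviving
#'   ink inside which erased line pixels are re-added.
#' @return an integer matrix with line pixels removed.
#' @export
removeLines <- function(binary, lineMinLen = NULL, restoreRadius = 2L) {
  if (is.null(lineMinLen)) lineMinLen <- max(8L, floor(ncol(binary) / 2))
  lines <- .lineRuns(binary, lineMinLen) | t(.lineRuns(t(binary), lineMinLen))
  residual <- binary == 1L & !lines
  if (restoreRadius > 0L && any(residual)) {
    brush <- matrix(1L, 2L * restoreRadius + 1L, 2L * restoreRadius + 1L)
    near <- EBImage::dilate(residual + 0, brush) > 0
    restore <- lines & binary == 1L & near
  } else restore <- matrix(FALSE, nrow(binary), ncol(binary))
  out <- matrix(0L, nrow(binary), ncol(binary))
  out[residual | restore] <- 1L
  out
}

## merge connected-component labels whose minimum pairwise Chebyshev distance
## is <= radius, via per-component box dilation; exact transitive closure
## through union-find
.mergeByRadius <- function(labels, radius) {
  ncomp <- max(labels)
  if (ncomp <= 1L) return(labels)
  parent <- seq_len(ncomp)
  findRoot <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  brush <- matrix(1L, 2L * radius + 1L, 2L * radius + 1L)
  nr <- nrow(labels); nc <- ncol(labels)
  for (k in seq_len(ncomp)) {
    idx <- which(labels == k, arr.ind = TRUE)
    t0 <- max(1L, min(idx[, 1]) - radius); b0 <- min(nr, max(idx[, 1]) + radius)
    l0 <- max(1L, min(idx[, 2]) - radius); r0 <- min(nc, max(idx[, 2]) + radius)
    sub <- labels[t0:b0, l0:r0, drop = FALSE]
    mask <- (sub == k) + 0
    grown <- EBImage::dilate(mask, brush) > 0
    touched <- unique(sub[grown & sub > 0L & sub != k])
    for (m in touched) {
      rk <- findRoot(k); rm <- findRoot(m)
      if (rk != rm) parent[max(rk, rm)] <- min(rk, rm)
    }
  }
  roots <- vapply(seq_len(ncomp), findRoot, 1L)
  relab <- match(roots, sort(unique(roots)))
  out <- labels
  out[labels > 0L] <- relab[labels[labels > 0L]]
  out
}

#' Cluster ink pixels into connected components
#'
#' Two ink pixels belong to the same component iff they are connected through
#' hops of Chebyshev distance at most \code{linkRadius}; radius 1 is the
#' standard 8-connected labeling. Per component, the bounding box, pixel
#' count, bounding-box ink density and width/height ratio are computed.
#'
#' @param binary integer matrix (ink = 1).
#' @param linkRadius linking distance in pixels (default 3).
#' @return an \linkS4class{InkComponents}; empty stats for an all-background
#'   raster.
#' @export
findComponents <- function(binary, linkRadius = 3L) {
  stopifnot(linkRadius >= 1L)
  if (!any(binary == 1L)) {
    return(new("InkComponents", labels = matrix(0L, nrow(binary), ncol(binary)),
               stats = data.frame(label = integer(0), npix = integer(0),
                                  top = integer(0), left = integer(0),
                                  height = integer(0), width = integer(0),
                                  density = numeric(0), ratio = numeric(0))))
  }
  lab4 <- EBImage::bwlabel(binary + 0)        # 4-connected base labeling
  labels <- matrix(as.integer(round(lab4)), nrow(binary), ncol(binary))
  labels <- .mergeByRadius(labels, as.integer(linkRadius))
  idx <- which(labels > 0L, arr.ind = TRUE)
  lab <- labels[labels > 0L]
  tops <- tapply(idx[, 1], lab, min); bots <- tapply(idx[, 1], lab, max)
  lefts <- tapply(idx[, 2], lab, min); rights <- tapply(idx[, 2], lab, max)
  npix <- as.integer(table(lab))
  h <- as.integer(bots - tops + 1L); w <- as.integer(rights - lefts + 1L)
  stats <- data.frame(label = as.integer(names(tops)), npix = npix,
                      top = as.integer(tops), left = as.integer(lefts),
                      height = h, width = w,
                      density = npix / (as.numeric(h) * w), ratio = w / h)
  rownames(stats) <- NULL
  new("InkComponents", labels = labels, stats = stats)
}

#' Select the clock component
#'
#' A component qualifies as the clock drawing when its bounding-box ink
#' density is below \code{densityMax} and its width/height ratio r satisfies
#' |r - 1| < \code{ratioTol}. Among several qualifiers the one with the most
#' ink pixels wins (deterministic tie-break).
#'
#' @param components an \linkS4class{InkComponents}.
#' @param densityMax density threshold (default 0.6).
#' @param ratioTol aspect-ratio tolerance around 1 (default 0.4).
#' @return one row of the component statistics table.
#' @export
selectClock <- function(components, densityMax = 0.6, ratioTol = 0.4) {
  s <- componentStats(components)
  ok <- s$density < densityMax & abs(s$ratio - 1) < ratioTol
  if (!any(ok))
    csError("NoClockFound", "no component satisfies the clock density/aspect rule")
  cand <- s[ok, , drop = FALSE]
  cand[which.max(cand$npix), , drop = FALSE]
}

#' Extract the clock drawing from a scanned page
#'
#' Runs the full segmentation pipeline: binarize, remove ruled lines, cluster
#' ink into components, select the clock component, then crop its bounding
#' box with a relative margin, pad to square on background and resize to the
#' model input side.
#'
#' @param page a \linkS4class{ScannedPage}.
#' @param side output side in pixels (default 224).
#' @param margin relative crop margin (default 0.05).
#' @param linkRadius,lineMinLen,densityMax,ratioTol,binarizeMethod,threshold
#'   parameters forwarded to the pipeline stages.
#' @return a \linkS4class{ClockImage}; its \code{cropBox} records the
#'   (margin-expanded) crop, and attribute \code{"componentBox"} the tight
#'   bounding box of the selected ink component.
#' @export
extractClock <- function(page, side = 224L, margin = 0.05, linkRadius = 8L,
                         lineMinLen = NULL, densityMax = 0.6, ratioTol = 0.4,
                         binarizeMethod = "otsu", threshold = 0.5) {
  bin <- binarizeImage(page, method = binarizeMethod, threshold = threshold)
  bin <- removeLines(bin, lineMinLen = lineMinLen)
  if (!any(bin == 1L))
    csError("NoClockFound", "no ink remains after line removal")
  comp <- findComponents(bin, linkRadius = linkRadius)
  sel <- selectClock(comp, densityMax = densityMax, ratioTol = ratioTol)
  mg <- ceiling(margin * max(sel$height, sel$width))
  top <- max(1L, sel$top - mg); left <- max(1L, sel$left - mg)
  bot <- min(nrow(page@pixels), sel$top + sel$height - 1L + mg)
  right <- min(ncol(page@pixels), sel$left + sel$width - 1L + mg)
  ## crop the cleaned raster: lines are gone, and any ink falling inside the
  ## clock box (e.g. numerals labelled as separate components) is kept
  crop <- bin[top:bot, left:right, drop = FALSE] + 0
  ## pad to square, centred, background = 0
  h <- nrow(crop); w <- ncol(crop); s <- max(h, w)
  sq <- matrix(0, s, s)
  r0 <- (s - h) %/% 2; c0 <- (s - w) %/% 2
  sq[r0 + seq_len(h), c0 + seq_len(w)] <- crop
  rs <- EBImage::resize(EBImage::Image(sq), w = side, h = side)
  px <- matrix(pmin(pmax(EBImage::imageData(rs), 0), 1), side, side)
  out <- new("ClockImage", pixels = px, source = page@id,
             cropBox = as.integer(c(top, left, bot - top + 1L, right - left + 1L)))
  attr(out, "componentBox") <- as.integer(c(sel$top, sel$left, sel$height, sel$width))
  attr(out, "componentStats") <- sel
  out
}

#' Intersection-over-union of two bounding boxes
#'
#' @param a,b integer vectors \code{c(top, left, height, width)}.
#' @return IoU in \[0, 1\].
#' @export
bboxIoU <- function(a, b) {
  at <- a[1]; al <- a[2]; ab <- a[1] + a[3] - 1; ar <- a[2] + a[4] - 1
  bt <- b[1]; bl <- b[2]; bb <- b[1] + b[3] - 1; br <- b[2] + b[4] - 1
  ih <- min(ab, bb) - max(at, bt) + 1
  iw <- min(ar, br) - max(al, bl) + 1
  if (ih <= 0 || iw <= 0) return(0)
  inter <- as.numeric(ih) * iw
  inter / (as.numeric(a[3]) * a[4] + as.numeric(b[3]) * b[4] - inter)
}

#' Batch clock extraction over a directory
#'
#' Reads every PNG/TIFF under \code{inDir}, extracts the clock, writes the
#' extracted images to \code{outDir} and returns (and optionally writes) an
#' extraction report.
#'
#' @param inDir directory of scanned pages.
#' @param outDir output directory for extracted clock PNGs.
#' @param reportPath optional CSV path for the report.
#' @param ... forwarded to \code{\link{extractClock}}.
#' @return data.frame report: source, status (ok / no_clock / degenerate),
#'   bbox, density, ratio.
#' @export
extractClockBatch <- function(inDir, outDir, reportPath = NULL, ...) {
  paths <- list.files(inDir, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  rows <- lapply(paths, function(p) {
    page <- readPage(p)
    res <- tryCatch(extractClock(page, ...), clockscoreError = function(e) e)
    if (is(res, "ClockImage")) {
      writeClockImage(res, file.path(outDir, paste0(tools::file_path_sans_ext(basename(p)), "_clock.png")))
      st <- attr(res, "componentStats")
      data.frame(source = p, status = "ok",
                 top = res@cropBox[1], left = res@cropBox[2],
                 height = res@cropBox[3], width = res@cropBox[4],
                 density = st$density, ratio = st$ratio)
    } else {
      status <- if (inherits(res, "NoClockFound")) "no_clock" else "degenerate"
      data.frame(source = p, status = status, top = NA, left = NA,
                 height = NA, width = NA, density = NA, ratio = NA)
    }
  })
  report <- do.call(rbind, rows)
  if (!is.null(reportPath)) utils::write.csv(report, reportPath, row.names = FALSE)
  report
}
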