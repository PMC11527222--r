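#' @import methods
NULL

#' Scanned clock-drawing page
#'
#' A single-channel raster of a scanned clock-drawing test (CDT) page.
#' Internally ink is always stored "high": pixel values lie in \[0, 1\] with 0
#' = blank paper and values near 1 = ink. Pages generated by
#' \code{\link{generatePage}} additionally carry the ground-truth bounding box
#' of the placed clock drawing and a mask of the ruled-line pixels, which the
#' segmentation tests use as oracles.
#'
#' Bounding boxes throughout the package are integer vectors
#' \code{c(top, left, height, width)} in 1-based matrix (row, column)
#' coordinates, closed on both ends.
#'
#' @slot pixels numeric matrix, values in \[0, 1\], ink high.
#' @slot id character scalar identifying the source.
#' @slot clockBox integer(4) ground-truth clock bounding box, or integer(0)
#'   when unknown.
#' @slot ruleMask logical matrix marking ruled-line pixels, or a 0x0 matrix
#'   when unknown.
#' @aliases ScannedPage-class
#' @exportClass ScannedPage
setClass("ScannedPage",
  representation(pixels = "matrix", id = "character",
                 clockBox = "integer", ruleMask = "matrix"),
  prototype(id = "page", clockBox = integer(0),
            ruleMask = matrix(logical(0), 0, 0)))

setValidity("ScannedPage", function(object) {
  p <- object@pixels
  if (!is.numeric(p)) return("pixels must be a numeric matrix")
  if (nrow(p) < 16L || ncol(p) < 16L) return("page must be at least 16x16 pixels")
  if (anyNA(p) || min(p) < 0 || max(p) > 1) return("pixel values must lie in [0, 1]")
  if (length(object@clockBox) && length(object@clockBox) != 4L)
    return("clockBox must be integer(4): top, left, height, width")
  TRUE
})

#' Extracted clock image
#'
#' A square grayscale raster of an extracted clock drawing, resized to the
#' configured model input side, with provenance back to the source page.
#'
#' @slot pixels numeric square matrix in \[0, 1\], ink high.
#' @slot source character id of the source page.
#' @slot cropBox integer(4) crop box (top, left, height, width) applied to the
#'   source page, or integer(0) for synthetic clocks drawn directly.
#' @aliases ClockImage-class
#' @exportClass ClockImage
setClass("ClockImage",
  representation(pixels = "matrix", source = "character", cropBox = "integer"),
  prototype(source = "synthetic", cropBox = integer(0)))

setValidity("ClockImage", function(object) {
  p <- object@pixels
  if (nrow(p) != ncol(p)) return("clock image must be square")
  if (anyNA(p) || min(p) < 0 || max(p) > 1) return("pixel values must lie in [0, 1]")
  TRUE
})

#' Ink components of a binarized page
#'
#' Result of clustering ink pixels into connected components: a label matrix
#' (0 = background, k = component k) and a per-component statistics table with
#' the bounding box, pixel count, bounding-box ink density and width/height
#' aspect ratio used by the clock-selection rule.
#'
#' @slot labels integer matrix of component labels, 0 = background.
#' @slot stats data.frame with one row per component: \code{label},
#'   \code{npix}, \code{top}, \code{left}, \code{height}, \code{width},
#'   \code{density} (npix / bbox area) and \code{ratio} (width / height).
#' @aliases InkComponents-class
#' @exportClass InkComponents
setClass("InkComponents",
  representation(labels = "matrix", stats = "data.frame"))

setValidity("InkComponents", function(object) {
  s <- object@stats
  need <- c("label", "npix", "top", "left", "height", "width", "density", "ratio")
  if (!all(need %in% names(s))) return("stats is missing required columns")
  if (nrow(s) && (any(s$density <= 0) || any(s$density > 1)))
    return("density must lie in (0, 1]")
  if (nrow(s) && any(s$ratio <= 0)) return("ratio must be positive")
  TRUE
})

#' Clock scoring model
#'
#' A backbone feature embedder plus a classification head. The in-repo
#' \code{toy_cnn} backbone is a small three-block convolutional network
#' (conv 3x3 + ReLU + 2x2 average pooling, then global average pooling);
#' heads are \code{ordinal6} (shared weight vector, five per-rank biases),
#' \code{nominal6} (softmax over six classes) or \code{binary} (softmax over
#' impaired / non-impaired).
#'
#' @slot backbone character, one of "toy_cnn", "resnet101",
#'   "efficientnet_b0", "vit_b16" (only toy_cnn is constructible offline).
#' @slot head character, one of "ordinal6", "nominal6", "binary".
#' @slot inputSide integer, side of the square input image in pixels.
#' @slot channels integer vector of channel widths for the three conv blocks.
#' @slot params list of numeric arrays holding all trainable parameters.
#' @slot trained logical, whether the model has been through training.
#' @aliases ClockModel-class
#' @exportClass ClockModel
setClass("ClockModel",
  representation(backbone = "character", head = "character",
                 inputSide = "integer", channels = "integer",
                 params = "list", trained = "logical"),
  prototype(trained = FALSE))

setValidity("ClockModel", function(object) {
  if (!object@head %in% c("ordinal6", "nominal6", "binary"))
    return("head must be one of ordinal6, nominal6, binary")
  if (object@inputSide < 16L) return("inputSide must be at least 16")
  TRUE
})

#' Evaluation report for predicted vs. reference CDT scores
#'
#' Holds every ordinal metric (exact accuracy, accuracy allowing r+1,
#' accuracy allowing r+/-1, RMSE, Goodman-Kruskal gamma, weighted kappa,
#' overestimation rate), the 6x6 confusion matrix, and the derived binary
#' (impaired vs. non-impaired) report with sensitivity, specificity and
#' likelihood ratios.
#'
#' @slot ordinal named numeric vector of ordinal metrics.
#' @slot confusion 6x6 integer matrix, rows = truth, columns = prediction.
#' @slot binary named numeric vector of binary metrics.
#' @slot binaryConfusion 2x2 matrix, rows = truth, columns = prediction.
#' @slot kappaScheme character, "quadratic" or "linear".
#' @slot positiveClass character, class treated as positive in the binary
#'   report.
#' @slot n integer, number of score pairs.
#' @aliases MetricsReport-class
#' @exportClass MetricsReport
setClass("MetricsReport",
  representation(ordinal = "numeric", confusion = "matrix",
                 binary = "numeric", binaryConfusion = "matrix",
                 kappaScheme = "character", positiveClass = "character",
                 n = "integer"))

setMethod("show", "ScannedPage", function(object) {
  cat(sprintf("ScannedPage '%s': %d x %d px", object@id,
              nrow(object@pixels), ncol(object@pixels)))
  if (length(object@clockBox))
    cat(sprintf(", ground-truth clock box [%s]",
                paste(object@clockBox, collapse = ", ")))
  cat("\n")
})

setMethod("show", "ClockImage", function(object) {
  cat(sprintf("ClockImage (%d x %d px) from '%s'\n",
              nrow(object@pixels), ncol(object@pixels), object@source))
})

setMethod("show", "InkComponents", function(object) {
  cat(sprintf("InkComponents: %d component(s)\n", nrow(object@stats)))
  if (nrow(object@stats)) print(utils::head(object@stats, 10L))
})

setMethod("show", "ClockModel", function(object) {
  np <- sum(vapply(unlist(object@params, recursive = FALSE), length, 1L))
  cat(sprintf("ClockModel: backbone=%s head=%s input=%dpx (%s), %d parameters\n",
              object@backbone, object@head, object@inputSide,
              if (object@trained) "trained" else "untrained", np))
})

setMethod("show", "MetricsReport", function(object) {
  cat(sprintf("MetricsReport over %d score pairs\n", object@n))
  cat("Ordinal metrics:\n")
  print(round(object@ordinal, 4))
  cat(sprintf("Binary metrics (positive class: %s):\n", object@positiveClass))
  print(round(object@binary, 4))
})

#' Accessors for clockscore objects
#'
#' \code{clockPixels} returns the pixel matrix of a page or clock image;
#' \code{componentStats} the per-component statistics table;
#' \code{ordinalMetrics} / \code{binaryMetrics} / \code{confusionMatrix6}
#' the corresponding pieces of a \linkS4class{MetricsReport}.
#'
#' @param x a clockscore S4 object.
#' @return the requested component.
#' @rdname accessors
#' @export
clockPixels <- function(x) {
  stopifnot(is(x, "ScannedPage") || is(x, "ClockImage"))
  x@pixels
}

#' @rdname accessors
#' @export
componentStats <- function(x) {
  stopifnot(is(x, "InkComponents"))
  x@stats
}

#' @rdname accessors
#' @export
ordinalMetrics <- function(x) {
  stopifnot(is(x, "MetricsReport"))
  x@ordinal
}

#' @rdname accessors
#' @export
binaryMetrics <- function(x) {
  stopifnot(is(x, "MetricsReport"))
  x@binary
}

#' @rdname accessors
#' @export
confusionMatrix6 <- function(x) {
  stopifnot(is(x, "MetricsReport"))
  x@confusion
}

## internal condition helpers: signalled errors carry a class the callers
## (and the CLI) can test for
csError <- function(class, message, ...) {
  stop(structure(class = c(class, "clockscoreError", "error", "condition"),
                 list(message = message, call = sys.call(-1), ...)))
}
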