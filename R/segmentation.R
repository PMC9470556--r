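#' @importFrom EBImage otsu closing makeBrush bwlabel
NULL

# Rule-based segmentation of one B-scan (nz x nx dB image).
# Returns a logical matrix; empty when no tissue is found.
.segmentBscan <- function(img, valid, closingSize, minTissuePixels) {
  empty <- matrix(FALSE, nrow(img), ncol(img))
  v <- img[valid]
  if (length(v) < minTissuePixels) return(empty)
  lo <- min(v); hi <- max(v)
  if (hi - lo < 1e-9) return(empty)
  x01 <- (img - lo) / (hi - lo)
  x01[!valid] <- 0
  x01 <- pmin(pmax(x01, 0), 1)
  th <- EBImage::otsu(x01, range = c(0, 1))
  tissue <- x01 > th & valid
  if (sum(tissue) < minTissuePixels) return(empty)

  brush <- EBImage::makeBrush(closingSize, shape = "disc")
  closed <- EBImage::closing(tissue, brush) > 0

  lbl <- EBImage::bwlabel(closed)
  if (max(lbl) == 0) return(empty)
  sizes <- tabulate(lbl[lbl > 0])
  comp <- lbl == which.max(sizes)
  if (sum(comp) < minTissuePixels) return(empty)

  # Keep the band from the tissue surface down to the axial midline of
  # the tissue extent, per A-line.
  out <- empty
  zIdx <- seq_len(nrow(img))
  for (x in seq_len(ncol(img))) {
    zz <- zIdx[comp[, x]]
    if (!length(zz)) next
    surface <- min(zz)
    bottom <- max(zz)
    mid <- floor((surface + bottom) / 2)
    keep <- comp[, x] & zIdx >= surface & zIdx <= mid
    out[, x] <- keep
  }
  out
}

#' @describeIn segmentUpperMuscle method for a [ContrastSet-class]: uses
#'   its intensity channel and validity mask.
#' @export
setMethod("segmentUpperMuscle", "ContrastSet", function(x, ...) {
  segmentUpperMuscle(intensityDb(x), valid = validMask(x), ...)
})

#' @describeIn segmentUpperMuscle method for a dB intensity array.
#'
#' Segments, B-scan by B-scan, the upper half of the tail musculature on
#' the intensity channel: Otsu thresholding restricted to valid pixels,
#' morphological closing, largest connected component, then per A-line the
#' band from the detected tissue surface down to the axial midline of the
#' tissue extent. The lower half is excluded because multiple scattering
#' degrades intensity and inflates birefringence there. The output is
#' deterministic; B-scans without tissue above threshold yield an empty
#' mask slice.
#'
#' @param valid logical array of analyzable voxels (same grid as `x`).
#' @param closingSize diameter of the morphological closing brush, px.
#' @param minTissuePixels minimum tissue pixels for a B-scan to count as
#'   containing tissue.
#' @export
setMethod("segmentUpperMuscle", "array", function(x, valid = NULL,
                                                  closingSize = 5L,
                                                  minTissuePixels = 50L,
                                                  ...) {
  stopifnot(length(dim(x)) == 3L)
  if (is.null(valid)) valid <- array(TRUE, dim = dim(x))
  stopifnot(identical(dim(valid), dim(x)))
  d <- dim(x)
  mask <- array(FALSE, dim = d)
  nEmpty <- 0L
  for (y in seq_len(d[3L])) {
    sl <- .segmentBscan(x[, , y], valid[, , y], closingSize,
                        minTissuePixels)
    if (!any(sl)) nEmpty <- nEmpty + 1L
    mask[, , y] <- sl
  }
  if (nEmpty > 0L) {
    message(nEmpty, " B-scan(s) contained no tissue above threshold")
  }
  new("MaskVolume", mask = mask, provenance = "rule_based")
})

#' @rdname accessors
setMethod("maskArray", "MaskVolume", function(x) x@mask)

#' @rdname accessors
setMethod("provenance", "MaskVolume", function(x) x@provenance)

setMethod("show", "MaskVolume", function(object) {
  d <- dim(object@mask)
  cat(sprintf("MaskVolume (%s): %d x %d x %d, %d voxels set (%.1f%%)\n",
              object@provenance, d[1], d[2], d[3], sum(object@mask),
              100 * mean(object@mask)))
})

#' Truth mask as a MaskVolume
#'
#' Wraps a phantom ground-truth mask in a [MaskVolume-class] so it can be
#' used interchangeably with rule-based segmentations downstream.
#'
#' @param phantom a [PhantomVolume-class].
#' @param name mask name, default `"upper_muscle"`.
#' @return a [MaskVolume-class] with provenance `"truth"`.
#' @export
truthMaskVolume <- function(phantom, name = "upper_muscle") {
  new("MaskVolume", mask = truthMask(phantom, name), provenance = "truth")
}

#' Segmentation accuracy metrics
#'
#' Pixelwise accuracy and Dice coefficient of a predicted mask against a
#' reference: `accuracy = 100 (TP + TN) / total`,
#' `dice = 2 TP / (2 TP + FP + FN)`; the Dice of two empty masks is 1 by
#' definition.
#'
#' @param pred,truth [MaskVolume-class] objects (or logical arrays) on the
#'   same grid.
#' @return list with `pixel_accuracy` (percent) and `dice` (fraction).
#' @export
segmentationAccuracy <- function(pred, truth) {
  p <- if (is(pred, "MaskVolume")) maskArray(pred) else pred
  t <- if (is(truth, "MaskVolume")) maskArray(truth) else truth
  if (!identical(dim(p), dim(t))) stop("mask grids do not match")
  tp <- sum(p & t)
  tn <- sum(!p & !t)
  fp <- sum(p & !t)
  fn <- sum(!p & t)
  dice <- if (tp + fp + fn == 0) 1 else 2 * tp / (2 * tp + fp + fn)
  list(pixel_accuracy = 100 * (tp + tn) / length(p), dice = dice)
}
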