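#' Accessors for pipeline objects
#'
#' Small accessor generics shared by the volume classes: `acqGeometry`
#' returns the [AcquisitionGeometry-class] attached to an object,
#' `nRepeats` the number of repeated B-scans, `jonesEntry` one complex
#' entry of the measured Jones matrices as a `(repeat, z, x, y)` array,
#' `tissueLabels`/`truthMask` the phantom ground truth, `maskArray` and
#' `provenance` the contents of a [MaskVolume-class], and
#' `intensityDb`, `birefringenceMap`, `reliabilityMap`, `dopuMap`,
#' `octaMap`, `validMask` the channels of a [ContrastSet-class].
#'
#' @param x an object of the documented class.
#' @param i,j row/column of the Jones matrix entry (1 or 2).
#' @param name name of a ground-truth mask, e.g. `"upper_muscle"`.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("acqGeometry", function(x) standardGeneric("acqGeometry"))

#' @rdname accessors
#' @export
setGeneric("nRepeats", function(x) standardGeneric("nRepeats"))

#' @rdname accessors
#' @export
setGeneric("jonesEntry", function(x, i, j) standardGeneric("jonesEntry"))

#' @rdname accessors
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' @rdname accessors
#' @export
setGeneric("truthMask", function(x, name) standardGeneric("truthMask"))

#' @rdname accessors
#' @export
setGeneric("maskArray", function(x) standardGeneric("maskArray"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(x) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("intensityDb", function(x) standardGeneric("intensityDb"))

#' @rdname accessors
#' @export
setGeneric("birefringenceMap", function(x) standardGeneric("birefringenceMap"))

#' @rdname accessors
#' @export
setGeneric("reliabilityMap", function(x) standardGeneric("reliabilityMap"))

#' @rdname accessors
#' @export
setGeneric("dopuMap", function(x) standardGeneric("dopuMap"))

#' @rdname accessors
#' @export
setGeneric("octaMap", function(x) standardGeneric("octaMap"))

#' @rdname accessors
#' @export
setGeneric("validMask", function(x) standardGeneric("validMask"))

#' Segment the upper tail musculature
#'
#' Generic for [segmentUpperMuscle()]; methods exist for
#' [ContrastSet-class] and for a plain dB intensity array plus validity
#' mask.
#'
#' @param x a [ContrastSet-class] or a dB intensity array `(z, x, y)`.
#' @param ... passed to the array method (notably `valid`, `closingSize`,
#'   `minTissuePixels`).
#' @export
setGeneric("segmentUpperMuscle", function(x, ...) {
  standardGeneric("segmentUpperMuscle")
})
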