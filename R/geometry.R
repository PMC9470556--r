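#' Construct an acquisition geometry
#'
#' Creates an [AcquisitionGeometry-class] with defaults matching the
#' 1.31 um JM-OCT prototype (6 x 8 mm field of view, 512 x 128 lateral
#' pixels, depth pitch 7.24 um, 12.8 ms inter-scan time, four repeats,
#' 36 mm scan lens, 3.5 mm beam).
#'
#' @param fovFast,fovSlow field of view along the fast/slow axis, mm.
#' @param nFast,nSlow,nDepth pixel counts along fast, slow and depth axes.
#' @param depthPitch depth pixel separation, um.
#' @param centerWavelength source center wavelength, um.
#' @param interScanTime inter-scan time between repeats, ms.
#' @param nRepeats repeated B-scans per location.
#' @param axialResolution,lateralResolution optical resolutions, um. The
#'   lateral value is a measured instrument constant, not derived from the
#'   numerical aperture.
#' @param focalLength scan lens focal length, mm.
#' @param beamDiameter beam diameter at the lens, mm.
#' @return an [AcquisitionGeometry-class] object.
#' @examples
#' g <- AcquisitionGeometry()
#' lateralPixelPitch(g@fovFast, g@nFast, display = TRUE)  # 11.7 um
#' @export
AcquisitionGeometry <- function(fovFast = 6, fovSlow = 8,
                                nFast = 512, nSlow = 128, nDepth = 400,
                                depthPitch = 7.24, centerWavelength = 1.31,
                                interScanTime = 12.8, nRepeats = 4,
                                axialResolution = 14.0,
                                lateralResolution = 18.1,
                                focalLength = 36, beamDiameter = 3.5) {
  new("AcquisitionGeometry",
      fovFast = fovFast, fovSlow = fovSlow,
      nFast = nFast, nSlow = nSlow, nDepth = nDepth,
      depthPitch = depthPitch, centerWavelength = centerWavelength,
      interScanTime = interScanTime, nRepeats = nRepeats,
      axialResolution = axialResolution,
      lateralResolution = lateralResolution,
      focalLength = focalLength, beamDiameter = beamDiameter)
}

#' @rdname accessors
setMethod("acqGeometry", "AcquisitionGeometry", function(x) x)

#' @rdname accessors
setMethod("nRepeats", "AcquisitionGeometry", function(x) as.integer(x@nRepeats))

setMethod("show", "AcquisitionGeometry", function(object) {
  cat("AcquisitionGeometry\n")
  cat(sprintf("  FoV: %g x %g mm (%d x %d px), depth %d px at %g um\n",
              object@fovFast, object@fovSlow, as.integer(object@nFast),
              as.integer(object@nSlow), as.integer(object@nDepth),
              object@depthPitch))
  cat(sprintf("  lambda_c %g um, inter-scan %g ms, %d repeats\n",
              object@centerWavelength, object@interScanTime,
              as.integer(object@nRepeats)))
  cat(sprintf("  pixel pitch %s x %s um, effective NA %s\n",
              format(lateralPixelPitch(object@fovFast, object@nFast,
                                       display = TRUE)),
              format(lateralPixelPitch(object@fovSlow, object@nSlow,
                                       display = TRUE)),
              format(effectiveNA(object@beamDiameter, object@focalLength,
                                 display = TRUE))))
})

#' Lateral pixel pitch
#'
#' Converts a lateral field of view and its pixel count to the pixel pitch
#' in micrometers, `1000 * fov / nPixels`. With `display = TRUE` the value
#' is rounded half-up to one decimal, the precision at which such pitches
#' are conventionally reported (6 mm / 512 px -> 11.7 um,
#' 8 mm / 512 px -> 15.6 um).
#'
#' @param fov field of view, mm.
#' @param nPixels number of pixels across `fov`.
#' @param display round for display? Internal computations should keep the
#'   default `FALSE` (full precision).
#' @return pixel pitch in um.
#' @export
lateralPixelPitch <- function(fov, nPixels, display = FALSE) {
  if (!is.finite(fov) || fov <= 0) .geometryError("fov must be positive")
  if (!is.finite(nPixels) || nPixels < 1) {
    .geometryError("nPixels must be at least 1")
  }
  p <- 1000 * fov / nPixels
  if (display) roundHalfUp(p, 1L) else p
}

#' Physical extent of a pixel run
#'
#' Converts a pixel count and pitch (um) to millimeters,
#' `nPixels * pitch / 1000`; e.g. 30 depth pixels at 7.24 um span 0.2 mm,
#' and a 200-pixel fast-axis run at 6000/512 um spans 2.3 mm.
#'
#' @param nPixels number of pixels (>= 0).
#' @param pitch pixel pitch, um.
#' @param display round half-up to one decimal for display?
#' @return extent in mm.
#' @export
physicalExtent <- function(nPixels, pitch, display = FALSE) {
  if (!is.finite(nPixels) || nPixels < 0) {
    .geometryError("nPixels must be non-negative")
  }
  if (!is.finite(pitch) || pitch <= 0) .geometryError("pitch must be positive")
  e <- nPixels * pitch / 1000
  if (display) roundHalfUp(e, 1L) else e
}

#' Effective OCTA frame rate
#'
#' The rate at which complete repeat groups are acquired,
#' `1000 / (nRepeats * interScanTime)` Hz (12.8 ms with 4 repeats gives
#' 20 Hz after rounding for display).
#'
#' @param interScanTime inter-scan time, ms.
#' @param nRepeats repeats per location (>= 1).
#' @param display round to the nearest integer Hz for display?
#' @return frame rate in Hz.
#' @export
effectiveOctaFrameRate <- function(interScanTime, nRepeats, display = FALSE) {
  if (!is.finite(interScanTime) || interScanTime <= 0) {
    .geometryError("interScanTime must be positive")
  }
  if (!is.finite(nRepeats) || nRepeats < 1) {
    .geometryError("nRepeats must be at least 1")
  }
  f <- 1000 / (nRepeats * interScanTime)
  if (display) roundHalfUp(f, 0L) else f
}

#' Effective numerical aperture
#'
#' `(beamDiameter / 2) / focalLength`. For display the value is truncated
#' (not rounded) to three decimals, matching how such apertures are quoted
#' (3.5 mm beam with a 36 mm lens: 0.04861 -> 0.048).
#'
#' @param beamDiameter beam diameter, mm.
#' @param focalLength focal length, mm.
#' @param display truncate to three decimals for display?
#' @return dimensionless NA estimate.
#' @export
effectiveNA <- function(beamDiameter, focalLength, display = FALSE) {
  if (!is.finite(beamDiameter) || beamDiameter <= 0) {
    .geometryError("beamDiameter must be positive")
  }
  if (!is.finite(focalLength) || focalLength <= 0) {
    .geometryError("focalLength must be positive")
  }
  na <- (beamDiameter / 2) / focalLength
  if (display) truncDecimals(na, 3L) else na
}

#' Birefringence per radian of local retardation
#'
#' Conversion factor between the local round-trip retardation delta
#' (radians accrued over one depth pixel) and birefringence:
#' `dn = delta * lambda_c / (4 pi * dz)`. The factor is
#' `lambda_c / (4 pi * dz)` per radian; the maximum unambiguous
#' birefringence (delta = pi) is `lambda_c / (4 dz)`, 0.04523 at the
#' default geometry.
#'
#' @param geometry an [AcquisitionGeometry-class].
#' @return dn per radian of local round-trip retardation.
#' @seealso [maxBirefringence()]
#' @export
birefringenceScale <- function(geometry) {
  stopifnot(is(geometry, "AcquisitionGeometry"))
  geometry@centerWavelength / (4 * pi * geometry@depthPitch)
}

#' Maximum unambiguous birefringence
#'
#' `lambda_c / (4 dz)`, the birefringence mapped from a local retardation
#' of pi radians per depth pixel; values above this ceiling alias.
#'
#' @inheritParams birefringenceScale
#' @return maximum measurable dn.
#' @export
maxBirefringence <- function(geometry) {
  stopifnot(is(geometry, "AcquisitionGeometry"))
  geometry@centerWavelength / (4 * geometry@depthPitch)
}

# Geometry <-> list conversion for the JSON pipeline config.
.geometryToList <- function(g) {
  out <- lapply(slotNames(g), function(nm) slot(g, nm))
  names(out) <- slotNames(g)
  out
}

.geometryFromList <- function(lst) {
  known <- names(formals(AcquisitionGeometry))
  bad <- setdiff(names(lst), known)
  if (length(bad)) {
    stop("unknown geometry field(s): ", paste(bad, collapse = ", "))
  }
  do.call(AcquisitionGeometry, lst)
}
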