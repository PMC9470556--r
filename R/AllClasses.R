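#' @import methods
NULL

#' Acquisition geometry of a Jones-matrix OCT scan
#'
#' Holds the scan, pixel, wavelength and timing parameters of a swept-source
#' JM-OCT acquisition. Defaults mirror a 1.31 um passive-polarization-delay
#' prototype: 6 x 8 mm field of view sampled with 512 x 128 lateral pixels,
#' depth pixel separation 7.24 um, 12.8 ms inter-scan time with four
#' repeated B-scans per location, axial/lateral resolutions 14.0/18.1 um,
#' a 36 mm scan lens and a 3.5 mm beam.
#'
#' Pixel pitches and derived quantities are never stored; they are computed
#' on demand by [lateralPixelPitch()], [physicalExtent()],
#' [effectiveOctaFrameRate()], [effectiveNA()] and [birefringenceScale()].
#'
#' The axis convention used throughout the package is
#' `(repeat, depth z, fast x, slow y)` with depth increasing away from the
#' probe.
#'
#' @slot fovFast,fovSlow lateral field of view along the fast/slow scan
#'   axis, mm.
#' @slot nFast,nSlow,nDepth pixel counts along fast, slow and depth axes.
#' @slot depthPitch depth pixel separation, um.
#' @slot centerWavelength source center wavelength, um.
#' @slot interScanTime time between repeated B-scans at one location, ms.
#' @slot nRepeats number of repeated B-scans per location (>= 2 for OCTA).
#' @slot axialResolution,lateralResolution optical resolutions in tissue, um.
#' @slot focalLength scan lens focal length, mm.
#' @slot beamDiameter collimated beam diameter at the lens, mm.
#' @export
setClass("AcquisitionGeometry",
  representation(
    fovFast = "numeric", fovSlow = "numeric",
    nFast = "numeric", nSlow = "numeric", nDepth = "numeric",
    depthPitch = "numeric", centerWavelength = "numeric",
    interScanTime = "numeric", nRepeats = "numeric",
    axialResolution = "numeric", lateralResolution = "numeric",
    focalLength = "numeric", beamDiameter = "numeric"
  )
)

setValidity("AcquisitionGeometry", function(object) {
  msgs <- character()
  for (nm in slotNames(object)) {
    v <- slot(object, nm)
    if (length(v) != 1L || !is.finite(v)) {
      msgs <- c(msgs, sprintf("slot '%s' must be a single finite number", nm))
    } else if (v <= 0) {
      msgs <- c(msgs, sprintf("slot '%s' must be strictly positive", nm))
    }
  }
  for (nm in c("nFast", "nSlow", "nDepth", "nRepeats")) {
    v <- slot(object, nm)
    if (length(v) == 1L && is.finite(v) && v != round(v)) {
      msgs <- c(msgs, sprintf("slot '%s' must be a whole number", nm))
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Phantom tissue volume with ground truth
#'
#' A voxel label volume on the `(z, x, y)` grid together with the tissue
#' class catalogue that defines the optical properties of each label and a
#' set of binary ground-truth masks (one per class plus `musculature` and
#' `upper_muscle`, the region quantified downstream).
#'
#' @slot labels integer array `(z, x, y)` of row indices into
#'   `classCatalogue`.
#' @slot classCatalogue data.frame with columns `name`, `reflectivity`,
#'   `birefringence`, `optic_axis`, `depolarization`, `flow`.
#' @slot truthMasks named list of logical arrays on the label grid.
#' @slot geometry the [AcquisitionGeometry-class] the phantom emulates.
#' @export
setClass("PhantomVolume",
  representation(
    labels = "array",
    classCatalogue = "data.frame",
    truthMasks = "list",
    geometry = "AcquisitionGeometry"
  )
)

setValidity("PhantomVolume", function(object) {
  msgs <- character()
  lab <- object@labels
  if (length(dim(lab)) != 3L) msgs <- c(msgs, "labels must be a 3-d array")
  ncls <- nrow(object@classCatalogue)
  if (length(lab) && (min(lab) < 1L || max(lab) > ncls)) {
    msgs <- c(msgs, "labels must index rows of classCatalogue")
  }
  need <- c("name", "reflectivity", "birefringence", "optic_axis",
            "depolarization", "flow")
  if (!all(need %in% names(object@classCatalogue))) {
    msgs <- c(msgs, "classCatalogue is missing required columns")
  }
  for (nm in names(object@truthMasks)) {
    m <- object@truthMasks[[nm]]
    if (!is.logical(m) || !identical(dim(m), dim(lab))) {
      msgs <- c(msgs, sprintf("truth mask '%s' must be logical on the label grid", nm))
    }
  }
  tm <- object@truthMasks
  if (all(c("upper_muscle", "musculature") %in% names(tm)) &&
      any(tm$upper_muscle & !tm$musculature)) {
    msgs <- c(msgs, "upper_muscle must be contained in musculature")
  }
  if (length(msgs)) msgs else TRUE
})

#' Measured Jones-matrix volume
#'
#' The complex 2 x 2 Jones matrix measured at every voxel for every
#' repeated B-scan, stored as a complex array of dimension
#' `(repeat, z, x, y, 2, 2)`, plus the acquisition geometry and the linear
#' noise-floor intensity of the measurement.
#'
#' @slot entries complex array `(repeat, z, x, y, 2, 2)`.
#' @slot geometry an [AcquisitionGeometry-class]; `nRepeats` must equal
#'   `dim(entries)[1]`.
#' @slot noiseFloor linear intensity of the noise floor (per-entry mean
#'   squared magnitude of the additive noise).
#' @export
setClass("JonesVolume",
  representation(
    entries = "array",
    geometry = "AcquisitionGeometry",
    noiseFloor = "numeric"
  )
)

setValidity("JonesVolume", function(object) {
  msgs <- character()
  d <- dim(object@entries)
  if (length(d) != 6L || d[5L] != 2L || d[6L] != 2L) {
    msgs <- c(msgs, "entries must have dimension (repeat, z, x, y, 2, 2)")
  } else if (d[1L] != object@geometry@nRepeats) {
    msgs <- c(msgs, "repeat count must equal geometry nRepeats")
  }
  if (!is.complex(object@entries)) msgs <- c(msgs, "entries must be complex")
  if (anyNA(object@entries)) msgs <- c(msgs, "entries must be finite")
  if (length(object@noiseFloor) != 1L || !is.finite(object@noiseFloor) ||
      object@noiseFloor < 0) {
    msgs <- c(msgs, "noiseFloor must be a single non-negative number")
  }
  if (length(msgs)) msgs else TRUE
})

#' Co-registered multi-contrast volume set
#'
#' The four contrast channels computed from one [JonesVolume-class], all on
#' the `(z, x, y)` voxel grid: scattering intensity in dB, local
#' birefringence (refractive-index difference, dimensionless) with its
#' reliability channel, degree of polarization uniformity, and (when at
#' least two repeats were acquired) the OCTA decorrelation. `valid` flags
#' voxels whose intensity exceeds the noise floor margin.
#'
#' @slot intensity dB array `(z, x, y)`.
#' @slot birefringence local birefringence array, in `[0, lambda/(4 dz)]`.
#' @slot reliability birefringence reliability in `[0, 1]`.
#' @slot dopu degree of polarization uniformity in `[0, 1]`.
#' @slot octa decorrelation in `[0, 1]`; zero-length array when the
#'   acquisition had fewer than two repeats.
#' @slot valid logical intensity validity mask.
#' @slot geometry the shared [AcquisitionGeometry-class].
#' @export
setClass("ContrastSet",
  representation(
    intensity = "array",
    birefringence = "array",
    reliability = "array",
    dopu = "array",
    octa = "array",
    valid = "array",
    geometry = "AcquisitionGeometry"
  )
)

setValidity("ContrastSet", function(object) {
  msgs <- character()
  d <- dim(object@intensity)
  if (length(d) != 3L) msgs <- c(msgs, "intensity must be a 3-d array")
  for (nm in c("birefringence", "reliability", "dopu", "valid")) {
    if (!identical(dim(slot(object, nm)), d)) {
      msgs <- c(msgs, sprintf("channel '%s' must share the intensity grid", nm))
    }
  }
  if (length(object@octa) && !identical(dim(object@octa), d)) {
    msgs <- c(msgs, "octa must share the intensity grid (or be empty)")
  }
  eps <- 1e-9
  rng <- function(x) if (length(x)) range(x) else c(0, 0)
  if (length(object@dopu) && (rng(object@dopu)[1L] < -eps ||
                              rng(object@dopu)[2L] > 1 + eps)) {
    msgs <- c(msgs, "dopu must lie in [0, 1]")
  }
  if (length(object@octa) && (rng(object@octa)[1L] < -eps ||
                              rng(object@octa)[2L] > 1 + eps)) {
    msgs <- c(msgs, "octa must lie in [0, 1]")
  }
  if (length(object@birefringence)) {
    dnMax <- object@geometry@centerWavelength / (4 * object@geometry@depthPitch)
    r <- rng(object@birefringence)
    if (r[1L] < -eps || r[2L] > dnMax + eps) {
      msgs <- c(msgs, "birefringence must lie in [0, lambda/(4 dz)]")
    }
  }
  if (length(msgs)) msgs else TRUE
})

#' Binary segmentation mask volume
#'
#' @slot mask logical array `(z, x, y)`.
#' @slot provenance one of `"truth"`, `"rule_based"`, `"learned"`,
#'   `"manual"`.
#' @export
setClass("MaskVolume",
  representation(mask = "array", provenance = "character")
)

setValidity("MaskVolume", function(object) {
  msgs <- character()
  if (!is.logical(object@mask) || length(dim(object@mask)) != 3L) {
    msgs <- c(msgs, "mask must be a logical 3-d array")
  }
  if (!object@provenance %in% c("truth", "rule_based", "learned", "manual")) {
    msgs <- c(msgs, "unknown provenance")
  }
  if (length(msgs)) msgs else TRUE
})

#' Longitudinal cohort simulation settings
#'
#' Group sizes, imaging schedule, per-group exponential death hazards, and
#' the group-difference profile of the contrast summaries, used by
#' [simulateCohort()]. See [cohortSpec()] for the defaults and their
#' provenance.
#'
#' @slot nControl,nTumor animals per group.
#' @slot timepoints imaging days post-injection.
#' @slot hazardControl,hazardTumor exponential death hazards, per day.
#' @slot baseline named numeric: control-group means of the per-animal
#'   summaries.
#' @slot withinSd named numeric: animal-to-animal standard deviations.
#' @slot effects data.frame of tumor-minus-control mean shifts by `dpi`.
#' @export
setClass("CohortSpec",
  representation(
    nControl = "numeric", nTumor = "numeric",
    timepoints = "numeric",
    hazardControl = "numeric", hazardTumor = "numeric",
    baseline = "numeric", withinSd = "numeric",
    effects = "data.frame"
  )
)

setValidity("CohortSpec", function(object) {
  msgs <- character()
  if (object@nControl < 1 || object@nTumor < 1) {
    msgs <- c(msgs, "group sizes must be >= 1")
  }
  if (!length(object@timepoints)) msgs <- c(msgs, "timepoints must be nonempty")
  if (any(object@timepoints <= 0)) msgs <- c(msgs, "timepoints must be positive")
  if (object@hazardControl < 0 || object@hazardTumor < 0) {
    msgs <- c(msgs, "hazards must be non-negative")
  }
  qs <- c("mean_intensity_db", "mean_birefringence", "mean_dopu",
          "abnormality_pct", "vessel_density_pct", "mean_vessel_length_mm")
  if (!all(qs %in% names(object@baseline))) {
    msgs <- c(msgs, "baseline must name all summary quantities")
  }
  if (!all(qs %in% names(object@withinSd))) {
    msgs <- c(msgs, "withinSd must name all summary quantities")
  }
  if (!all(c("dpi", qs) %in% names(object@effects))) {
    msgs <- c(msgs, "effects must have dpi plus all summary quantities")
  }
  if (length(msgs)) msgs else TRUE
})

#' Two-group survival analysis result
#'
#' Kaplan-Meier curves per group plus the log-rank observed/expected event
#' table, the observed-over-expected hazard ratio with its 95% confidence
#' interval, and the log-rank test.
#'
#' @slot kmControl,kmTumor product-limit curves as data.frames with columns
#'   `time`, `n_risk`, `n_event`, `n_censor`, `surv`.
#' @slot observed,expected named numeric of length 2 (`control`, `tumor`):
#'   observed and expected event counts.
#' @slot hr hazard ratio `(O_C/E_C)/(O_T/E_T)`.
#' @slot hrCi 95% confidence interval for `hr`.
#' @slot chisq,p log-rank chi-squared statistic (1 df) and two-sided
#'   p-value.
#' @export
setClass("SurvivalResult",
  representation(
    kmControl = "data.frame", kmTumor = "data.frame",
    observed = "numeric", expected = "numeric",
    hr = "numeric", hrCi = "numeric",
    chisq = "numeric", p = "numeric"
  )
)

setValidity("SurvivalResult", function(object) {
  msgs <- character()
  if (length(object@observed) != 2L || length(object@expected) != 2L) {
    msgs <- c(msgs, "observed/expected must have one entry per group")
  }
  if (abs(sum(object@observed) - sum(object@expected)) > 1e-9) {
    msgs <- c(msgs, "total expected events must equal total observed events")
  }
  for (km in list(object@kmControl, object@kmTumor)) {
    if (nrow(km) && any(diff(km$surv) > 1e-12)) {
      msgs <- c(msgs, "survival curves must be non-increasing")
    }
  }
  if (length(msgs)) msgs else TRUE
})
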