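#' Default tissue class catalogue
#'
#' The optical-property table used by [buildPhantom()]. Values are chosen
#' to reproduce the contrast directions seen in vivo: ordered muscle is
#' strongly birefringent (dn = 1.5e-3) while disorganized tumor tissue is
#' nearly isotropic (dn = 2e-4) but scatters about twice as strongly;
#' pigmented skin depolarizes (axis scrambling strength 0.8); vessels carry
#' flow. Background has zero reflectivity by definition.
#'
#' @return data.frame with one row per tissue class and columns `name`,
#'   `reflectivity` (linear backscatter), `birefringence` (dn),
#'   `optic_axis` (rad in `[0, pi)`), `depolarization` (0-1) and `flow`.
#' @export
tissueCatalogue <- function() {
  data.frame(
    name = c("background", "skin_pigment", "muscle", "tumor", "vessel",
             "scar"),
    reflectivity = c(0, 0.9, 0.5, 1.0, 0.55, 0.7),
    birefringence = c(0, 2e-4, 1.5e-3, 2e-4, 1e-4, 2.2e-3),
    optic_axis = c(0, 0.9, 0.6, 0.3, 0.2, 1.1),
    depolarization = c(0, 0.8, 0.05, 0.1, 0.05, 0.1),
    flow = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE
  )
}

# Row index of a class name in a catalogue.
.classId <- function(catalogue, name) {
  id <- match(name, catalogue$name)
  if (is.na(id)) stop("tissue class not in catalogue: ", name)
  id
}

#' Build a zebrafish-tail phantom volume
#'
#' Constructs a labelled voxel volume emulating a sagittal block of the
#' zebrafish tail at the injection site: water/agar background above a
#' thin pigmented skin layer whose surface undulates gently, the tail
#' musculature below the skin, an optional ellipsoidal tumor embedded in
#' the upper musculature (tumor voxels replace muscle voxels only), and a
#' few straight vessels running along the fast axis inside the upper
#' musculature. All ground-truth masks, including the `upper_muscle`
#' region quantified downstream (the musculature from the tissue surface
#' to its axial midline), are returned alongside the labels.
#'
#' @param geometry an [AcquisitionGeometry-class]; `nDepth`, `nFast`,
#'   `nSlow` are overridden by the grid actually built.
#' @param nz,nx,ny grid size (depth, fast, slow); minimum 64 x 64 x 8.
#' @param includeTumor place the tumor ellipsoid?
#' @param tumorSemiAxes ellipsoid semi-axes in pixels `(z, x, y)`; must fit
#'   inside the musculature.
#' @param tumorCenter ellipsoid center `(z, x, y)` in pixels; default is
#'   the middle of the upper musculature at the lateral volume center.
#' @param nVessels number of vessels (tubes along x).
#' @param vesselRadius vessel tube radius, pixels.
#' @param surfaceFrac,bottomFrac fractional depth of the mean tissue
#'   surface and of the tissue bottom.
#' @param skinThickness skin layer thickness, pixels.
#' @param catalogue tissue class catalogue, see [tissueCatalogue()].
#' @param seed integer seed; the build is deterministic given the seed.
#' @return a [PhantomVolume-class].
#' @export
buildPhantom <- function(geometry = AcquisitionGeometry(),
                         nz = 256, nx = 256, ny = 32,
                         includeTumor = TRUE,
                         tumorSemiAxes = NULL,
                         tumorCenter = NULL,
                         nVessels = 3, vesselRadius = 3,
                         surfaceFrac = 0.12, bottomFrac = 0.85,
                         skinThickness = 3,
                         catalogue = tissueCatalogue(),
                         seed = 1L) {
  if (nz < 64 || nx < 64 || ny < 8) {
    stop("phantom grid must be at least 64 (z) x 64 (x) x 8 (y)")
  }
  set.seed(seed)
  nz <- as.integer(nz); nx <- as.integer(nx); ny <- as.integer(ny)

  idBg <- .classId(catalogue, "background")
  idSkin <- .classId(catalogue, "skin_pigment")
  idMuscle <- .classId(catalogue, "muscle")
  idTumor <- .classId(catalogue, "tumor")
  idVessel <- .classId(catalogue, "vessel")

  labels <- array(idBg, dim = c(nz, nx, ny))

  # Gently undulating tissue surface, constant along y up to a small tilt.
  xs <- seq_len(nx)
  ys <- seq_len(ny)
  surf <- round(nz * surfaceFrac +
                nz * 0.03 * cos(2 * pi * xs / nx) +
                runif(1, -1, 1))
  tilt <- round((ys - mean(ys)) * 0.1)
  zBottom <- as.integer(round(nz * bottomFrac))

  zIdx <- seq_len(nz)
  surfMat <- outer(surf, tilt, `+`)               # (x, y) surface depth
  surfMat <- matrix(pmax(2, pmin(surfMat, nz - 10)), nx, ny)
  for (y in ys) {
    sy <- surfMat[, y]
    skin <- outer(zIdx, sy, function(z, s) z >= s & z < s + skinThickness)
    musc <- outer(zIdx, sy, function(z, s) z >= s + skinThickness) &
      (zIdx <= zBottom)
    sl <- labels[, , y]
    sl[skin] <- idSkin
    sl[musc] <- idMuscle
    labels[, , y] <- sl
  }

  muscleOriginal <- labels == idMuscle

  # Tumor ellipsoid, replacing muscle voxels only.
  if (includeTumor) {
    if (is.null(tumorSemiAxes)) {
      tumorSemiAxes <- c(round(nz * 0.10), round(nx * 0.14),
                         max(2, round(ny * 0.30)))
    }
    muscTop <- min(surfMat) + skinThickness
    if (is.null(tumorCenter)) {
      tumorCenter <- c(round((muscTop + (muscTop + zBottom) / 2) / 2) +
                         round(tumorSemiAxes[1]),
                       round(nx / 2), round(ny / 2))
    }
    lo <- tumorCenter - tumorSemiAxes
    hi <- tumorCenter + tumorSemiAxes
    if (any(lo < c(muscTop, 1, 1)) || any(hi > c(zBottom, nx, ny))) {
      stop("tumor ellipsoid does not fit inside the musculature")
    }
    zz <- (zIdx - tumorCenter[1]) / tumorSemiAxes[1]
    xx <- (xs - tumorCenter[2]) / tumorSemiAxes[2]
    yy <- (ys - tumorCenter[3]) / tumorSemiAxes[3]
    ell <- outer(outer(zz^2, xx^2, `+`), yy^2, `+`) <= 1
    labels[ell & muscleOriginal] <- idTumor
  }

  # Vessels: straight tubes along x in the upper musculature, avoiding
  # the tumor so that flow voxels keep their label.
  if (nVessels > 0) {
    muscTopMat <- surfMat + skinThickness
    midMat <- round((surfMat + zBottom) / 2)
    for (v in seq_len(nVessels)) {
      zc <- round(runif(1, min(muscTopMat) + vesselRadius + 2,
                        min(midMat) - vesselRadius - 2))
      yc <- round(runif(1, vesselRadius + 1, ny - vesselRadius))
      zz <- (zIdx - zc)^2
      yy <- (ys - yc)^2
      tube <- outer(zz, yy, `+`) <= vesselRadius^2   # (z, y)
      for (y in ys[colSums(tube) > 0 & ys >= 1]) {
        sel <- tube[, y]
        sl <- labels[, , y]
        repl <- outer(sel, rep(TRUE, nx)) & (sl == idMuscle)
        sl[repl] <- idVessel
        labels[, , y] <- sl
      }
    }
  }

  # Ground-truth masks.
  masks <- lapply(seq_len(nrow(catalogue)), function(i) labels == i)
  names(masks) <- catalogue$name
  musculature <- masks$muscle | masks$tumor | masks$vessel
  upper <- array(FALSE, dim = dim(labels))
  midMat <- round((surfMat + zBottom) / 2)
  for (y in ys) {
    upper[, , y] <- outer(zIdx, midMat[, y], `<=`)
  }
  masks$musculature <- musculature
  masks$upper_muscle <- musculature & upper

  geometry@nDepth <- nz
  geometry@nFast <- nx
  geometry@nSlow <- ny

  new("PhantomVolume", labels = labels, classCatalogue = catalogue,
      truthMasks = masks, geometry = geometry)
}

#' @rdname accessors
setMethod("acqGeometry", "PhantomVolume", function(x) x@geometry)

#' @rdname accessors
setMethod("tissueLabels", "PhantomVolume", function(x) x@labels)

#' @rdname accessors
setMethod("truthMask", "PhantomVolume", function(x, name) {
  m <- x@truthMasks[[name]]
  if (is.null(m)) stop("no truth mask named '", name, "'")
  m
})

setMethod("show", "PhantomVolume", function(object) {
  d <- dim(object@labels)
  cat(sprintf("PhantomVolume: %d x %d x %d (z, x, y)\n", d[1], d[2], d[3]))
  tab <- table(factor(object@classCatalogue$name[object@labels],
                      levels = object@classCatalogue$name))
  for (nm in names(tab)) {
    if (tab[[nm]] > 0) cat(sprintf("  %-12s %d voxels\n", nm, tab[[nm]]))
  }
})

#' Noiseless cumulative round-trip Jones matrices
#'
#' Propagates polarized light down every A-line of a phantom. Each voxel k
#' acts as a linear retarder
#' `L_k = R(theta_k) diag(exp(+i phi_k/2), exp(-i phi_k/2)) R(-theta_k)`
#' with round-trip retardation `phi_k = 4 pi dn_k dz / lambda_c`; the
#' matrix observed at depth z is the backscatter amplitude
#' `sqrt(reflectivity_z)` times the ordered product `L_z ... L_1`.
#' Depolarizing classes perturb the optic axis voxel-by-voxel with a
#' zero-mean Gaussian angle of standard deviation
#' `depolarization * pi/3`, modelling sub-resolution axis scrambling
#' within the Jones formalism.
#'
#' @param phantom a [PhantomVolume-class].
#' @param seed seed for the axis-scrambling draws (deterministic given the
#'   seed). Ignored if no class depolarizes.
#' @return complex array `(z, x, y, 2, 2)` of noiseless Jones matrices.
#' @export
cumulativeJones <- function(phantom, seed = 1L) {
  stopifnot(is(phantom, "PhantomVolume"))
  set.seed(seed)
  lab <- phantom@labels
  cat <- phantom@classCatalogue
  g <- phantom@geometry
  d <- dim(lab)
  nz <- d[1]; nxy <- d[2] * d[3]

  refl <- matrix(cat$reflectivity[lab], nrow = nz)
  dn <- matrix(cat$birefringence[lab], nrow = nz)
  ax <- matrix(cat$optic_axis[lab], nrow = nz)
  depol <- matrix(cat$depolarization[lab], nrow = nz)
  phi <- 4 * pi * dn * g@depthPitch / g@centerWavelength

  p11 <- rep(1 + 0i, nxy); p22 <- p11
  p12 <- rep(0 + 0i, nxy); p21 <- p12

  j11 <- matrix(0 + 0i, nz, nxy); j12 <- j11; j21 <- j11; j22 <- j11
  axisJitterSd <- pi / 3

  for (z in seq_len(nz)) {
    theta <- ax[z, ] + rnorm(nxy) * depol[z, ] * axisJitterSd
    h <- phi[z, ] / 2
    ep <- complex(modulus = 1, argument = h)
    em <- Conj(ep)
    c2 <- cos(theta)^2
    s2 <- sin(theta)^2
    sc <- 1i * sin(h) * sin(2 * theta)
    l11 <- ep * c2 + em * s2
    l22 <- ep * s2 + em * c2
    # off-diagonals equal for a linear retarder
    n11 <- l11 * p11 + sc * p21
    n12 <- l11 * p12 + sc * p22
    n21 <- sc * p11 + l22 * p21
    n22 <- sc * p12 + l22 * p22
    p11 <- n11; p12 <- n12; p21 <- n21; p22 <- n22
    a <- sqrt(refl[z, ])
    j11[z, ] <- a * p11; j12[z, ] <- a * p12
    j21[z, ] <- a * p21; j22[z, ] <- a * p22
  }

  out <- array(0 + 0i, dim = c(d, 2, 2))
  out[, , , 1, 1] <- j11; out[, , , 1, 2] <- j12
  out[, , , 2, 1] <- j21; out[, , , 2, 2] <- j22
  out
}

#' Render a speckled, noisy repeated measurement
#'
#' Turns noiseless cumulative Jones matrices into a measured
#' [JonesVolume-class]. Each repeat r observes
#' `J_r = a_r * J + N_r`, where `a` is a unit-mean-power complex
#' circular-Gaussian speckle field shared by all four matrix entries
#' (fully developed speckle: per-voxel intensity is exponentially
#' distributed). Static tissue keeps the same speckle realization across
#' repeats; voxels flagged as flowing redraw it independently per repeat,
#' which is what the decorrelation angiography detects. `N_r` is complex
#' white noise whose per-entry mean power sets the noise floor,
#' `floor = meanSignal * 10^(-snrDb/10)`.
#'
#' With `snrDb = -Inf` the signal is switched off and only the noise floor
#' (referenced to the would-be mean signal) is rendered.
#'
#' @param jones complex array `(z, x, y, 2, 2)` from [cumulativeJones()].
#' @param geometry an [AcquisitionGeometry-class]; its `nRepeats` sets the
#'   number of rendered repeats.
#' @param snrDb signal-to-noise ratio of the mean tissue signal over the
#'   noise floor, dB.
#' @param flowMask logical `(z, x, y)` array of flowing voxels, e.g.
#'   `truthMask(phantom, "vessel")`; `NULL` for a fully static scene.
#' @param seed integer seed; rendering is deterministic given the seed.
#' @return a [JonesVolume-class].
#' @export
renderMeasurement <- function(jones, geometry, snrDb = 25,
                              flowMask = NULL, seed = 1L) {
  d <- dim(jones)
  stopifnot(length(d) == 5L, d[4] == 2L, d[5] == 2L)
  if (!is.finite(snrDb) && snrDb > 0) stop("snrDb must be finite or -Inf")
  set.seed(seed)
  nrep <- as.integer(geometry@nRepeats)
  nvox <- prod(d[1:3])

  e11 <- as.vector(jones[, , , 1, 1]); e12 <- as.vector(jones[, , , 1, 2])
  e21 <- as.vector(jones[, , , 2, 1]); e22 <- as.vector(jones[, , , 2, 2])
  sig <- (Mod(e11)^2 + Mod(e12)^2 + Mod(e21)^2 + Mod(e22)^2) / 4
  tissue <- sig > 0
  meanSig <- if (any(tissue)) mean(sig[tissue]) else 1
  gain <- if (is.finite(snrDb)) 1 else 0
  floorLin <- meanSig * if (is.finite(snrDb)) 10^(-snrDb / 10) else 1
  noiseAmp <- sqrt(floorLin)     # cgauss() draws have unit mean power

  flow <- if (is.null(flowMask)) rep(FALSE, nvox) else as.vector(flowMask)
  stopifnot(length(flow) == nvox)

  cgauss <- function(n) complex(real = rnorm(n), imaginary = rnorm(n)) /
    sqrt(2)

  aStatic <- cgauss(nvox)
  nFlow <- sum(flow)

  entries <- array(0 + 0i, dim = c(nrep, d[1:3], 2, 2))
  eList <- list(e11, e12, e21, e22)
  ij <- list(c(1, 1), c(1, 2), c(2, 1), c(2, 2))
  for (r in seq_len(nrep)) {
    a <- aStatic
    if (nFlow > 0) a[flow] <- cgauss(nFlow)
    for (k in 1:4) {
      meas <- gain * a * eList[[k]] + noiseAmp * cgauss(nvox)
      entries[r, , , , ij[[k]][1], ij[[k]][2]] <-
        array(meas, dim = d[1:3])
    }
  }

  new("JonesVolume", entries = entries, geometry = geometry,
      noiseFloor = floorLin)
}

#' @rdname accessors
setMethod("acqGeometry", "JonesVolume", function(x) x@geometry)

#' @rdname accessors
setMethod("nRepeats", "JonesVolume", function(x) dim(x@entries)[1L])

#' @rdname accessors
setMethod("jonesEntry", "JonesVolume", function(x, i, j) {
  stopifnot(i %in% 1:2, j %in% 1:2)
  d <- dim(x@entries)
  array(x@entries[, , , , i, j], dim = d[1:4])
})

setMethod("show", "JonesVolume", function(object) {
  d <- dim(object@entries)
  cat(sprintf("JonesVolume: %d repeats, %d x %d x %d (z, x, y)\n",
              d[1], d[2], d[3], d[4]))
  cat(sprintf("  noise floor %.3g (linear intensity)\n", object@noiseFloor))
})

# Repeat-averaged Jones matrices as a (z, x, y, 2, 2) complex array.
.meanJones <- function(jones) {
  e <- jones@entries
  m <- colMeans(e, dims = 1L)
  m
}
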