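#' Scattering intensity in dB
#'
#' The conventional JM-OCT intensity channel: per voxel, the four
#' absolute-squared Jones matrix entries are averaged and the result is
#' averaged over the repeated B-scans before conversion to decibels.
#' Voxels whose linear intensity falls at or below the floor are clamped
#' to the floor value and flagged invalid.
#'
#' @param jones a [JonesVolume-class].
#' @param floorLin linear intensity floor; defaults to the volume's noise
#'   floor (or a tiny positive value for a noiseless volume).
#' @param marginDb validity margin above the floor, dB: a voxel is valid
#'   when its linear intensity exceeds `floorLin * 10^(marginDb/10)`.
#' @return list with `db` (dB array `(z, x, y)`), `linear` (the linear
#'   mean intensity), and `valid` (logical array).
#' @export
scatterIntensity <- function(jones, floorLin = NULL, marginDb = 6) {
  stopifnot(is(jones, "JonesVolume"))
  e <- jones@entries
  d <- dim(e)
  lin <- (Mod(e[, , , , 1, 1])^2 + Mod(e[, , , , 1, 2])^2 +
          Mod(e[, , , , 2, 1])^2 + Mod(e[, , , , 2, 2])^2) / 4
  if (d[1L] > 1L) lin <- colMeans(lin, dims = 1L) else dim(lin) <- d[2:4]
  if (is.null(floorLin)) {
    floorLin <- if (jones@noiseFloor > 0) jones@noiseFloor else
      max(lin) * 1e-12
  }
  if (floorLin <= 0) floorLin <- 1e-300
  valid <- lin > floorLin * 10^(marginDb / 10)
  db <- 10 * log10(pmax(lin, floorLin))
  list(db = db, linear = lin, valid = valid)
}

# Eigenvalue phase splitting of 2 x 2 complex matrices given as flat
# vectors; returns |arg(l1) - arg(l2)| wrapped to [0, pi].
.eigPhaseSplit <- function(m11, m12, m21, m22) {
  tr <- m11 + m22
  dt <- m11 * m22 - m12 * m21
  disc <- sqrt(as.complex(tr * tr - 4 * dt))
  l1 <- (tr + disc) / 2
  l2 <- (tr - disc) / 2
  ratio <- l1 / l2
  delta <- abs(Arg(ratio))
  delta[!is.finite(delta)] <- NA_real_
  delta
}

#' Local birefringence and reliability
#'
#' Estimates depth-resolved birefringence by local Jones matrix analysis.
#' The repeats are averaged, the local matrix over an axial separation of
#' `deltaZ` pixels is formed as `Jloc(z) = J(z + deltaZ) J(z)^{-1}`, and
#' the local round-trip retardation is read off the eigenvalue phases,
#' `delta = |arg(l1) - arg(l2)|` wrapped to `[0, pi]` (the tie at pi is
#' kept at pi, the measurable ceiling). The retardation maps to
#' birefringence via `dn = delta * lambda_c / (4 pi deltaZ dz)`, see
#' [birefringenceScale()].
#'
#' The estimator is pluggable through `estimator`: any function mapping
#' the four flat local-matrix entry vectors to a retardation vector can
#' replace the eigen-analysis default (e.g. a maximum a posteriori
#' estimator).
#'
#' Reliability grows monotonically with local SNR and is exactly zero at
#' or below `marginDb` above the noise floor; singular local matrices
#' (sub-floor intensity) get reliability 0 and, by convention, dn = 0.
#' The last `deltaZ` depth planes, where no local matrix exists, are
#' likewise zero with zero reliability.
#'
#' @param jones a [JonesVolume-class].
#' @param deltaZ axial separation in depth pixels (default 1).
#' @param marginDb SNR margin above the noise floor, dB, below which the
#'   estimate is deemed unreliable.
#' @param estimator retardation estimator; see Details.
#' @return list with `dn` (birefringence array) and `reliability`.
#' @export
localBirefringence <- function(jones, deltaZ = 1L, marginDb = 6,
                               estimator = .eigPhaseSplit) {
  stopifnot(is(jones, "JonesVolume"))
  g <- jones@geometry
  m <- .meanJones(jones)
  d <- dim(m)[1:3]
  nz <- d[1L]
  deltaZ <- as.integer(deltaZ)
  if (nz < deltaZ + 1L) stop("volume too shallow for axial separation")

  up <- (deltaZ + 1L):nz     # z + deltaZ
  lo <- 1L:(nz - deltaZ)     # z

  a11 <- as.vector(m[up, , , 1, 1]); a12 <- as.vector(m[up, , , 1, 2])
  a21 <- as.vector(m[up, , , 2, 1]); a22 <- as.vector(m[up, , , 2, 2])
  b11 <- as.vector(m[lo, , , 1, 1]); b12 <- as.vector(m[lo, , , 1, 2])
  b21 <- as.vector(m[lo, , , 2, 1]); b22 <- as.vector(m[lo, , , 2, 2])

  det <- b11 * b22 - b12 * b21
  l11 <- (a11 * b22 - a12 * b21) / det
  l12 <- (a12 * b11 - a11 * b12) / det
  l21 <- (a21 * b22 - a22 * b21) / det
  l22 <- (a22 * b11 - a21 * b12) / det

  delta <- estimator(l11, l12, l21, l22)
  scale <- birefringenceScale(g) / deltaZ
  dnFlat <- delta * scale

  # Reliability from the local SNR of both planes involved.
  linUp <- (Mod(a11)^2 + Mod(a12)^2 + Mod(a21)^2 + Mod(a22)^2) / 4
  linLo <- (Mod(b11)^2 + Mod(b12)^2 + Mod(b21)^2 + Mod(b22)^2) / 4
  floorLin <- if (jones@noiseFloor > 0) jones@noiseFloor else
    max(linUp, linLo) * 1e-12
  snr <- pmin(linUp, linLo) / (floorLin * 10^(marginDb / 10))
  rel <- pmax(0, 1 - 1 / pmax(snr, .Machine$double.eps))

  bad <- !is.finite(dnFlat) | rel <= 0
  dnFlat[bad] <- 0
  rel[bad] <- 0

  dn <- array(0, dim = d)
  reliability <- array(0, dim = d)
  dn[lo, , ] <- array(dnFlat, dim = c(nz - deltaZ, d[2L], d[3L]))
  reliability[lo, , ] <- array(rel, dim = c(nz - deltaZ, d[2L], d[3L]))
  dn <- pmin(dn, maxBirefringence(g))
  list(dn = dn, reliability = reliability)
}

#' Degree of polarization uniformity
#'
#' Measures how uniform the backscattered polarization state is within a
#' small spatial kernel. For each incident polarization channel (the two
#' columns of the repeat-averaged Jones matrix), the Stokes vector of the
#' backscattered field is formed per voxel
#' (`I = |E_H|^2 + |E_V|^2`, `Q = |E_H|^2 - |E_V|^2`,
#' `U = 2 Re(E_H conj(E_V))`, `V = -2 Im(E_H conj(E_V))`), normalized by
#' `I`, averaged over the kernel, and the norm of the averaged vector is
#' taken. The two channels are averaged and the result clipped to
#' `[0, 1]`. Polarization-preserving tissue gives values near 1;
#' depolarizing tissue (e.g. pigment) scrambles the state across the
#' kernel and pushes the value towards 0.
#'
#' Zero-intensity voxels are excluded from the kernel average; a kernel
#' with no contributing voxel is set to 1 by convention and flagged in
#' the returned `defined` mask.
#'
#' @param jones a [JonesVolume-class].
#' @param kernel odd window sizes `(z, x, y)`; default 5 x 5 x 1.
#' @return list with `dopu` (array in `[0, 1]`) and `defined` (logical:
#'   kernel had at least one contributing voxel).
#' @export
dopuVolume <- function(jones, kernel = c(5L, 5L, 1L)) {
  stopifnot(is(jones, "JonesVolume"), all(kernel >= 1L),
            all(kernel %% 2L == 1L))
  m <- .meanJones(jones)
  d <- dim(m)[1:3]

  total <- array(0, dim = d)
  anyDef <- array(FALSE, dim = d)
  for (ch in 1:2) {
    eh <- array(m[, , , 1, ch], dim = d)
    ev <- array(m[, , , 2, ch], dim = d)
    ih <- Mod(eh)^2
    iv <- Mod(ev)^2
    I <- ih + iv
    w <- I > 0
    Iw <- ifelse(w, I, 1)                 # avoid 0/0; excluded anyway
    cr <- eh * Conj(ev)
    q <- ifelse(w, (ih - iv) / Iw, 0)
    u <- ifelse(w, 2 * Re(cr) / Iw, 0)
    v <- ifelse(w, -2 * Im(cr) / Iw, 0)
    wn <- array(as.numeric(w), dim = d)
    sw <- boxSum3d(wn, kernel)
    def <- sw > 0
    swSafe <- ifelse(def, sw, 1)
    qb <- boxSum3d(q, kernel) / swSafe
    ub <- boxSum3d(u, kernel) / swSafe
    vb <- boxSum3d(v, kernel) / swSafe
    dch <- sqrt(qb^2 + ub^2 + vb^2)
    dch[!def] <- 1                        # convention: undefined -> 1
    total <- total + dch
    anyDef <- anyDef | def
  }
  list(dopu = pmin(pmax(total / 2, 0), 1), defined = anyDef)
}

#' OCTA decorrelation
#'
#' Label-free angiographic contrast from the repeated B-scans. The complex
#' field per repeat is the coherent sum of the first Jones column
#' (`E = J11 + J21`). For each adjacent repeat pair the windowed complex
#' correlation
#' `rho_ij = |sum_w E_i conj(E_j)| / sqrt(sum_w |E_i|^2 sum_w |E_j|^2)`
#' is computed over a small window in the B-scan plane, and the
#' decorrelation is `1 - mean(rho)` over the adjacent pairs. Static tissue
#' (identical speckle across repeats) decorrelates only through noise;
#' flowing blood redraws the speckle between repeats and decorrelates
#' strongly. Taking the modulus makes the measure invariant to global
#' phase drift between repeats.
#'
#' @param jones a [JonesVolume-class] with at least two repeats.
#' @param window odd window sizes `(z, x)` in the B-scan plane.
#' @param valid optional logical mask; voxels outside it are set to 0
#'   (intensity masking separates tissue from background).
#' @return decorrelation array `(z, x, y)` in `[0, 1]`.
#' @export
octaDecorrelation <- function(jones, window = c(5L, 5L), valid = NULL) {
  stopifnot(is(jones, "JonesVolume"))
  e <- jones@entries
  nrep <- dim(e)[1L]
  if (nrep < 2L) {
    stop("OCTA requires at least two repeated B-scans per location")
  }
  d <- dim(e)[2:4]
  k <- c(as.integer(window), 1L)

  fields <- lapply(seq_len(nrep), function(r) {
    array(e[r, , , , 1, 1] + e[r, , , , 2, 1], dim = d)
  })
  pw <- lapply(fields, function(f) boxSum3d(Re(f * Conj(f)), k))

  rhoSum <- array(0, dim = d)
  for (r in seq_len(nrep - 1L)) {
    num <- Mod(boxSum3d(fields[[r]] * Conj(fields[[r + 1L]]), k))
    den <- sqrt(pw[[r]] * pw[[r + 1L]])
    rho <- ifelse(den > 0, num / den, 1)
    rhoSum <- rhoSum + rho
  }
  octa <- pmin(pmax(1 - rhoSum / (nrep - 1L), 0), 1)
  if (!is.null(valid)) octa[!valid] <- 0
  octa
}

#' Compute all contrast channels
#'
#' Runs [scatterIntensity()], [localBirefringence()], [dopuVolume()] and,
#' when at least two repeats exist, [octaDecorrelation()] on a measured
#' volume and assembles the co-registered [ContrastSet-class].
#'
#' @param jones a [JonesVolume-class].
#' @param dopuKernel odd DOPU kernel sizes `(z, x, y)`.
#' @param octaWindow odd OCTA correlation window `(z, x)`.
#' @param deltaZ axial separation of the local Jones analysis, pixels.
#' @param marginDb noise-floor margin for validity and reliability, dB.
#' @return a [ContrastSet-class].
#' @export
computeContrasts <- function(jones, dopuKernel = c(5L, 5L, 1L),
                             octaWindow = c(5L, 5L), deltaZ = 1L,
                             marginDb = 6) {
  si <- scatterIntensity(jones, marginDb = marginDb)
  lb <- localBirefringence(jones, deltaZ = deltaZ, marginDb = marginDb)
  dp <- dopuVolume(jones, kernel = dopuKernel)
  octa <- if (nRepeats(jones) >= 2L) {
    octaDecorrelation(jones, window = octaWindow, valid = si$valid)
  } else {
    array(numeric(0), dim = c(0, 0, 0))
  }
  new("ContrastSet",
      intensity = si$db, birefringence = lb$dn,
      reliability = lb$reliability, dopu = dp$dopu,
      octa = octa, valid = si$valid, geometry = jones@geometry)
}

#' @rdname accessors
setMethod("acqGeometry", "ContrastSet", function(x) x@geometry)

#' @rdname accessors
setMethod("intensityDb", "ContrastSet", function(x) x@intensity)

#' @rdname accessors
setMethod("birefringenceMap", "ContrastSet", function(x) x@birefringence)

#' @rdname accessors
setMethod("reliabilityMap", "ContrastSet", function(x) x@reliability)

#' @rdname accessors
setMethod("dopuMap", "ContrastSet", function(x) x@dopu)

#' @rdname accessors
setMethod("octaMap", "ContrastSet", function(x) x@octa)

#' @rdname accessors
setMethod("validMask", "ContrastSet", function(x) x@valid)

setMethod("show", "ContrastSet", function(object) {
  d <- dim(object@intensity)
  cat(sprintf("ContrastSet: %d x %d x %d (z, x, y)\n", d[1], d[2], d[3]))
  cat(sprintf("  intensity [%.1f, %.1f] dB, %.1f%% valid\n",
              min(object@intensity), max(object@intensity),
              100 * mean(object@valid)))
  cat(sprintf("  birefringence [0, %.3g], DOPU median %.3f\n",
              max(object@birefringence), stats::median(object@dopu)))
  if (length(object@octa)) {
    cat(sprintf("  OCTA decorrelation median %.3f\n",
                stats::median(object@octa)))
  } else cat("  OCTA: not available (single repeat)\n")
})
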