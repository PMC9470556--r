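# Shared fixtures, built in code at test time.

# Small geometry matched to a (nz, nx, ny) grid.
testGeometry <- function(nz = 80, nx = 64, ny = 8, nRepeats = 4) {
  AcquisitionGeometry(nDepth = nz, nFast = nx, nSlow = ny,
                      nRepeats = nRepeats)
}

# Homogeneous-slab phantom: tissue everywhere muscle below a thin skin,
# optionally with zero depolarization so that the cumulative matrices are
# exact retarder products.
slabPhantom <- function(nz = 80, nx = 64, ny = 8, nRepeats = 1,
                        deterministicAxes = TRUE, seed = 7) {
  catal <- tissueCatalogue()
  if (deterministicAxes) catal$depolarization[] <- 0
  buildPhantom(testGeometry(nz, nx, ny, nRepeats), nz = nz, nx = nx,
               ny = ny, includeTumor = FALSE, nVessels = 0,
               surfaceFrac = 0.05, skinThickness = 1,
               catalogue = catal, seed = seed)
}

# Wrap a noiseless cumulative Jones array as a single-repeat JonesVolume.
noiselessVolume <- function(jones, geometry) {
  geometry@nRepeats <- 1
  new("JonesVolume", entries = array(jones, dim = c(1, dim(jones))),
      geometry = geometry, noiseFloor = 0)
}

# JonesVolume with identical entries across repeats (plus optional
# per-repeat global phase), for OCTA identities.
repeatedVolume <- function(field, nRepeats = 4, phases = rep(0, nRepeats),
                           geometry = NULL) {
  d <- dim(field)  # (z, x, y)
  if (is.null(geometry)) {
    geometry <- AcquisitionGeometry(nDepth = d[1], nFast = d[2],
                                    nSlow = d[3], nRepeats = nRepeats)
  }
  e <- array(0 + 0i, dim = c(nRepeats, d, 2, 2))
  for (r in seq_len(nRepeats)) {
    ph <- complex(modulus = 1, argument = phases[r])
    e[r, , , , 1, 1] <- ph * field
    e[r, , , , 2, 1] <- ph * field
    e[r, , , , 1, 2] <- ph * field
    e[r, , , , 2, 2] <- ph * field
  }
  new("JonesVolume", entries = e, geometry = geometry, noiseFloor = 1e-6)
}

# Default mid-size rendered phantom shared by several test files
# (computed once per test run).
renderedFixture <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      ph <- buildPhantom(testGeometry(128, 96, 12), nz = 128, nx = 96,
                         ny = 12, includeTumor = TRUE, nVessels = 2,
                         seed = 11)
      jn <- cumulativeJones(ph, seed = 12)
      jv <- renderMeasurement(jn, acqGeometry(ph), snrDb = 25,
                              flowMask = truthMask(ph, "vessel"),
                              seed = 13)
      cache <<- list(phantom = ph, jones = jv,
                     contrasts = computeContrasts(jv))
    }
    cache
  }
})
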