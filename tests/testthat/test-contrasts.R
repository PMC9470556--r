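test_that("scatter intensity matches the per-voxel definition", {
  # unit-magnitude entries -> linear mean 1 -> 0 dB
  f <- array(1 + 0i, dim = c(4, 5, 3))
  jv <- repeatedVolume(f, nRepeats = 2)
  si <- scatterIntensity(jv, floorLin = 1e-12)
  expect_equal(max(abs(si$db)), 0)
  expect_true(all(si$valid))

  # all-zero voxel clamps to the floor and is flagged invalid
  f0 <- f
  f0[1, 1, 1] <- 0
  jv0 <- repeatedVolume(f0, nRepeats = 2)
  si0 <- scatterIntensity(jv0, floorLin = 1e-8)
  expect_equal(si0$db[1, 1, 1], 10 * log10(1e-8))
  expect_false(si0$valid[1, 1, 1])

  # random volume vs elementwise brute-force recomputation
  set.seed(42)
  d <- c(3, 6, 4, 5)
  e <- array(complex(real = rnorm(prod(d) * 4),
                     imaginary = rnorm(prod(d) * 4)),
             dim = c(d, 2, 2))
  g <- AcquisitionGeometry(nDepth = d[2], nFast = d[3], nSlow = d[4],
                           nRepeats = d[1])
  jv <- new("JonesVolume", entries = e, geometry = g, noiseFloor = 1e-9)
  si <- scatterIntensity(jv)
  brute <- array(0, dim = d[2:4])
  for (z in 1:d[2]) for (x in 1:d[3]) for (y in 1:d[4]) {
    acc <- 0
    for (r in 1:d[1]) {
      acc <- acc + sum(Mod(e[r, z, x, y, , ])^2) / 4
    }
    brute[z, x, y] <- 10 * log10(acc / d[1])
  }
  expect_lt(max(abs(si$db - brute)), 1e-9)
})

test_that("local birefringence recovers analytic retarders", {
  # identity matrices at all depths -> zero retardation everywhere
  d <- c(20, 8, 4)
  e <- array(0 + 0i, dim = c(1, d, 2, 2))
  e[1, , , , 1, 1] <- 1
  e[1, , , , 2, 2] <- 1
  g <- AcquisitionGeometry(nDepth = d[1], nFast = d[2], nSlow = d[3],
                           nRepeats = 1)
  jv <- new("JonesVolume", entries = e, geometry = g, noiseFloor = 1e-12)
  lb <- localBirefringence(jv)
  expect_equal(max(lb$dn), 0)

  # noiseless homogeneous muscle slab: dn = 1.5e-3 within 1e-6
  ph <- slabPhantom()
  jn <- cumulativeJones(ph, seed = 3)
  jvn <- noiselessVolume(jn, acqGeometry(ph))
  lbn <- localBirefringence(jvn)
  sel <- truthMask(ph, "muscle") & lbn$reliability > 0
  expect_gt(sum(sel), 1000)
  expect_lt(abs(mean(lbn$dn[sel]) - 1.5e-3), 1e-6)

  # speckled phantom at SNR 25: reliability-weighted masked mean within 10%
  fx <- renderedFixture()
  cs <- fx$contrasts
  musc <- truthMask(fx$phantom, "muscle") & reliabilityMap(cs) > 0
  rel <- reliabilityMap(cs)[musc]
  rec <- sum(birefringenceMap(cs)[musc] * rel) / sum(rel)
  expect_lt(abs(rec - 1.5e-3) / 1.5e-3, 0.10)

  # retardation ceiling: dn never exceeds lambda/(4 dz)
  expect_lte(max(birefringenceMap(cs)), maxBirefringence(acqGeometry(cs)))
})

test_that("recovered birefringence increases strictly with phantom birefringence", {
  levels <- c(2e-4, 8e-4, 1.5e-3, 2.2e-3, 3e-3)
  rec <- vapply(levels, function(dn) {
    catal <- tissueCatalogue()
    catal$depolarization[] <- 0
    catal$birefringence[catal$name == "muscle"] <- dn
    ph <- buildPhantom(testGeometry(64, 64, 8, 1), nz = 64, nx = 64,
                       ny = 8, includeTumor = FALSE, nVessels = 0,
                       surfaceFrac = 0.05, skinThickness = 1,
                       catalogue = catal, seed = 5)
    jn <- cumulativeJones(ph, seed = 5)
    lb <- localBirefringence(noiselessVolume(jn, acqGeometry(ph)))
    sel <- truthMask(ph, "muscle") & lb$reliability > 0
    mean(lb$dn[sel])
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
  expect_equal(rec, levels, tolerance = 0.02)
})

test_that("DOPU is 1 for uniform states and small for random states", {
  # spatially uniform polarization state -> DOPU = 1 within 1e-12
  f <- array(complex(real = 0.6, imaginary = 0.2), dim = c(6, 6, 3))
  jv <- repeatedVolume(f, nRepeats = 2)
  dv <- dopuVolume(jv, kernel = c(5, 5, 1))
  expect_lt(max(abs(dv$dopu - 1)), 1e-12)
  expect_true(all(dv$defined))

  # degenerate 1x1x1 kernel -> unit norm everywhere
  set.seed(8)
  e <- array(complex(real = rnorm(6 * 6 * 3 * 4),
                     imaginary = rnorm(6 * 6 * 3 * 4)),
             dim = c(1, 6, 6, 3, 2, 2))
  g <- AcquisitionGeometry(nDepth = 6, nFast = 6, nSlow = 3, nRepeats = 1)
  jvr <- new("JonesVolume", entries = e, geometry = g, noiseFloor = 0)
  dv1 <- dopuVolume(jvr, kernel = c(1, 1, 1))
  expect_lt(max(abs(dv1$dopu - 1)), 1e-9)

  # isotropically random states, ~100-voxel kernel: DOPU < 0.3 in >99%
  # of trials (normalized Stokes of circular-Gaussian fields are uniform
  # on the sphere)
  set.seed(31)
  g2 <- AcquisitionGeometry(nDepth = 9, nFast = 11, nSlow = 3,
                            nRepeats = 1)
  n <- 9 * 11 * 3
  trials <- replicate(400, {
    e <- array(complex(real = rnorm(n * 4), imaginary = rnorm(n * 4)),
               dim = c(1, 9, 11, 3, 2, 2))
    jv <- new("JonesVolume", entries = e, geometry = g2, noiseFloor = 0)
    dopuVolume(jv, kernel = c(9, 11, 1))$dopu[5, 6, 2]
  })
  expect_gt(mean(trials < 0.3), 0.99)
})

test_that("DOPU separates depolarizing skin from polarization-preserving muscle", {
  fx <- renderedFixture()
  cs <- fx$contrasts
  ph <- fx$phantom
  v <- validMask(cs)
  skin <- truthMask(ph, "skin_pigment") & v
  musc <- truthMask(ph, "muscle") & v
  expect_gt(mean(dopuMap(cs)[musc]), mean(dopuMap(cs)[skin]) + 0.1)
})

test_that("OCTA decorrelation obeys its exact identities", {
  set.seed(12)
  f <- array(complex(real = rnorm(120), imaginary = rnorm(120)),
             dim = c(6, 5, 4))
  # identical repeats -> decorrelation 0 exactly
  jv <- repeatedVolume(f, nRepeats = 4)
  expect_equal(max(octaDecorrelation(jv)), 0)

  # repeats differing by a global phase only -> still 0
  jvp <- repeatedVolume(f, nRepeats = 4, phases = c(0, 1.1, -2.3, 0.4))
  expect_lt(max(octaDecorrelation(jvp)), 1e-12)

  # fewer than two repeats is unsupported
  jv1 <- noiselessVolume(array(f, dim = c(dim(f), 2, 2)) * 0 + 1,
                         AcquisitionGeometry(nDepth = 6, nFast = 5,
                                             nSlow = 4))
  expect_error(octaDecorrelation(jv1), "two repeated")
})

test_that("OCTA on independent speckle matches the Monte-Carlo expectation", {
  # brute-force oracle: expected decorrelation of two independent
  # complex-Gaussian fields over a 5x5 window
  set.seed(99)
  nMc <- 2e4
  rho <- replicate(nMc %/% 200, {
    a <- complex(real = rnorm(25), imaginary = rnorm(25))
    b <- complex(real = rnorm(25), imaginary = rnorm(25))
    Mod(sum(a * Conj(b))) / sqrt(sum(Mod(a)^2) * sum(Mod(b)^2))
  })
  oracle <- 1 - mean(rho)
  seMc <- stats::sd(1 - rho) / sqrt(length(rho))

  # implementation on a volume of independent repeats
  set.seed(100)
  d <- c(25, 25, 1)
  e <- array(complex(real = rnorm(prod(d) * 16),
                     imaginary = rnorm(prod(d) * 16)),
             dim = c(4, d, 2, 2))
  g <- AcquisitionGeometry(nDepth = d[1], nFast = d[2], nSlow = d[3],
                           nRepeats = 4)
  jv <- new("JonesVolume", entries = e, geometry = g, noiseFloor = 0)
  oc <- octaDecorrelation(jv, window = c(5, 5))
  # central voxels have full windows; decorrelation of adjacent-pair
  # means shares the oracle's per-pair expectation
  ctr <- oc[6:20, 6:20, 1]
  se <- stats::sd(ctr) / sqrt(length(ctr)) + seMc
  expect_lt(abs(mean(ctr) - oracle), 3 * se + 0.02)
})

test_that("flow voxels decorrelate far more than static tissue", {
  fx <- renderedFixture()
  cs <- fx$contrasts
  ph <- fx$phantom
  oc <- octaMap(cs)
  flow <- truthMask(ph, "vessel") & validMask(cs)
  stat <- truthMask(ph, "muscle") & validMask(cs)
  expect_gt(stats::median(oc[flow]) - stats::median(oc[stat]), 0.3)
})

test_that("computeContrasts assembles a valid co-registered set", {
  fx <- renderedFixture()
  cs <- fx$contrasts
  expect_s4_class(cs, "ContrastSet")
  expect_true(validObject(cs))
  d <- dim(intensityDb(cs))
  expect_identical(dim(dopuMap(cs)), d)
  expect_identical(dim(octaMap(cs)), d)
  expect_true(all(dopuMap(cs) >= 0 & dopuMap(cs) <= 1))
  expect_true(all(octaMap(cs) >= 0 & octaMap(cs) <= 1))

  # tumor vs muscle contrast directions
  ph <- fx$phantom
  v <- validMask(cs)
  tum <- truthMask(ph, "tumor") & v
  musc <- truthMask(ph, "muscle") & v
  expect_gt(mean(intensityDb(cs)[tum]), mean(intensityDb(cs)[musc]))
  expect_lt(mean(birefringenceMap(cs)[tum & reliabilityMap(cs) > 0]),
            mean(birefringenceMap(cs)[musc & reliabilityMap(cs) > 0]))
  expect_gt(mean(dopuMap(cs)[tum]), mean(dopuMap(cs)[musc]))
})
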