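test_that("the separable Gaussian filter matches brute-force convolution", {
  set.seed(50)
  a <- array(rnorm(11 * 10 * 9), dim = c(11, 10, 9))
  f <- gaussianFilter3d(a, 1.1)

  # brute-force normalized convolution at a handful of voxels
  r <- ceiling(3 * 1.1)
  g1 <- exp(-((-r:r)^2) / (2 * 1.1^2)); g1 <- g1 / sum(g1)
  bf <- function(z, x, y) {
    num <- 0; wt <- 0
    for (dz in -r:r) for (dx in -r:r) for (dy in -r:r) {
      zz <- z + dz; xx <- x + dx; yy <- y + dy
      if (zz < 1 || zz > 11 || xx < 1 || xx > 10 || yy < 1 || yy > 9) next
      w <- g1[dz + r + 1] * g1[dx + r + 1] * g1[dy + r + 1]
      num <- num + w * a[zz, xx, yy]
      wt <- wt + w
    }
    num / wt
  }
  for (pt in list(c(6, 5, 5), c(1, 1, 1), c(11, 10, 9), c(2, 9, 4))) {
    expect_equal(f[pt[1], pt[2], pt[3]], bf(pt[1], pt[2], pt[3]),
                 tolerance = 1e-6)
  }

  # constants are preserved exactly, including at the borders
  cst <- gaussianFilter3d(array(3.7, dim = c(8, 8, 4)), 1.1)
  expect_lt(max(abs(cst - 3.7)), 1e-12)
})

test_that("en-face projection masks, smooths, projects and crops", {
  g <- AcquisitionGeometry(nDepth = 60, nFast = 64, nSlow = 32)
  oc <- array(0, dim = c(60, 64, 32))

  # all-zero volume -> all-zero projection
  p0 <- octaEnface(oc, geometry = g, depthStart = 10, depthPixels = 30)
  expect_identical(max(p0), 0)
  expect_identical(attr(p0, "depth_extent_mm"), 0.2)

  # single bright voxel: lateral location preserved, value reduced per
  # the kernel normalization (central weight cubed at an interior voxel)
  oc[25, 30, 16] <- 1
  p1 <- octaEnface(oc, geometry = g, depthStart = 10, depthPixels = 30,
                   sigma = 1.1)
  expect_identical(which(p1 == max(p1)),
                   which(matrix(seq_len(64 * 32), 64, 32) ==
                           30 + (16 - 1) * 64))
  r <- ceiling(3 * 1.1)
  g1 <- exp(-((-r:r)^2) / (2 * 1.1^2)); g1 <- g1 / sum(g1)
  expect_equal(max(p1), g1[r + 1]^3, tolerance = 1e-9)

  # the intensity mask removes background voxels before smoothing
  valid <- array(TRUE, dim = dim(oc))
  valid[25, 30, 16] <- FALSE
  p2 <- octaEnface(oc, valid = valid, geometry = g, depthStart = 10,
                   depthPixels = 30)
  expect_identical(max(p2), 0)

  # out-of-bounds windows and ROIs error
  expect_error(octaEnface(oc, geometry = g, depthStart = 40,
                          depthPixels = 30), "depth window")
  expect_error(octaEnface(oc, geometry = g, depthStart = 1,
                          depthPixels = 30, roi = c(60, 1, 10, 10)),
               "ROI")
})

test_that("vessel binarization separates levels and tolerates noise", {
  # flat image -> empty mask with a warning
  expect_warning(m0 <- binarizeVessels(matrix(0.5, 40, 40)), "flat")
  expect_identical(sum(m0), 0L)

  # clean two-level image -> exact vessel set
  img <- matrix(0, 120, 90)
  img[40:80, 30:34] <- 1
  m1 <- binarizeVessels(img)
  expect_identical(m1, img == 1)

  # additive noise: Dice >= 0.95 against the truth
  set.seed(60)
  noisy <- img + matrix(rnorm(length(img), sd = 0.05), nrow(img))
  m2 <- binarizeVessels(noisy)
  acc <- segmentationAccuracy(array(m2, c(1, dim(img))),
                              array(img == 1, c(1, dim(img))))
  expect_gte(acc$dice, 0.95)
})

test_that("vessel metrics match the straight-vessel geometry oracle", {
  pitch <- 6000 / 512
  mask <- matrix(FALSE, 200, 150)
  mask[51:150, 73:77] <- TRUE    # 100 px x 5 px vessel along fast axis

  m <- vesselMetrics(mask, pitch, pitch)
  expect_equal(m$vessel_density_pct, 100 * 500 / (200 * 150),
               tolerance = 1e-12)
  expect_identical(m$n_segments, 1L)
  expect_equal(m$mean_vessel_length_mm, 100 * pitch / 1000,
               tolerance = 0.05)

  # empty mask -> all zero
  m0 <- vesselMetrics(matrix(FALSE, 10, 10), pitch, pitch)
  expect_equal(m0$mean_vessel_length_mm, 0)
  expect_equal(m0$vessel_density_pct, 0)
  expect_identical(m0$n_segments, 0L)

  # two disjoint identical vessels: density doubles, mean length stays
  mask2 <- mask
  mask2[51:150, 100:104] <- TRUE
  m2 <- vesselMetrics(mask2, pitch, pitch)
  expect_equal(m2$vessel_density_pct, 2 * m$vessel_density_pct)
  expect_equal(m2$mean_vessel_length_mm, m$mean_vessel_length_mm,
               tolerance = 1e-12)
  expect_identical(m2$n_segments, 2L)

  # density is invariant under translation inside the ROI
  maskT <- matrix(FALSE, 200, 150)
  maskT[21:120, 10:14] <- TRUE
  expect_equal(vesselMetrics(maskT, pitch, pitch)$vessel_density_pct,
               m$vessel_density_pct)

  # anisotropic pitch: a slow-axis vessel measures with the slow pitch
  maskS <- matrix(FALSE, 200, 150)
  maskS[100:104, 21:120] <- TRUE
  mS <- vesselMetrics(maskS, 6000 / 512, 8000 / 512)
  expect_equal(mS$mean_vessel_length_mm, 100 * 8000 / 512 / 1000,
               tolerance = 0.05)
})

test_that("skeleton length of a straight bar converges to its Euclidean length", {
  for (len in c(60, 100, 140)) {
    mask <- matrix(FALSE, 180, 60)
    mask[20:(19 + len), 28:32] <- TRUE
    m <- vesselMetrics(mask, 10, 10)
    expect_equal(m$total_length_mm, len * 10 / 1000, tolerance = 0.05)
  }
})

test_that("phantom vessels are detected in the en-face projection", {
  fx <- renderedFixture()
  cs <- fx$contrasts
  ph <- fx$phantom
  musc <- truthMask(ph, "musculature")
  zTop <- which(apply(musc, 1, any))[1]
  depthPixels <- min(30L, dim(octaMap(cs))[1] - zTop)
  proj <- octaEnface(cs, depthStart = zTop, depthPixels = depthPixels)
  m <- binarizeVessels(proj)
  met <- vesselMetrics(m, 6000 / 96, 8000 / 12)
  expect_gt(met$vessel_density_pct, 0)

  # phantom without vessels: near-empty mask, lower density
  ph0 <- buildPhantom(testGeometry(128, 96, 12), nz = 128, nx = 96,
                      ny = 12, includeTumor = TRUE, nVessels = 0,
                      seed = 11)
  jn0 <- cumulativeJones(ph0, seed = 12)
  jv0 <- renderMeasurement(jn0, acqGeometry(ph0), snrDb = 25, seed = 13)
  cs0 <- computeContrasts(jv0)
  proj0 <- octaEnface(cs0, depthStart = zTop, depthPixels = depthPixels)
  m0 <- tryCatch(binarizeVessels(proj0), warning = function(w) {
    matrix(FALSE, nrow(proj0), ncol(proj0))
  })
  met0 <- vesselMetrics(m0, 6000 / 96, 8000 / 12)
  expect_gt(met$vessel_density_pct, met0$vessel_density_pct)
})
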