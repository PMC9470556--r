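test_that("masked means reduce to the brute-force voxel loop", {
  fx <- renderedFixture()
  cs <- fx$contrasts
  d <- dim(intensityDb(cs))

  # checkerboard mask vs explicit loop over the central window
  mask <- array((slice.index(array(0, d), 1) +
                   slice.index(array(0, d), 2) +
                   slice.index(array(0, d), 3)) %% 2 == 0, dim = d)
  got <- maskedMeans(cs, mask, bscanWindow = 6)
  ny <- d[3]
  start <- floor((ny - 6) / 2) + 1
  ySel <- start:(start + 5)
  use <- mask & validMask(cs)
  use[, , setdiff(seq_len(ny), ySel)] <- FALSE
  expect_equal(got$mean_intensity_db, mean(intensityDb(cs)[use]),
               tolerance = 1e-12)
  expect_equal(got$mean_dopu, mean(dopuMap(cs)[use]), tolerance = 1e-12)
  rel <- reliabilityMap(cs)[use]
  expect_equal(got$mean_birefringence,
               sum(birefringenceMap(cs)[use] * rel) / sum(rel),
               tolerance = 1e-12)
  expect_identical(got$n_voxels, sum(use))

  # constant channel value under any mask -> that constant
  csC <- cs
  csC@intensity <- array(7.5, d)
  expect_equal(maskedMeans(csC, mask, bscanWindow = 6)$mean_intensity_db,
               7.5)

  # window larger than the volume is clipped with a warning
  expect_warning(big <- maskedMeans(cs, mask, bscanWindow = 500),
                 "clipping")
  expect_gt(big$n_voxels, got$n_voxels)

  # empty mask yields a missing-value record
  expect_warning(na <- maskedMeans(cs, array(FALSE, d), bscanWindow = 6),
                 "empty")
  expect_true(is.na(na$mean_intensity_db))
  expect_identical(na$n_voxels, 0L)
})

test_that("abnormality fraction equals the direct count and is monotone in the threshold", {
  # 3 of 10 voxels below threshold -> 30%
  dn <- array(c(rep(2e-4, 3), rep(1.5e-3, 7)), dim = c(10, 1, 1))
  m <- array(TRUE, dim = c(10, 1, 1))
  expect_equal(abnormalityFraction(dn, m), 30)
  expect_equal(abnormalityFraction(dn, m, threshold = 1e-5), 0)

  # random masks vs brute-force count
  set.seed(14)
  fx <- renderedFixture()
  cs <- fx$contrasts
  d <- dim(birefringenceMap(cs))
  for (rep in 1:5) {
    mask <- array(runif(prod(d)) < 0.3, dim = d)
    got <- abnormalityFraction(cs, mask)
    use <- mask & reliabilityMap(cs) > 0
    brute <- 100 * sum(birefringenceMap(cs)[use] < 0.0006) / sum(use)
    expect_equal(got, brute, tolerance = 1e-12)
  }

  # monotone non-decreasing in the threshold
  ths <- c(1e-4, 3e-4, 6e-4, 1e-3, 2e-3)
  mask <- truthMask(fx$phantom, "upper_muscle")
  fr <- vapply(ths, function(t) abnormalityFraction(cs, mask,
                                                    threshold = t),
               numeric(1))
  expect_true(all(diff(fr) >= 0))

  # empty mask -> missing value
  expect_warning(v <- abnormalityFraction(cs, array(FALSE, d)), "empty")
  expect_true(is.na(v))
})

test_that("noiseless tumor phantom abnormality equals the tumor mask fraction", {
  ph <- buildPhantom(testGeometry(96, 72, 10, 1), nz = 96, nx = 72,
                     ny = 10, includeTumor = TRUE, nVessels = 0,
                     seed = 6)
  jn <- cumulativeJones(ph, seed = 6)
  lb <- localBirefringence(noiselessVolume(jn, acqGeometry(ph)))
  mask <- truthMask(ph, "upper_muscle")
  got <- abnormalityFraction(lb$dn, mask, reliability = lb$reliability)
  truthFrac <- 100 * sum(truthMask(ph, "tumor") & mask) / sum(mask)
  expect_gt(truthFrac, 2)
  expect_equal(got, truthFrac, tolerance = 0.15)
})

test_that("rank sum test is exact for small samples and calibrated for large ones", {
  # hand enumeration: U_a = 0, two-sided p = 2/6
  r <- rankSumTest(c(1, 2), c(3, 4))
  expect_identical(r$method, "exact")
  expect_equal(r$U, 0)
  expect_equal(r$p, 1 / 3)

  # identical multisets -> p = 1
  expect_equal(rankSumTest(c(5, 5, 8), c(5, 5, 8))$p, 1)

  # exact branch agrees with wilcox.test when there are no ties
  set.seed(3)
  for (rep in 1:5) {
    a <- rnorm(5); b <- rnorm(6)
    expect_equal(rankSumTest(a, b)$p,
                 stats::wilcox.test(a, b)$p.value, tolerance = 1e-12)
  }

  # normal branch tracks wilcox.test's corrected approximation
  set.seed(4)
  a <- rnorm(15); b <- rnorm(18)
  expect_equal(rankSumTest(a, b)$p,
               stats::wilcox.test(a, b, exact = FALSE)$p.value,
               tolerance = 1e-6)

  # invariance under strictly monotone transforms of the pooled values
  expect_equal(rankSumTest(exp(a), exp(b))$p, rankSumTest(a, b)$p)
  expect_equal(rankSumTest(a^3, b^3)$U, rankSumTest(a, b)$U)

  # empty group errors
  expect_error(rankSumTest(numeric(0), 1), "nonempty")
})

test_that("rank sum type-I error at the study's group sizes is near nominal", {
  set.seed(9)
  rej <- mean(replicate(4000, rankSumTest(stats::rnorm(10),
                                          stats::rnorm(13))$p < 0.05))
  expect_gte(rej, 0.035)
  expect_lte(rej, 0.065)
})

test_that("group summaries follow the documented box-whisker rules", {
  tab <- data.frame(
    group = rep(c("control", "tumor"), c(5, 1)),
    dpi = 11,
    val = c(1, 2, 3, 4, 5, 9)
  )
  gs <- groupSummary(tab, "val", 11)
  ctl <- gs[gs$group == "control", ]
  expect_equal(ctl$median, 3)
  expect_equal(ctl$q25, 2)   # type-7 linear interpolation
  expect_equal(ctl$q75, 4)
  expect_equal(c(ctl$lower, ctl$upper), c(1, 5))

  # single value: median = min = max
  tum <- gs[gs$group == "tumor", ]
  expect_equal(c(tum$median, tum$lower, tum$upper), c(9, 9, 9))

  # duplicating the median leaves it unchanged
  tab2 <- rbind(tab, data.frame(group = "control", dpi = 11, val = 3))
  expect_equal(groupSummary(tab2, "val", 11)[1, "median"], 3)

  # outliers under the Tukey rule
  tab3 <- data.frame(group = "control", dpi = 7,
                     val = c(10, 11, 12, 13, 14, 40))
  gs3 <- groupSummary(tab3, "val", 7)
  expect_identical(gs3$n_outliers, 1L)
  expect_equal(attr(gs3, "outliers")$control, 40)
  # min-max whiskers flag nothing
  gs4 <- groupSummary(tab3, "val", 7, whiskerRule = "minmax")
  expect_identical(gs4$n_outliers, 0L)
  expect_equal(gs4$upper, 40)

  # no data at a day -> empty summary
  expect_identical(nrow(groupSummary(tab, "val", 21)), 0L)
})
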