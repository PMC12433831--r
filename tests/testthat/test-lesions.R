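test_that("diagonal chains merge under 8- but not 4-connectivity", {
  m <- matrix(FALSE, 5, 5)
  m[cbind(c(1, 2), c(1, 2))] <- TRUE
  m[5, 5] <- TRUE
  expect_identical(max(labelComponents(m, 8L)), 2L)
  expect_identical(max(labelComponents(m, 4L)), 3L)
  expect_identical(max(floodFillOracle(m, 8L)), 2L)
  expect_identical(max(floodFillOracle(m, 4L)), 3L)
})

test_that("component labeling agrees with the flood-fill oracle on random grids", {
  set.seed(99)
  for (i in 1:25) {
    m <- matrix(runif(32 * 32) < runif(1, 0.2, 0.6), 32, 32)
    for (conn in c(4L, 8L)) {
      expect_identical(
        canonicalLabels(labelComponents(m, conn)),
        canonicalLabels(floodFillOracle(m, conn))
      )
    }
  }
})

test_that("size filters follow the calibrated thresholds", {
  ps <- 0.13
  nr <- 40L
  ## single pixel: 0.0169 um2 passes the 0.01 um2 inclusive minimum
  m <- matrix(0L, nr, nr)
  m[5, 5] <- 1L
  mask <- matrix(TRUE, nr, nr)
  det <- extractLesions(m, mask, ps)
  expect_identical(nrow(det), 1L)
  expect_equal(det$areaUm2, 0.0169, tolerance = 1e-12)
  expect_false(det$isMacro)
  ## 591 px = 9.9879 um2 is not a macrolesion; 592 px = 10.0048 um2 is
  for (n in c(591L, 592L)) {
    m2 <- matrix(0L, nr, nr)
    m2[seq_len(n)] <- 1L  # column-major block, 8-connected
    det2 <- extractLesions(m2, mask, ps)
    expect_identical(nrow(det2), 1L)
    expect_equal(det2$areaUm2, n * 0.0169, tolerance = 1e-12)
    expect_identical(det2$isMacro, n == 592L)
  }
  ## a coarser calibration where the minimum filter does bite
  m3 <- matrix(0L, 10, 10)
  m3[1, 1] <- 1L
  det3 <- extractLesions(m3, matrix(TRUE, 10, 10), 0.05,
                         QuantConfig(minDetectionUm2 = 0.01))
  expect_identical(nrow(det3), 0L)  # 0.0025 um2 < 0.01
})

test_that("retained pixel counts never exceed in-mask positives, with equality when nothing is filtered", {
  set.seed(7)
  for (i in 1:10) {
    m <- matrix(as.integer(runif(30 * 30) < 0.3), 30, 30)
    mask <- matrix(runif(30 * 30) < 0.8, 30, 30)
    det <- extractLesions(m, mask, 0.13)
    expect_lte(sum(det$pixelCount), sum(m == 1L & mask))
    ## at 0.13 um/px the minimum filter is inert, so equality holds
    expect_identical(sum(det$pixelCount), sum(m == 1L & mask))
  }
})

test_that("areas scale as s^2 and densities as s^-2 with pixel size", {
  set.seed(13)
  m <- matrix(as.integer(runif(25 * 25) < 0.2), 25, 25)
  mask <- matrix(TRUE, 25, 25)
  s <- 3
  d1 <- extractLesions(m, mask, 0.13, QuantConfig(connectivity = 8L))
  d2 <- extractLesions(m, mask, 0.13 * s, QuantConfig(connectivity = 8L))
  expect_equal(d2$areaUm2, d1$areaUm2 * s^2, tolerance = 1e-12)
  r1 <- quantifySample(d1, sum(mask) * 0.13^2)
  r2 <- quantifySample(d2, sum(mask) * (0.13 * s)^2)
  expect_equal(
    r2$lesion_density_per_mm2, r1$lesion_density_per_mm2 / s^2,
    tolerance = 1e-12
  )
  expect_equal(
    r2$mean_lesion_size_um2, r1$mean_lesion_size_um2 * s^2,
    tolerance = 1e-12
  )
})

test_that("lesions are clipped to the ROI before size assessment", {
  m <- matrix(0L, 10, 10)
  m[4:6, 4:8] <- 1L          # one 15-px component
  mask <- matrix(FALSE, 10, 10)
  mask[, 1:5] <- TRUE        # ROI covers only columns 1..5
  det <- extractLesions(m, mask, 0.13)
  expect_identical(nrow(det), 1L)
  expect_identical(det$pixelCount, 6L)  # 3 rows x 2 in-mask columns
})

test_that("detections are sorted by centroid and shapes must match", {
  m <- matrix(0L, 12, 12)
  m[10, 2] <- 1L
  m[2, 10] <- 1L
  m[5, 5] <- 1L
  det <- extractLesions(m, matrix(TRUE, 12, 12), 0.13)
  expect_identical(det$centroidRow, c(1, 4, 9))
  expect_error(
    extractLesions(m, matrix(TRUE, 10, 12), 0.13),
    "shape"
  )
})

test_that("the worked readout example is reproduced exactly", {
  r <- quantifySample(c(0.5, 1.5, 28), roiAreaUm2 = 1e6)
  expect_identical(r$lesion_count, 3L)
  expect_equal(r$lesion_density_per_mm2, 3.0)
  expect_equal(r$mean_lesion_size_um2, 10.0)
  expect_identical(r$macro_count, 1L)
  expect_equal(r$macro_fraction_pct, 100 / 3, tolerance = 1e-12)
  expect_equal(r$macro_density_per_mm2, 1.0)
})

test_that("zero-lesion samples report missing mean size and macro fraction", {
  r <- quantifySample(numeric(0), roiAreaUm2 = 5e5)
  expect_identical(r$lesion_count, 0L)
  expect_identical(r$lesion_density_per_mm2, 0)
  expect_identical(r$macro_density_per_mm2, 0)
  expect_true(is.na(r$mean_lesion_size_um2))
  expect_true(is.na(r$macro_fraction_pct))
})

test_that("density arithmetic: 100 lesions in half a square millimetre", {
  r <- quantifySample(rep(1, 100), roiAreaUm2 = 5e5)
  expect_equal(r$lesion_density_per_mm2, 200)
})

test_that("invalid readout inputs are errors", {
  expect_error(quantifySample(c(1, 2), roiAreaUm2 = 0), "positive")
  expect_error(quantifySample(c(1, 2), 1e5, genotype = "XX"), "genotype")
  expect_error(QuantConfig(minDetectionUm2 = 11, macroThresholdUm2 = 10))
})
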