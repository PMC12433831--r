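test_that("the size-mixture solver hits its target moments", {
  for (tgt in list(c(0.7, 16 / 1874), c(0.9, 39 / 3473), c(1.4, 341 / 16924))) {
    mix <- solveSizeMixture(tgt[1], tgt[2])
    mu <- (1 - mix$macroWeight) * mix$microMeanUm2 + mix$macroWeight * 18
    expect_equal(mu, tgt[1], tolerance = 1e-6)
    ## implied macro fraction (areas > 10 um2) matches the target
    p10 <- (1 - mix$macroWeight) *
      plnorm(10, log(mix$microMeanUm2) - 0.32, 0.8, lower.tail = FALSE) +
      mix$macroWeight * plnorm(10, log(18) - 0.125, 0.5, lower.tail = FALSE)
    expect_equal(p10, tgt[2], tolerance = 1e-6)
  }
})

test_that("tissue generation is deterministic under a fixed seed", {
  spec <- TissueSpec(fieldSizePx = c(128L, 128L), lesionDensityPerMm2 = 3e4,
                     seed = 42L)
  s1 <- generateTissueImage(spec)
  s2 <- generateTissueImage(spec)
  expect_identical(pixels(s1$image), pixels(s2$image))
  expect_identical(s1$truth@mask, s2$truth@mask)
  expect_identical(s1$truth@lesionAreasUm2, s2$truth@lesionAreasUm2)
})

test_that("lesion counts follow the Poisson law of the spec density", {
  density <- 40000
  counts <- vapply(1:60, function(s) {
    sim <- generateTissueImage(TissueSpec(
      fieldSizePx = c(160L, 160L), lesionDensityPerMm2 = density,
      roiCoverage = c(0.45, 0.55), nExcludeMax = 0L, seed = 500L + s
    ))
    ## compare against each realized ROI area
    c(length(sim$truth@lesionAreasUm2),
      density * sim$truth@roiAreaUm2 * 1e-6)
  }, numeric(2))
  lambda <- mean(counts[2, ])
  expect_lt(
    abs(mean(counts[1, ]) - lambda),
    3 * sqrt(lambda / 60) + 0.5  # merged overlaps shave a little
  )
})

test_that("zero lesion intensity leaves the image at background statistics", {
  mk <- function(peak, dens) generateTissueImage(TissueSpec(
    fieldSizePx = c(128L, 128L), lesionDensityPerMm2 = dens,
    lesionPeak = peak, seed = 9L
  ))
  dark <- mk(0, 3e4)
  blank <- mk(100, 1e-6)  # effectively lesion-free render
  ## same seed shares the mosaic; only the read-noise draws differ
  expect_lt(
    abs(mean(pixels(dark$image)) - mean(pixels(blank$image))),
    6 * 4 * sqrt(2) / 128
  )
  expect_lt(
    abs(sd(pixels(dark$image)) - sd(pixels(blank$image))),
    0.5
  )
  expect_gt(length(dark$truth@lesionAreasUm2), 0)
})

test_that("ground-truth mask and ledger are exactly consistent", {
  for (s in c(3L, 4L)) {
    sim <- generateTissueImage(TissueSpec(
      fieldSizePx = c(160L, 160L), lesionDensityPerMm2 = 4e4, seed = s
    ))
    probe <- FluorescenceImage(
      matrix(0, 160, 160), pixelSizeUm = sim$truth@pixelSizeUm
    )
    roiMask <- buildRoiMask(sim$roi, probe)
    comp <- labelComponents(sim$truth@mask & roiMask$mask, 8L)
    areas <- sort(tabulate(comp[comp > 0L]) * sim$truth@pixelSizeUm^2)
    expect_equal(sort(sim$truth@lesionAreasUm2), areas, tolerance = 1e-12)
  }
})

test_that("ground-truth readout shares definitions with quantifySample", {
  gt <- new("GroundTruth",
    mask = matrix(FALSE, 2, 2), lesionAreasUm2 = c(0.5, 1.5, 28),
    roiAreaUm2 = 1e6, pixelSizeUm = 0.13
  )
  r <- groundTruthReadout(gt)
  q <- quantifySample(c(0.5, 1.5, 28), 1e6, sampleId = "truth")
  expect_equal(r[, -1], q[, -1])
  empty <- new("GroundTruth",
    mask = matrix(FALSE, 2, 2), lesionAreasUm2 = numeric(0),
    roiAreaUm2 = 1e6, pixelSizeUm = 0.13
  )
  rE <- groundTruthReadout(empty)
  expect_identical(rE$lesion_count, 0L)
  expect_true(is.na(rE$mean_lesion_size_um2))
})

test_that("macro counts in random ledgers match a brute-force filter", {
  set.seed(12)
  for (i in 1:100) {
    areas <- rlnorm(sample(1:40, 1), 0, 2)
    gt <- new("GroundTruth",
      mask = matrix(FALSE, 2, 2), lesionAreasUm2 = areas,
      roiAreaUm2 = 1e6, pixelSizeUm = 0.13
    )
    r <- groundTruthReadout(gt)
    expect_identical(r$macro_count, sum(areas > 10))
  }
})

test_that("cohort generation is deterministic and matches the study design", {
  c1 <- generateCohort(baseSeed = 5L)
  c2 <- generateCohort(baseSeed = 5L)
  expect_identical(c1$cohort, c2$cohort)
  tab <- table(c1$cohort$genotype, c1$cohort$condition)
  expect_identical(as.integer(tab[c("WT", "HET", "HOM"), "no_run"]),
                   c(8L, 9L, 10L))
  expect_identical(as.integer(tab[c("WT", "HET", "HOM"), "run"]),
                   c(9L, 9L, 12L))
})

test_that("cohort group means track the regime targets", {
  targets <- data.frame(
    genotype = rep(c("WT", "HET", "HOM"), 2),
    condition = rep(c("no_run", "run"), each = 3),
    density = c(1874, 3473, 16924, 5232, 5468, 18149)
  )
  dens <- list()
  sizesWT <- c()
  for (s in 1:12) {
    co <- generateCohort(baseSeed = 300L + s)$cohort
    for (i in seq_len(nrow(targets))) {
      key <- paste(targets$genotype[i], targets$condition[i])
      v <- co$lesion_density_per_mm2[
        co$genotype == targets$genotype[i] &
          co$condition == targets$condition[i]
      ]
      dens[[key]] <- c(dens[[key]], v)
    }
    wt <- co[co$genotype == "WT" & co$condition == "no_run", ]
    sizesWT <- c(sizesWT, wt$mean_lesion_size_um2)
  }
  for (i in seq_len(nrow(targets))) {
    key <- paste(targets$genotype[i], targets$condition[i])
    expect_lt(
      abs(mean(dens[[key]]) - targets$density[i]) / targets$density[i],
      0.15
    )
  }
  ## mean lesion size of the wild-type baseline regime is ~0.7 um2
  expect_lt(abs(mean(sizesWT) - 0.7) / 0.7, 0.10)
})

test_that("increasing spec density increases recovered ground-truth density", {
  mean3 <- vapply(c(2000, 8000, 30000), function(d) {
    mean(vapply(1:8, function(s) {
      sim <- generateTissueImage(TissueSpec(
        fieldSizePx = c(160L, 160L), lesionDensityPerMm2 = d,
        seed = 700L + s
      ))
      length(sim$truth@lesionAreasUm2) / (sim$truth@roiAreaUm2 * 1e-6)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(mean3) > 0))
})

test_that("simulation guards reject runaway and degenerate requests", {
  expect_error(
    generateTissueImage(TissueSpec(
      fieldSizePx = c(4000L, 4000L), lesionDensityPerMm2 = 1e7
    )),
    "1e6|refusing"
  )
  expect_error(TissueSpec(fieldSizePx = c(0L, 10L)), ">= 8")
  expect_error(TissueSpec(lesionDensityPerMm2 = -5), "positive")
})
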