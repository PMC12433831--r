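## Synthetic muscle cross-sections with known ground truth: fibre-mosaic
## background, Poisson-placed elliptical lesions with a two-component
## (micro/macro) lognormal area mixture, PSF blur and read noise.

.GROUP_LEVELS <- data.frame(
  genotype = rep(c("WT", "HET", "HOM"), 2),
  condition = rep(c("no_run", "run"), each = 3),
  stringsAsFactors = FALSE
)

## Six-group regime parameters: printed cohort means of the reference study
## (lesion densities /mm^2, mean lesion sizes um^2, macrolesion densities
## /mm^2) reused as simulation targets, with the Fig-5 group sizes.
.GROUP_REGIMES <- within(.GROUP_LEVELS, {
  density <- c(1874, 3473, 16924, 5232, 5468, 18149)
  meanSize <- c(0.7, 0.9, 1.4, 0.8, 1.0, 1.4)
  macroDensity <- c(16, 39, 341, 49, 62, 337)
  n <- c(8L, 9L, 10L, 9L, 9L, 12L)
})

#' @keywords internal
.meanlog <- function(meanValue, sdlog) log(meanValue) - sdlog^2 / 2

#' Solve the micro/macro lognormal mixture for target moments
#'
#' Given a target mean lesion area and a target macrolesion fraction
#' (areas > \code{thresholdUm2}), finds the macro-component weight and the
#' micro-component mean so that the mixture reproduces both. The macro
#' component is held fixed; a short fixed-point iteration accounts for the
#' micro tail above the threshold.
#'
#' @param meanSizeUm2 target mean lesion area in um^2.
#' @param macroFraction target fraction of lesions above the threshold.
#' @param macroMeanUm2,macroSdLog macro component (lognormal, mean/log-sd).
#' @param microSdLog micro component log-sd.
#' @param thresholdUm2 macrolesion area threshold.
#' @return list with \code{microMeanUm2} and \code{macroWeight}.
#' @export
solveSizeMixture <- function(meanSizeUm2, macroFraction,
                             macroMeanUm2 = 18, macroSdLog = 0.5,
                             microSdLog = 0.8, thresholdUm2 = 10) {
  pMacroTail <- plnorm(
    thresholdUm2, .meanlog(macroMeanUm2, macroSdLog), macroSdLog,
    lower.tail = FALSE
  )
  w <- macroFraction / pMacroTail
  microMean <- meanSizeUm2
  for (i in 1:20) {
    microMean <- (meanSizeUm2 - w * macroMeanUm2) / (1 - w)
    if (microMean <= 0) {
      stop("macro component too heavy for the requested mean size")
    }
    pMicroTail <- plnorm(
      thresholdUm2, .meanlog(microMean, microSdLog), microSdLog,
      lower.tail = FALSE
    )
    w <- max(0, (macroFraction - pMicroTail) / (pMacroTail - pMicroTail))
  }
  list(microMeanUm2 = microMean, macroWeight = w)
}

#' Tissue specification for one of the six study groups
#'
#' Returns a [TissueSpec-class] parameterized at the printed group means of
#' the reference cohort: lesion density, mean lesion size and macrolesion
#' fraction (macrolesion density / lesion density) per genotype x exercise
#' condition, with the size mixture solved by [solveSizeMixture()].
#'
#' @param genotype \code{"WT"}, \code{"HET"} or \code{"HOM"}.
#' @param condition \code{"no_run"} or \code{"run"}.
#' @param ... overrides passed on to [TissueSpec()].
#' @return A [TissueSpec-class].
#' @examples
#' groupTissueSpec("WT", "no_run")
#' @export
groupTissueSpec <- function(genotype = c("WT", "HET", "HOM"),
                            condition = c("no_run", "run"), ...) {
  genotype <- match.arg(genotype)
  condition <- match.arg(condition)
  reg <- .GROUP_REGIMES[
    .GROUP_REGIMES$genotype == genotype &
      .GROUP_REGIMES$condition == condition, , drop = FALSE
  ]
  mix <- solveSizeMixture(reg$meanSize, reg$macroDensity / reg$density)
  args <- list(
    lesionDensityPerMm2 = reg$density,
    microMeanUm2 = mix$microMeanUm2,
    macroWeight = mix$macroWeight
  )
  do.call(TissueSpec, utils::modifyList(args, list(...)))
}

#' @keywords internal
.drawLesionAreas <- function(n, spec) {
  if (n == 0L) return(numeric(0))
  macro <- runif(n) < spec@macroWeight
  areas <- numeric(n)
  areas[!macro] <- rlnorm(
    sum(!macro), .meanlog(spec@microMeanUm2, spec@microSdLog), spec@microSdLog
  )
  areas[macro] <- rlnorm(
    sum(macro), .meanlog(spec@macroMeanUm2, spec@macroSdLog), spec@macroSdLog
  )
  areas
}

#' @keywords internal
.soleusRoiPolygon <- function(nr, nc, coverage) {
  ## smooth radial blob: low-order cosine modulation of a circle
  target <- coverage * nr * nc
  r0 <- sqrt(target / pi)
  r0 <- min(r0, (min(nr, nc) / 2 - 3) / 1.25)
  cy <- (nr - 1) / 2 + runif(1, -0.03, 0.03) * nr
  cx <- (nc - 1) / 2 + runif(1, -0.03, 0.03) * nc
  th <- seq(0, 2 * pi, length.out = 49L)[-49L]
  mod <- 1 + 0.12 * cos(2 * th + runif(1, 0, 2 * pi)) +
    0.08 * cos(3 * th + runif(1, 0, 2 * pi))
  rad <- r0 * mod
  x <- pmin(pmax(cx + rad * cos(th), 1), nc - 2)
  y <- pmin(pmax(cy + rad * sin(th), 1), nr - 2)
  cbind(x, y)
}

#' @keywords internal
.ellipsePixels <- function(centerRC, areaPx, axisRatio, theta, nr, nc) {
  ## pixel centers inside an ellipse of given pixel area; returns indices
  a <- sqrt(areaPx * axisRatio / pi)   # semi-major (px)
  b <- a / axisRatio
  r <- centerRC[1]; c <- centerRC[2]
  rr <- max(1L, floor(r - a)):min(nr, ceiling(r + a))
  cc <- max(1L, floor(c - a)):min(nc, ceiling(c + a))
  grid <- expand.grid(r = rr, c = cc)
  dx <- grid$c - c
  dy <- grid$r - r
  u <- (dx * cos(theta) + dy * sin(theta)) / a
  v <- (-dx * sin(theta) + dy * cos(theta)) / b
  sel <- (u^2 + v^2) <= 1
  idx <- (grid$c[sel] - 1L) * nr + grid$r[sel]
  if (length(idx) == 0L) {
    ## sub-pixel lesion: occupy the nearest pixel
    idx <- (round(c) - 1L) * nr + round(r)
  }
  idx
}

#' @keywords internal
.voronoiBackground <- function(nr, nc, pixelSizeUm, level, cellAmp, texAmp) {
  ## fibre mosaic: nearest-seed partition with per-cell level jitter,
  ## plus a smooth low-amplitude texture
  fibreDiamPx <- 45 / pixelSizeUm       # ~45 um fibre calibre
  nSeeds <- max(4L, ceiling(nr * nc / fibreDiamPx^2))
  sr <- runif(nSeeds, 1, nr)
  sc <- runif(nSeeds, 1, nc)
  lev <- level * (1 + runif(nSeeds, -cellAmp, cellAmp))
  rows <- matrix(seq_len(nr), nr, nc)
  cols <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  best <- matrix(Inf, nr, nc)
  cell <- matrix(1L, nr, nc)
  for (s in seq_len(nSeeds)) {
    d2 <- (rows - sr[s])^2 + (cols - sc[s])^2
    upd <- d2 < best
    best[upd] <- d2[upd]
    cell[upd] <- s
  }
  bg <- matrix(lev[cell], nr, nc)
  if (texAmp > 0) {
    tex <- matrix(rnorm(nr * nc), nr, nc)
    k <- .gaussKernel(max(2, fibreDiamPx / 12), 0L)
    tex <- .sepConv(tex, k, k)
    tex <- tex / max(sd(tex), 1e-12)
    bg <- bg * (1 + texAmp * tex)
  }
  pmax(bg, 0)
}

#' Generate one synthetic tissue image with ground truth
#'
#' Renders a soleus-like cross-section: a smooth blob ROI (with optional
#' artefact exclusion disks), a Voronoi fibre-mosaic background with gentle
#' texture, lesions placed by a homogeneous Poisson process inside the ROI
#' with areas drawn from the micro/macro lognormal mixture and elliptical
#' shapes (axis ratio uniform on 1-3, random orientation), then PSF blur
#' and Gaussian read noise (optionally Poisson shot noise). The ground
#' truth is the pre-blur lesion footprint; because dense regimes allow
#' overlap, the per-lesion ledger is recomputed from the merged mask
#' clipped to the ROI, so mask and ledger are exactly consistent.
#'
#' @param spec a [TissueSpec-class]; \code{spec@seed} drives all
#'   randomness.
#' @return list with \code{image} ([FluorescenceImage-class]),
#'   \code{truth} ([GroundTruth-class]) and \code{roi}
#'   ([RegionOfInterest-class]).
#' @export
generateTissueImage <- function(spec) {
  stopifnot(is(spec, "TissueSpec"))
  validObject(spec)
  nr <- spec@fieldSizePx[1]
  nc <- spec@fieldSizePx[2]
  ps <- spec@pixelSizeUm
  fieldMm2 <- nr * nc * ps^2 * 1e-6
  if (spec@lesionDensityPerMm2 * fieldMm2 > 1e6) {
    stop("expected lesion count exceeds 1e6; refusing to simulate")
  }
  set.seed(spec@seed)
  coverage <- runif(1, spec@roiCoverage[1], spec@roiCoverage[2])
  roiPoly <- .soleusRoiPolygon(nr, nc, coverage)
  exclude <- list()
  nEx <- if (spec@nExcludeMax > 0L) sample(0:spec@nExcludeMax, 1L) else 0L
  if (nEx > 0L) {
    cy <- mean(roiPoly[, 2]); cx <- mean(roiPoly[, 1])
    rr <- 0.25 * sqrt(coverage * nr * nc / pi)
    for (i in seq_len(nEx)) {
      er <- runif(1, 0.02, 0.05) * min(nr, nc)
      ang <- runif(1, 0, 2 * pi)
      dd <- runif(1, 0.2, 0.8) * rr
      th <- seq(0, 2 * pi, length.out = 17L)[-17L]
      exclude[[i]] <- cbind(
        cx + dd * cos(ang) + er * cos(th),
        cy + dd * sin(ang) + er * sin(th)
      )
    }
  }
  roi <- RegionOfInterest(roiPoly, exclude)
  probe <- FluorescenceImage(
    matrix(0, nr, nc), pixelSizeUm = ps, sampleId = "probe"
  )
  roiMask <- buildRoiMask(roi, probe)
  roiIdx <- which(roiMask$mask)
  roiAreaMm2 <- roiMask$areaUm2 * 1e-6

  ## background drawn before lesion placement so that renders of the same
  ## seed share their mosaic regardless of the lesion regime
  img <- .voronoiBackground(
    nr, nc, ps, spec@backgroundLevel,
    spec@backgroundCellAmplitude, spec@textureAmplitude
  )
  nLesions <- rpois(1L, spec@lesionDensityPerMm2 * roiAreaMm2)
  mask <- matrix(FALSE, nr, nc)
  if (nLesions > 0L) {
    centers <- sample(roiIdx, nLesions, replace = TRUE)
    areas <- .drawLesionAreas(nLesions, spec)
    ratios <- runif(nLesions, 1, 3)
    thetas <- runif(nLesions, 0, pi)
    jr <- runif(nLesions, -0.5, 0.5)
    jc <- runif(nLesions, -0.5, 0.5)
    for (i in seq_len(nLesions)) {
      rc <- c(
        (centers[i] - 1L) %% nr + 1L + jr[i],
        (centers[i] - 1L) %/% nr + 1L + jc[i]
      )
      px <- .ellipsePixels(rc, areas[i] / ps^2, ratios[i], thetas[i], nr, nc)
      mask[px] <- TRUE
    }
  }
  ## ledger from the merged, ROI-clipped footprint
  comp <- labelComponents(mask & roiMask$mask, 8L)
  ledger <- if (max(comp) > 0L) {
    as.numeric(tabulate(comp[comp > 0L])) * ps^2
  } else {
    numeric(0)
  }
  if (spec@lesionPeak > 0 && any(mask)) {
    img <- img + spec@lesionPeak * mask
  }
  k <- .gaussKernel(spec@psfSigmaPx, 0L)
  img <- .sepConv(img, k, k)
  if (spec@shotNoise) img <- rpois(length(img), pmax(img, 0)) + img * 0
  if (spec@readNoiseSd > 0) img <- img + rnorm(length(img), 0, spec@readNoiseSd)
  img <- matrix(pmax(img, 0), nr, nc)
  list(
    image = FluorescenceImage(img, pixelSizeUm = ps,
                              sampleId = sprintf("sim_seed%d", spec@seed)),
    truth = new("GroundTruth",
      mask = mask, lesionAreasUm2 = ledger,
      roiAreaUm2 = roiMask$areaUm2, pixelSizeUm = ps
    ),
    roi = roi
  )
}

#' Ground-truth readout of a simulated section
#'
#' Computes the seven readout parameters directly from the placed-lesion
#' ledger (not from classified pixels), giving the recovery target for
#' pipeline validation. Shares its definitions with [quantifySample()].
#'
#' @param truth a [GroundTruth-class].
#' @param cfg a [QuantConfig-class].
#' @param sampleId,genotype,condition labels for the readout row.
#' @return one-row readout data.frame (schema of [quantifySample()]).
#' @export
groundTruthReadout <- function(truth, cfg = QuantConfig(),
                               sampleId = "truth",
                               genotype = NA_character_,
                               condition = NA_character_) {
  stopifnot(is(truth, "GroundTruth"))
  areas <- truth@lesionAreasUm2
  areas <- areas[areas >= cfg@minDetectionUm2]
  quantifySample(
    areas, truth@roiAreaUm2,
    sampleId = sampleId, genotype = genotype, condition = condition, cfg = cfg
  )
}

#' Annotations derived from simulated ground truth
#'
#' Builds a training [AnnotationSet-class] from a simulated section:
#' lesion-class polygons are the bounding outlines of sampled ground-truth
#' components; ignore-class polygons are small background squares sampled
#' inside the ROI away from any lesion. This stands in for manual brush
#' annotation when training on synthetic data.
#'
#' @param truth a [GroundTruth-class].
#' @param roi the matching [RegionOfInterest-class].
#' @param nPerClass annotation objects per class (training guideline: 100).
#' @param seed RNG seed.
#' @return An [AnnotationSet-class].
#' @export
annotationsFromTruth <- function(truth, roi, nPerClass = 100L, seed = 1L) {
  stopifnot(is(truth, "GroundTruth"))
  set.seed(seed)
  nr <- nrow(truth@mask); nc <- ncol(truth@mask)
  comp <- labelComponents(truth@mask, 8L)
  k <- max(comp)
  if (k == 0L) stop("ground truth contains no lesions to annotate")
  polys <- list()
  pick <- sample(seq_len(k), min(nPerClass, k))
  for (ci in pick) {
    idx <- which(comp == ci)
    r0 <- (idx - 1L) %% nr
    c0 <- (idx - 1L) %/% nr
    if (length(idx) < 3L) {
      ## tiny component: tight box around its pixel centers
      poly <- cbind(
        c(min(c0) - 0.45, max(c0) + 0.45, max(c0) + 0.45, min(c0) - 0.45),
        c(min(r0) - 0.45, min(r0) - 0.45, max(r0) + 0.45, max(r0) + 0.45)
      )
    } else {
      ## brush-style outline: convex hull of the pixel centers, slightly
      ## shrunk toward the centroid so the trace stays inside the lesion
      h <- grDevices::chull(c0, r0)
      cx <- mean(c0); cy <- mean(r0)
      poly <- cbind(
        cx + 0.92 * (c0[h] - cx),
        cy + 0.92 * (r0[h] - cy)
      )
      if (nrow(poly) < 3L) {
        poly <- cbind(
          c(min(c0) - 0.45, max(c0) + 0.45, max(c0) + 0.45, min(c0) - 0.45),
          c(min(r0) - 0.45, min(r0) - 0.45, max(r0) + 0.45, max(r0) + 0.45)
        )
      }
    }
    polys[[length(polys) + 1L]] <- list(coords = poly, class = "lesion")
  }
  nLesion <- length(polys)
  probe <- FluorescenceImage(
    matrix(0, nr, nc), pixelSizeUm = truth@pixelSizeUm, sampleId = "probe"
  )
  roiMask <- buildRoiMask(roi, probe)
  ## ignore-class supervision needs both far background and the pixels just
  ## outside lesion boundaries (where the blurred signal still carries a
  ## faint halo), so half the boxes are sampled from a rim 2-3 px from the
  ## nearest lesion and half uniformly from clear background
  dil8 <- function(m) {
    m | rbind(m[-1, ], FALSE) | rbind(FALSE, m[-nr, ]) |
      cbind(m[, -1], FALSE) | cbind(FALSE, m[, -nc]) |
      rbind(cbind(m[-1, -1], FALSE), FALSE) |
      rbind(cbind(FALSE, m[-1, -nc]), FALSE) |
      rbind(FALSE, cbind(m[-nr, -1], FALSE)) |
      rbind(FALSE, cbind(FALSE, m[-nr, -nc]))
  }
  d1 <- dil8(truth@mask)
  d2 <- dil8(d1)
  d3 <- dil8(d2)
  rimIdx <- which(roiMask$mask & d3 & !d1)
  farIdx <- which(roiMask$mask & !d3)
  ## convex outlines of merged (concave) components can cover background
  ## pixels, so ignore boxes must also avoid the drawn lesion polygons
  annMask <- matrix(FALSE, nr, nc)
  for (p in polys) {
    annMask <- annMask | .rasterizePolygon(p$coords, nr, nc)
  }
  sampleBoxes <- function(cand, nWanted, half, clearance) {
    got <- 0L
    guard <- 0L
    out <- list()
    if (length(cand) == 0L) return(out)
    while (got < nWanted && guard < nWanted * 50L) {
      guard <- guard + 1L
      i <- cand[sample.int(length(cand), 1L)]
      r0 <- (i - 1L) %% nr
      c0 <- (i - 1L) %/% nr
      if (r0 < clearance || c0 < clearance ||
          r0 > nr - clearance - 1L || c0 > nc - clearance - 1L) next
      rows <- (r0 - clearance):(r0 + clearance) + 1L
      cols <- (c0 - clearance):(c0 + clearance) + 1L
      if (any(truth@mask[rows, cols]) || any(annMask[rows, cols])) next
      out[[got + 1L]] <- list(
        coords = cbind(
          c(c0 - half, c0 + half, c0 + half, c0 - half),
          c(r0 - half, r0 - half, r0 + half, r0 + half)
        ),
        class = "ignore"
      )
      got <- got + 1L
    }
    out
  }
  rim <- sampleBoxes(rimIdx, ceiling(nPerClass / 2), half = 1.45, clearance = 1L)
  far <- sampleBoxes(farIdx, nPerClass - length(rim), half = 2.45, clearance = 2L)
  polys <- c(polys, rim, far)
  nBg <- length(rim) + length(far)
  ## equal object counts across classes where possible
  if (nBg > nLesion) polys <- polys[seq_len(2L * nLesion)]
  AnnotationSet(polys)
}

#' Generate a six-group synthetic cohort
#'
#' Draws per-animal readouts for the six genotype x condition groups at the
#' study regime parameters (see [groupTissueSpec()]): each animal gets a
#' lognormal between-animal density multiplier (CV \code{animalCv}), an ROI
#' area drawn uniformly from \code{roiAreaRangeMm2}, a Poisson lesion count
#' and mixture-drawn lesion areas, from which the seven-parameter readout
#' is computed. With \code{render = TRUE} full images are also generated
#' via [generateTissueImage()] (sized by \code{fieldSizePx}), which is
#' considerably slower and intended for small validation cohorts.
#'
#' @param nPerGroup named integer vector of group sizes in the order
#'   WT/HET/HOM no_run then run; defaults to the study sizes
#'   8, 9, 10, 9, 9, 12.
#' @param baseSeed integer; all randomness flows from it.
#' @param animalCv between-animal coefficient of variation on density
#'   (default 0.3).
#' @param roiAreaRangeMm2 per-animal ROI area range (default 0.4-0.8 mm^2).
#' @param render also render images (default FALSE).
#' @param fieldSizePx field size when rendering.
#' @param cfg [QuantConfig-class] for the readouts.
#' @param ... overrides forwarded to [groupTissueSpec()].
#' @return list with \code{cohort} (readout data.frame, one row per
#'   animal), \code{truths} (per-animal ledgers) and, when rendering,
#'   \code{images} and \code{rois}.
#' @export
generateCohort <- function(nPerGroup = NULL, baseSeed = 1L, animalCv = 0.3,
                           roiAreaRangeMm2 = c(0.4, 0.8), render = FALSE,
                           fieldSizePx = c(512L, 512L),
                           cfg = QuantConfig(), ...) {
  reg <- .GROUP_REGIMES
  if (is.null(nPerGroup)) {
    nPerGroup <- reg$n
  } else {
    if (length(nPerGroup) != 6L) stop("nPerGroup must have six entries")
    nPerGroup <- as.integer(nPerGroup)
  }
  if (any(nPerGroup < 2L)) stop("each group needs n >= 2")
  set.seed(as.integer(baseSeed))
  sdlog <- sqrt(log(1 + animalCv^2))
  rows <- list()
  truths <- list()
  images <- list()
  rois <- list()
  for (gi in seq_len(nrow(reg))) {
    spec0 <- groupTissueSpec(reg$genotype[gi], reg$condition[gi], ...)
    for (ai in seq_len(nPerGroup[gi])) {
      id <- sprintf("%s_%s_%02d", reg$genotype[gi], reg$condition[gi], ai)
      mult <- rlnorm(1, -sdlog^2 / 2, sdlog)
      density <- spec0@lesionDensityPerMm2 * mult
      if (render) {
        animalSeed <- sample.int(.Machine$integer.max - 1L, 1L)
        spec <- spec0
        spec@lesionDensityPerMm2 <- density
        spec@fieldSizePx <- as.integer(fieldSizePx)
        spec@seed <- animalSeed
        sim <- generateTissueImage(spec)
        truth <- sim$truth
        images[[id]] <- sim$image
        rois[[id]] <- sim$roi
        areas <- truth@lesionAreasUm2
        roiAreaUm2 <- truth@roiAreaUm2
      } else {
        roiAreaUm2 <- runif(1, roiAreaRangeMm2[1], roiAreaRangeMm2[2]) * 1e6
        count <- rpois(1L, density * roiAreaUm2 * 1e-6)
        areas <- .drawLesionAreas(count, spec0)
        truth <- new("GroundTruth",
          mask = matrix(FALSE, 1L, 1L), lesionAreasUm2 = areas,
          roiAreaUm2 = roiAreaUm2, pixelSizeUm = spec0@pixelSizeUm
        )
      }
      truths[[id]] <- truth
      rows[[length(rows) + 1L]] <- quantifySample(
        areas[areas >= cfg@minDetectionUm2], roiAreaUm2,
        sampleId = id, genotype = reg$genotype[gi],
        condition = reg$condition[gi], cfg = cfg
      )
    }
  }
  cohort <- do.call(rbind, rows)
  rownames(cohort) <- NULL
  out <- list(cohort = cohort, truths = truths)
  if (render) {
    out$images <- images
    out$rois <- rois
  }
  out
}
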