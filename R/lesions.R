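## Connected-component lesion extraction and the seven-parameter readout.

#' Label connected components of a binary raster
#'
#' Breadth-first labeling with a vectorized frontier, supporting 4- and
#' 8-neighbour connectivity. Labels are assigned in column-major scan order
#' of the first-encountered pixel of each component, so the labeling is
#' deterministic.
#'
#' @param mask logical matrix.
#' @param connectivity 4 or 8 (default 8).
#' @return integer matrix; 0 = background, components numbered from 1.
#' @examples
#' m <- matrix(FALSE, 5, 5); m[cbind(c(1, 2, 5), c(1, 2, 5))] <- TRUE
#' max(labelComponents(m, 8))  # diagonal chain merges: 2 components
#' max(labelComponents(m, 4))  # 3 components
#' @export
labelComponents <- function(mask, connectivity = 8L) {
  stopifnot(is.matrix(mask))
  if (!connectivity %in% c(4L, 8L)) stop("connectivity must be 4 or 8")
  mask <- mask != 0
  nr <- nrow(mask); nc <- ncol(mask)
  labels <- matrix(0L, nr, nc)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  if (connectivity == 4L) {
    dr <- c(-1L, 1L, 0L, 0L)
    dc <- c(0L, 0L, -1L, 1L)
  } else {
    dr <- c(-1L, 1L, 0L, 0L, -1L, -1L, 1L, 1L)
    dc <- c(0L, 0L, -1L, 1L, -1L, 1L, -1L, 1L)
  }
  visited <- logical(nr * nc)
  lab <- 0L
  for (seed in fg) {
    if (visited[seed]) next
    lab <- lab + 1L
    visited[seed] <- TRUE
    frontier <- seed
    while (length(frontier) > 0L) {
      labels[frontier] <- lab
      r <- (frontier - 1L) %% nr + 1L
      c <- (frontier - 1L) %/% nr + 1L
      nxt <- integer(0)
      for (k in seq_along(dr)) {
        rr <- r + dr[k]
        cc <- c + dc[k]
        ok <- rr >= 1L & rr <= nr & cc >= 1L & cc <= nc
        if (!any(ok)) next
        idx <- (cc[ok] - 1L) * nr + rr[ok]
        idx <- idx[mask[idx] & !visited[idx]]
        if (length(idx) > 0L) {
          visited[idx] <- TRUE
          nxt <- c(nxt, idx)
        }
      }
      frontier <- unique(nxt)
    }
  }
  labels
}

#' Extract lesions as size-filtered connected components
#'
#' Intersects the classified lesion raster with the ROI mask (components
#' straddling the ROI border contribute only their inside pixels), labels
#' connected components, converts pixel counts to calibrated areas, applies
#' the inclusive minimum-detection filter and flags macrolesions by the
#' strict area threshold. At the reference calibration of 0.13 um/px a
#' single pixel (0.0169 um^2) already exceeds the default 0.01 um^2 minimum,
#' so the filter only bites at coarser resolutions.
#'
#' @param lesionRaster binary matrix from [classifyPixels()].
#' @param mask logical ROI mask congruent with \code{lesionRaster}.
#' @param pixelSizeUm pixel edge length in micrometres.
#' @param cfg a [QuantConfig-class].
#' @return data.frame with one row per retained lesion: \code{pixelCount},
#'   \code{areaUm2}, \code{centroidRow}, \code{centroidCol} (0-based) and
#'   \code{isMacro}, sorted by centroid (row, col).
#' @export
extractLesions <- function(lesionRaster, mask, pixelSizeUm,
                           cfg = QuantConfig()) {
  stopifnot(is(cfg, "QuantConfig"))
  validObject(cfg)
  if (!identical(dim(lesionRaster), dim(mask))) {
    stop("lesion raster and ROI mask differ in shape")
  }
  if (pixelSizeUm <= 0) stop("pixelSizeUm must be positive")
  inside <- (lesionRaster != 0) & mask
  labels <- labelComponents(inside, cfg@connectivity)
  k <- max(labels)
  empty <- data.frame(
    pixelCount = integer(0), areaUm2 = numeric(0),
    centroidRow = numeric(0), centroidCol = numeric(0), isMacro = logical(0)
  )
  if (k == 0L) return(empty)
  idx <- which(labels > 0L)
  lab <- labels[idx]
  nr <- nrow(labels)
  r0 <- (idx - 1L) %% nr        # 0-based row
  c0 <- (idx - 1L) %/% nr       # 0-based col
  count <- tabulate(lab, nbins = k)
  det <- data.frame(
    pixelCount = count,
    areaUm2 = count * pixelSizeUm^2,
    centroidRow = as.numeric(tapply(r0, lab, mean)),
    centroidCol = as.numeric(tapply(c0, lab, mean))
  )
  det <- det[det$areaUm2 >= cfg@minDetectionUm2, , drop = FALSE]
  if (nrow(det) == 0L) return(empty)
  det$isMacro <- det$areaUm2 > cfg@macroThresholdUm2
  det <- det[order(det$centroidRow, det$centroidCol), , drop = FALSE]
  rownames(det) <- NULL
  det
}

#' Compute the seven-parameter sample readout
#'
#' Summarises one muscle section: (i) ROI area in um^2, (ii) total lesion
#' count, (iii) mean lesion size in um^2, (iv) macrolesion count,
#' (v) lesion density per mm^2, (vi) macrolesion fraction in percent and
#' (vii) macrolesion density per mm^2. For a section without lesions the
#' mean size and macro fraction are undefined and reported as \code{NA}
#' (never zero), so group means are not deflated.
#'
#' @param lesions data.frame from [extractLesions()], or a numeric vector of
#'   lesion areas in um^2 (macro status then derived with
#'   \code{cfg@macroThresholdUm2}).
#' @param roiAreaUm2 included ROI area in square micrometres.
#' @param sampleId sample identifier.
#' @param genotype one of \code{"WT"}, \code{"HET"}, \code{"HOM"} (or NA).
#' @param condition one of \code{"no_run"}, \code{"run"} (or NA).
#' @param cfg [QuantConfig-class] used when \code{lesions} is an area vector.
#' @return one-row data.frame with columns \code{sample_id},
#'   \code{genotype}, \code{condition}, \code{roi_area_um2},
#'   \code{lesion_count}, \code{lesion_density_per_mm2},
#'   \code{mean_lesion_size_um2}, \code{macro_count},
#'   \code{macro_fraction_pct}, \code{macro_density_per_mm2}.
#' @examples
#' quantifySample(c(0.5, 1.5, 28), roiAreaUm2 = 1e6, sampleId = "demo")
#' @export
quantifySample <- function(lesions, roiAreaUm2, sampleId = "sample",
                           genotype = NA_character_,
                           condition = NA_character_,
                           cfg = QuantConfig()) {
  if (!is.finite(roiAreaUm2) || roiAreaUm2 <= 0) {
    stop("roiAreaUm2 must be positive")
  }
  if (is.numeric(lesions)) {
    areas <- as.numeric(lesions)
    isMacro <- areas > cfg@macroThresholdUm2
  } else {
    areas <- lesions$areaUm2
    isMacro <- lesions$isMacro
  }
  if (!is.na(genotype) && !genotype %in% c("WT", "HET", "HOM")) {
    stop("genotype must be WT, HET or HOM")
  }
  if (!is.na(condition) && !condition %in% c("no_run", "run")) {
    stop("condition must be no_run or run")
  }
  n <- length(areas)
  nMacro <- sum(isMacro)
  areaMm2 <- roiAreaUm2 * 1e-6
  data.frame(
    sample_id = as.character(sampleId),
    genotype = genotype,
    condition = condition,
    roi_area_um2 = roiAreaUm2,
    lesion_count = as.integer(n),
    lesion_density_per_mm2 = n / areaMm2,
    mean_lesion_size_um2 = if (n > 0) mean(areas) else NA_real_,
    macro_count = as.integer(nMacro),
    macro_fraction_pct = if (n > 0) 100 * nMacro / n else NA_real_,
    macro_density_per_mm2 = nMacro / areaMm2,
    stringsAsFactors = FALSE
  )
}

#' Quantify one image end to end
#'
#' Convenience wrapper chaining [computeFeatureStack()], [classifyPixels()],
#' [buildRoiMask()], [extractLesions()] and [quantifySample()].
#'
#' @param image a [FluorescenceImage-class].
#' @param classifier a trained [PixelClassifier-class].
#' @param roi a [RegionOfInterest-class].
#' @param cfg a [QuantConfig-class].
#' @param genotype,condition optional group labels for the readout row.
#' @return list with \code{readout} (one-row data.frame), \code{lesions}
#'   (detection table) and \code{roiAreaUm2}.
#' @export
quantifyImage <- function(image, classifier, roi, cfg = QuantConfig(),
                          genotype = NA_character_,
                          condition = NA_character_) {
  stack <- computeFeatureStack(image, classifier@scalesPx)
  raster <- classifyPixels(classifier, stack)
  roiMask <- buildRoiMask(roi, image)
  lesions <- extractLesions(raster, roiMask$mask, image@pixelSizeUm, cfg)
  list(
    readout = quantifySample(
      lesions, roiMask$areaUm2,
      sampleId = image@sampleId,
      genotype = genotype, condition = condition, cfg = cfg
    ),
    lesions = lesions,
    roiAreaUm2 = roiMask$areaUm2
  )
}
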