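#' @import methods
#' @importFrom stats aov anova approx bartlett.test coef complete.cases cor
#'   dlnorm kruskal.test lm median oneway.test p.adjust pf plnorm pnorm pt
#'   ptukey qnorm quantile rbinom rlnorm rnorm rpois runif sd setNames t.test
#'   var var.test wilcox.test
#' @importFrom utils head read.csv write.csv packageVersion combn
NULL

## Coordinate frame used throughout: rasters are R matrices indexed [row, col]
## (1-based); polygon vertices are (x, y) = (col - 1, row - 1), i.e. 0-based
## pixel centers at integer coordinates, matching GeoJSON-style annotations.

#' Single-channel fluorescence image with physical calibration
#'
#' Container for one 2D single-channel intensity raster together with the
#' physical pixel edge length. All downstream areas and densities are
#' calibrated through \code{pixelSizeUm}; the reference acquisition setting
#' for soleus cross-sections is 0.13 micrometre per pixel.
#'
#' @slot pixels numeric matrix of non-negative, finite intensities
#'   (rows x cols).
#' @slot pixelSizeUm positive scalar, physical pixel edge length in
#'   micrometres.
#' @slot sampleId opaque sample identifier.
#'
#' @seealso [FluorescenceImage()] for the user-facing constructor.
#' @exportClass FluorescenceImage
setClass("FluorescenceImage",
  representation(
    pixels = "matrix",
    pixelSizeUm = "numeric",
    sampleId = "character"
  )
)

setValidity("FluorescenceImage", function(object) {
  p <- object@pixels
  if (!is.numeric(p) || length(p) == 0L) {
    return("pixels must be a non-empty numeric matrix")
  }
  if (nrow(p) < 1L || ncol(p) < 1L) return("pixel raster must be non-empty")
  if (!all(is.finite(p))) return("pixels must be finite")
  if (any(p < 0)) return("pixels must be non-negative")
  if (length(object@pixelSizeUm) != 1L || !is.finite(object@pixelSizeUm) ||
      object@pixelSizeUm <= 0) {
    return("pixelSizeUm must be a single positive number")
  }
  if (length(object@sampleId) != 1L) return("sampleId must be length 1")
  TRUE
})

#' Construct a FluorescenceImage
#'
#' @param pixels numeric matrix of non-negative intensities.
#' @param pixelSizeUm physical pixel edge length in micrometres
#'   (default 0.13, the full-resolution confocal setting).
#' @param sampleId sample identifier.
#' @return A [FluorescenceImage-class] object.
#' @examples
#' img <- FluorescenceImage(matrix(0, 8, 8), pixelSizeUm = 0.13, sampleId = "s1")
#' pixelSizeUm(img)
#' @export
FluorescenceImage <- function(pixels, pixelSizeUm = 0.13, sampleId = "sample") {
  new("FluorescenceImage",
    pixels = pixels,
    pixelSizeUm = as.numeric(pixelSizeUm),
    sampleId = as.character(sampleId)
  )
}

#' Per-pixel multiscale feature stack
#'
#' Result of [computeFeatureStack()]: for every pixel a feature vector laid
#' out as an array (rows x cols x features). Channels are ordered scale-major:
#' all base features at the first scale, then the next scale, and so on.
#'
#' @slot features numeric array, dim = (rows, cols, n features).
#' @slot scalesPx smoothing scales (sigma, in pixels) used, strictly
#'   increasing.
#' @slot featureNames channel labels, e.g. \code{"gaussian_s2"}.
#' @exportClass FeatureStack
setClass("FeatureStack",
  representation(
    features = "array",
    scalesPx = "numeric",
    featureNames = "character"
  )
)

setValidity("FeatureStack", function(object) {
  d <- dim(object@features)
  if (length(d) != 3L) return("features must be a 3D array (rows, cols, channels)")
  if (d[3] != length(object@featureNames)) {
    return("featureNames must match the number of channels")
  }
  if (!all(is.finite(object@features))) return("features must be finite")
  if (length(object@scalesPx) == 0L || any(object@scalesPx <= 0)) {
    return("scalesPx must be positive")
  }
  if (d[3] %% length(object@scalesPx) != 0L) {
    return("channel count must be a multiple of the number of scales")
  }
  TRUE
})

#' Sparse polygon annotations for classifier training
#'
#' Two-class supervision in the brush-annotation paradigm: individual lesions
#' outlined as class \code{"lesion"}, regions of background / noise signal /
#' connective tissue as class \code{"ignore"}. Pixels outside any polygon stay
#' unlabeled and are excluded from training.
#'
#' @slot polygons list; each element a list with \code{coords} (n x 2 matrix
#'   of (x, y) vertices in 0-based pixel-center coordinates) and \code{class}
#'   (\code{"lesion"} or \code{"ignore"}).
#' @exportClass AnnotationSet
setClass("AnnotationSet", representation(polygons = "list"))

.isSimplePolygon <- function(xy) {
  ## reject self-intersecting rings (non-adjacent edge pairs crossing)
  n <- nrow(xy)
  if (n < 3L) return(FALSE)
  xs <- xy[, 1]; ys <- xy[, 2]
  x2 <- c(xs[-1], xs[1]); y2 <- c(ys[-1], ys[1])
  seg <- function(i) c(xs[i], ys[i], x2[i], y2[i])
  inter <- function(a, b) {
    d1 <- (b[3] - b[1]) * (a[2] - b[2]) - (b[4] - b[2]) * (a[1] - b[1])
    d2 <- (b[3] - b[1]) * (a[4] - b[2]) - (b[4] - b[2]) * (a[3] - b[1])
    d3 <- (a[3] - a[1]) * (b[2] - a[2]) - (a[4] - a[2]) * (b[1] - a[1])
    d4 <- (a[3] - a[1]) * (b[4] - a[2]) - (a[4] - a[2]) * (b[3] - a[1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  if (n > 60L) return(TRUE)  # O(n^2) guard; large rings accepted as-is
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      if (j == i + 1L || (i == 1L && j == n)) next
      if (inter(seg(i), seg(j))) return(FALSE)
    }
  }
  TRUE
}

setValidity("AnnotationSet", function(object) {
  for (p in object@polygons) {
    if (!is.list(p) || is.null(p$coords) || is.null(p$class)) {
      return("each polygon needs 'coords' and 'class'")
    }
    if (!p$class %in% c("lesion", "ignore")) {
      return("annotation class must be 'lesion' or 'ignore'")
    }
    if (!is.matrix(p$coords) || ncol(p$coords) != 2L || nrow(p$coords) < 3L) {
      return("polygon coords must be an n x 2 matrix with n >= 3")
    }
    if (!all(is.finite(p$coords))) return("polygon coords must be finite")
    if (!.isSimplePolygon(p$coords)) {
      return("polygons must be simple (non-self-intersecting)")
    }
  }
  TRUE
})

#' Construct an AnnotationSet
#'
#' @param polygons list of lists, each with \code{coords} (n x 2 matrix of
#'   (x, y) vertices, 0-based pixel-center frame) and \code{class}
#'   (\code{"lesion"} or \code{"ignore"}).
#' @return An [AnnotationSet-class] object.
#' @export
AnnotationSet <- function(polygons) new("AnnotationSet", polygons = polygons)

#' Trained binary pixel classifier with per-image checkpoints
#'
#' A multilayer perceptron over standardized multiscale pixel features. The
#' classifier is trained iteratively over the training images and a model
#' state (checkpoint) is retained after each image; [selectClassifier()]
#' picks the deployed iteration as the best compromise between detection
#' sensitivity and false positives (maximum pixel F1 on validation images).
#'
#' @slot checkpoints list of model states; each holds the nnet weight vector
#'   plus layer sizes and the number of training images seen.
#' @slot selectedIteration 1-based index of the deployed checkpoint.
#' @slot trainingSeed integer seed used for training.
#' @slot hyperparameters list: \code{hiddenUnits}, \code{maxEpochs},
#'   \code{decay}, \code{maxPixelsPerClass}.
#' @slot featureNames feature manifest; classification refuses mismatched
#'   stacks.
#' @slot scalesPx scale manifest.
#' @slot center,scale per-feature standardization statistics estimated from
#'   the training pixels.
#' @slot checkpointF1 validation F1 per checkpoint (NA before selection).
#' @exportClass PixelClassifier
setClass("PixelClassifier",
  representation(
    checkpoints = "list",
    selectedIteration = "integer",
    trainingSeed = "integer",
    hyperparameters = "list",
    featureNames = "character",
    scalesPx = "numeric",
    center = "numeric",
    scale = "numeric",
    checkpointF1 = "numeric"
  )
)

setValidity("PixelClassifier", function(object) {
  k <- length(object@checkpoints)
  if (k < 1L) return("at least one checkpoint required")
  if (object@selectedIteration < 1L || object@selectedIteration > k) {
    return("selectedIteration out of range")
  }
  if (length(object@center) != length(object@featureNames) ||
      length(object@scale) != length(object@featureNames)) {
    return("standardization statistics must match the feature manifest")
  }
  TRUE
})

#' Manually set region of interest with artefact exclusions
#'
#' The analysed muscle region: investigator-drawn include polygons (the
#' soleus outline) minus exclusion polygons (staining artefacts). Quantified
#' area is the number of included pixel centers times the squared pixel size.
#'
#' @slot includePolygons list of n x 2 (x, y) vertex matrices.
#' @slot excludePolygons list of n x 2 (x, y) vertex matrices (may be empty).
#' @exportClass RegionOfInterest
setClass("RegionOfInterest",
  representation(includePolygons = "list", excludePolygons = "list")
)

setValidity("RegionOfInterest", function(object) {
  chk <- function(lst, what) {
    for (m in lst) {
      if (!is.matrix(m) || ncol(m) != 2L || nrow(m) < 3L || !all(is.finite(m))) {
        return(sprintf("%s polygons must be finite n x 2 matrices (n >= 3)", what))
      }
    }
    NULL
  }
  msg <- chk(object@includePolygons, "include")
  if (!is.null(msg)) return(msg)
  msg <- chk(object@excludePolygons, "exclude")
  if (!is.null(msg)) return(msg)
  if (length(object@includePolygons) < 1L) {
    return("at least one include polygon required")
  }
  TRUE
})

#' Construct a RegionOfInterest
#'
#' @param includePolygons list of n x 2 (x, y) vertex matrices (or a single
#'   matrix) delimiting the analysed tissue.
#' @param excludePolygons optional list of artefact polygons subtracted from
#'   the mask.
#' @return A [RegionOfInterest-class] object.
#' @export
RegionOfInterest <- function(includePolygons, excludePolygons = list()) {
  if (is.matrix(includePolygons)) includePolygons <- list(includePolygons)
  if (is.matrix(excludePolygons)) excludePolygons <- list(excludePolygons)
  new("RegionOfInterest",
    includePolygons = includePolygons,
    excludePolygons = excludePolygons
  )
}

#' Lesion extraction configuration
#'
#' Size filters and pixel connectivity for connected-component lesion
#' extraction. Defaults follow the reference workflow: minimum detection
#' size 0.01 square micrometre (inclusive), macrolesion threshold 10 square
#' micrometres (strict), 8-neighbour connectivity.
#'
#' @slot minDetectionUm2 inclusive minimum component area in square
#'   micrometres.
#' @slot macroThresholdUm2 strict macrolesion area threshold in square
#'   micrometres.
#' @slot connectivity 4 or 8.
#' @exportClass QuantConfig
setClass("QuantConfig",
  representation(
    minDetectionUm2 = "numeric",
    macroThresholdUm2 = "numeric",
    connectivity = "integer"
  )
)

setValidity("QuantConfig", function(object) {
  if (object@minDetectionUm2 <= 0) return("minDetectionUm2 must be > 0")
  if (object@minDetectionUm2 >= object@macroThresholdUm2) {
    return("minDetectionUm2 must be < macroThresholdUm2")
  }
  if (!object@connectivity %in% c(4L, 8L)) return("connectivity must be 4 or 8")
  TRUE
})

#' Construct a QuantConfig
#'
#' @param minDetectionUm2 inclusive minimum lesion area (default 0.01).
#' @param macroThresholdUm2 strict macrolesion threshold (default 10).
#' @param connectivity pixel connectivity, 4 or 8 (default 8).
#' @return A [QuantConfig-class] object.
#' @export
QuantConfig <- function(minDetectionUm2 = 0.01, macroThresholdUm2 = 10,
                        connectivity = 8L) {
  new("QuantConfig",
    minDetectionUm2 = as.numeric(minDetectionUm2),
    macroThresholdUm2 = as.numeric(macroThresholdUm2),
    connectivity = as.integer(connectivity)
  )
}

#' Synthetic tissue specification
#'
#' Parameters of one simulated muscle cross-section: a textured fibre-mosaic
#' background, bright elliptical lesions placed by a homogeneous spatial
#' Poisson process inside a soleus-like region of interest, lesion areas
#' drawn from a two-component (micro/macro) lognormal mixture, followed by
#' point-spread-function blur and read noise. See the methods vignette for
#' the rationale behind each default.
#'
#' @slot fieldSizePx c(rows, cols) of the simulated field.
#' @slot pixelSizeUm pixel edge length in micrometres.
#' @slot lesionDensityPerMm2 target Poisson intensity, lesions per square
#'   millimetre of ROI.
#' @slot microMeanUm2,microSdLog mean (um^2) and log-sd of the microlesion
#'   area component.
#' @slot macroMeanUm2,macroSdLog mean (um^2) and log-sd of the macrolesion
#'   area component.
#' @slot macroWeight mixture weight of the macro component.
#' @slot lesionPeak expected added lesion intensity.
#' @slot backgroundLevel mean background (autofluorescence) intensity.
#' @slot backgroundCellAmplitude relative fibre-to-fibre level variation.
#' @slot textureAmplitude relative amplitude of smooth background texture.
#' @slot psfSigmaPx optics blur sigma in pixels.
#' @slot readNoiseSd Gaussian read-noise standard deviation.
#' @slot shotNoise logical, Poisson shot noise on or off.
#' @slot roiCoverage c(lo, hi) target ROI fraction of the field.
#' @slot nExcludeMax maximum number of artefact exclusion disks.
#' @slot seed integer RNG seed.
#' @exportClass TissueSpec
setClass("TissueSpec",
  representation(
    fieldSizePx = "integer",
    pixelSizeUm = "numeric",
    lesionDensityPerMm2 = "numeric",
    microMeanUm2 = "numeric",
    microSdLog = "numeric",
    macroMeanUm2 = "numeric",
    macroSdLog = "numeric",
    macroWeight = "numeric",
    lesionPeak = "numeric",
    backgroundLevel = "numeric",
    backgroundCellAmplitude = "numeric",
    textureAmplitude = "numeric",
    psfSigmaPx = "numeric",
    readNoiseSd = "numeric",
    shotNoise = "logical",
    roiCoverage = "numeric",
    nExcludeMax = "integer",
    seed = "integer"
  )
)

setValidity("TissueSpec", function(object) {
  if (length(object@fieldSizePx) != 2L || any(object@fieldSizePx < 8L)) {
    return("fieldSizePx must be two integers >= 8")
  }
  pos <- c(
    pixelSizeUm = object@pixelSizeUm,
    lesionDensityPerMm2 = object@lesionDensityPerMm2,
    microMeanUm2 = object@microMeanUm2, microSdLog = object@microSdLog,
    macroMeanUm2 = object@macroMeanUm2, macroSdLog = object@macroSdLog,
    psfSigmaPx = object@psfSigmaPx
  )
  if (any(!is.finite(pos)) || any(pos <= 0)) {
    return("pixel size, density, size-distribution and blur parameters must be positive")
  }
  if (object@macroWeight < 0 || object@macroWeight >= 1) {
    return("macroWeight must be in [0, 1)")
  }
  if (object@lesionPeak < 0 || object@backgroundLevel < 0 ||
      object@readNoiseSd < 0) {
    return("intensity parameters must be non-negative")
  }
  if (length(object@roiCoverage) != 2L || any(object@roiCoverage <= 0) ||
      any(object@roiCoverage >= 1) ||
      object@roiCoverage[1] > object@roiCoverage[2]) {
    return("roiCoverage must be 0 < lo <= hi < 1")
  }
  areaMm2 <- prod(object@fieldSizePx) * object@pixelSizeUm^2 * 1e-6
  if (!is.finite(object@lesionDensityPerMm2 * areaMm2)) {
    return("expected lesion count must be finite")
  }
  TRUE
})

#' Construct a TissueSpec
#'
#' @param fieldSizePx c(rows, cols) in pixels.
#' @param pixelSizeUm pixel size in micrometres (default 0.13).
#' @param lesionDensityPerMm2 lesions per square millimetre of ROI.
#' @param microMeanUm2,microSdLog microlesion area component (lognormal).
#' @param macroMeanUm2,macroSdLog macrolesion area component (lognormal).
#' @param macroWeight macro-component mixture weight.
#' @param lesionPeak added lesion intensity above background.
#' @param backgroundLevel mean background intensity.
#' @param backgroundCellAmplitude fibre-to-fibre level variation (relative).
#' @param textureAmplitude smooth texture amplitude (relative).
#' @param psfSigmaPx optics blur sigma (pixels).
#' @param readNoiseSd Gaussian read-noise SD.
#' @param shotNoise add Poisson shot noise.
#' @param roiCoverage target ROI fraction range of the field.
#' @param nExcludeMax maximum number of artefact exclusion disks (0 disables).
#' @param seed integer RNG seed.
#' @return A [TissueSpec-class] object.
#' @export
TissueSpec <- function(fieldSizePx = c(512L, 512L), pixelSizeUm = 0.13,
                       lesionDensityPerMm2 = 2000,
                       microMeanUm2 = 0.55, microSdLog = 0.8,
                       macroMeanUm2 = 18, macroSdLog = 0.5,
                       macroWeight = 0.012,
                       lesionPeak = 100, backgroundLevel = 20,
                       backgroundCellAmplitude = 0.25,
                       textureAmplitude = 0.1,
                       psfSigmaPx = 1, readNoiseSd = 4, shotNoise = FALSE,
                       roiCoverage = c(0.3, 0.7), nExcludeMax = 2L,
                       seed = 1L) {
  new("TissueSpec",
    fieldSizePx = as.integer(fieldSizePx), pixelSizeUm = pixelSizeUm,
    lesionDensityPerMm2 = lesionDensityPerMm2,
    microMeanUm2 = microMeanUm2, microSdLog = microSdLog,
    macroMeanUm2 = macroMeanUm2, macroSdLog = macroSdLog,
    macroWeight = macroWeight, lesionPeak = lesionPeak,
    backgroundLevel = backgroundLevel,
    backgroundCellAmplitude = backgroundCellAmplitude,
    textureAmplitude = textureAmplitude,
    psfSigmaPx = psfSigmaPx, readNoiseSd = readNoiseSd,
    shotNoise = shotNoise, roiCoverage = roiCoverage,
    nExcludeMax = as.integer(nExcludeMax), seed = as.integer(seed)
  )
}

#' Ground truth of a simulated tissue image
#'
#' The pre-blur lesion footprint together with the per-lesion ledger.
#' Because high-density regimes allow overlapping placements, the ledger is
#' recomputed from the merged mask (clipped to the ROI), so mask and ledger
#' are exactly consistent.
#'
#' @slot mask logical matrix, pre-blur lesion footprint.
#' @slot lesionAreasUm2 per-lesion calibrated areas from the merged mask.
#' @slot roiAreaUm2 included ROI area.
#' @slot pixelSizeUm calibration used.
#' @exportClass GroundTruth
setClass("GroundTruth",
  representation(
    mask = "matrix",
    lesionAreasUm2 = "numeric",
    roiAreaUm2 = "numeric",
    pixelSizeUm = "numeric"
  )
)

setValidity("GroundTruth", function(object) {
  if (!is.logical(object@mask)) return("mask must be logical")
  if (object@roiAreaUm2 <= 0) return("roiAreaUm2 must be positive")
  TRUE
})

## ---- accessors & show -------------------------------------------------

#' @describeIn FluorescenceImage intensity raster accessor
#' @param object,x a \code{FluorescenceImage}
#' @aliases pixels
#' @export
setGeneric("pixels", function(object) standardGeneric("pixels"))

#' @rdname FluorescenceImage-class
#' @export
setMethod("pixels", "FluorescenceImage", function(object) object@pixels)

#' @describeIn FluorescenceImage physical pixel size accessor
#' @aliases pixelSizeUm
#' @export
setGeneric("pixelSizeUm", function(object) standardGeneric("pixelSizeUm"))

#' @rdname FluorescenceImage-class
#' @export
setMethod("pixelSizeUm", "FluorescenceImage", function(object) object@pixelSizeUm)

#' @describeIn FluorescenceImage sample identifier accessor
#' @aliases sampleId
#' @export
setGeneric("sampleId", function(object) standardGeneric("sampleId"))

#' @rdname FluorescenceImage-class
#' @export
setMethod("sampleId", "FluorescenceImage", function(object) object@sampleId)

#' @rdname FluorescenceImage-class
#' @export
setMethod("dim", "FluorescenceImage", function(x) dim(x@pixels))

setMethod("show", "FluorescenceImage", function(object) {
  d <- dim(object@pixels)
  cat(sprintf(
    "FluorescenceImage '%s': %d x %d px @ %.4g um/px (%.4g x %.4g um)\n",
    object@sampleId, d[1], d[2], object@pixelSizeUm,
    d[1] * object@pixelSizeUm, d[2] * object@pixelSizeUm
  ))
  invisible(NULL)
})

#' @describeIn FeatureStack feature channel names
#' @param object a \code{FeatureStack}
#' @aliases featureNames
#' @export
setGeneric("featureNames", function(object) standardGeneric("featureNames"))

#' @rdname FeatureStack-class
#' @export
setMethod("featureNames", "FeatureStack", function(object) object@featureNames)

#' @describeIn FeatureStack smoothing scales (pixels)
#' @aliases scalesPx
#' @export
setGeneric("scalesPx", function(object) standardGeneric("scalesPx"))

#' @rdname FeatureStack-class
#' @export
setMethod("scalesPx", "FeatureStack", function(object) object@scalesPx)

#' @rdname FeatureStack-class
#' @param x a \code{FeatureStack}
#' @export
setMethod("dim", "FeatureStack", function(x) dim(x@features))

#' Feature matrix view of a stack
#'
#' Flattens a [FeatureStack-class] to an (n pixels) x (n features) matrix in
#' column-major pixel order, the layout consumed by the classifier.
#'
#' @param stack a \code{FeatureStack}.
#' @return numeric matrix with one row per pixel.
#' @export
featureMatrix <- function(stack) {
  d <- dim(stack@features)
  m <- stack@features
  dim(m) <- c(d[1] * d[2], d[3])
  colnames(m) <- stack@featureNames
  m
}

setMethod("show", "FeatureStack", function(object) {
  d <- dim(object@features)
  cat(sprintf(
    "FeatureStack: %d x %d px, %d channels (%d scales: %s)\n",
    d[1], d[2], d[3], length(object@scalesPx),
    paste(object@scalesPx, collapse = ", ")
  ))
  invisible(NULL)
})

#' Annotation object counts per class
#'
#' @param annots an [AnnotationSet-class].
#' @return named integer vector with counts for \code{lesion} and
#'   \code{ignore}.
#' @export
annotationCounts <- function(annots) {
  cls <- vapply(annots@polygons, function(p) p$class, character(1))
  c(
    lesion = sum(cls == "lesion"),
    ignore = sum(cls == "ignore")
  )
}

setMethod("show", "AnnotationSet", function(object) {
  ct <- annotationCounts(object)
  cat(sprintf(
    "AnnotationSet: %d polygons (%d lesion, %d ignore)\n",
    length(object@polygons), ct["lesion"], ct["ignore"]
  ))
  invisible(NULL)
})

#' @describeIn PixelClassifier index of the deployed checkpoint
#' @param object a \code{PixelClassifier}
#' @aliases selectedIteration
#' @export
setGeneric("selectedIteration", function(object) standardGeneric("selectedIteration"))

#' @rdname PixelClassifier-class
#' @export
setMethod("selectedIteration", "PixelClassifier", function(object) {
  object@selectedIteration
})

#' @describeIn PixelClassifier number of training checkpoints
#' @aliases nCheckpoints
#' @export
setGeneric("nCheckpoints", function(object) standardGeneric("nCheckpoints"))

#' @rdname PixelClassifier-class
#' @export
setMethod("nCheckpoints", "PixelClassifier", function(object) {
  length(object@checkpoints)
})

setMethod("show", "PixelClassifier", function(object) {
  cat(sprintf(
    "PixelClassifier: %d checkpoints, selected #%d; %d features, hidden = %d, seed = %d\n",
    length(object@checkpoints), object@selectedIteration,
    length(object@featureNames), object@hyperparameters$hiddenUnits,
    object@trainingSeed
  ))
  if (any(is.finite(object@checkpointF1))) {
    cat("  validation F1:",
        paste(sprintf("%.3f", object@checkpointF1), collapse = ", "), "\n")
  }
  invisible(NULL)
})

setMethod("show", "RegionOfInterest", function(object) {
  cat(sprintf(
    "RegionOfInterest: %d include / %d exclude polygon(s)\n",
    length(object@includePolygons), length(object@excludePolygons)
  ))
  invisible(NULL)
})

setMethod("show", "QuantConfig", function(object) {
  cat(sprintf(
    "QuantConfig: min detection >= %.3g um^2, macro > %.3g um^2, %d-connectivity\n",
    object@minDetectionUm2, object@macroThresholdUm2, object@connectivity
  ))
  invisible(NULL)
})

setMethod("show", "TissueSpec", function(object) {
  cat(sprintf(
    "TissueSpec: %d x %d px @ %.3g um/px, %.4g lesions/mm^2, macro weight %.3g, seed %d\n",
    object@fieldSizePx[1], object@fieldSizePx[2], object@pixelSizeUm,
    object@lesionDensityPerMm2, object@macroWeight, object@seed
  ))
  invisible(NULL)
})

setMethod("show", "GroundTruth", function(object) {
  cat(sprintf(
    "GroundTruth: %d lesions, ROI %.4g um^2 (density %.4g /mm^2)\n",
    length(object@lesionAreasUm2), object@roiAreaUm2,
    length(object@lesionAreasUm2) / (object@roiAreaUm2 * 1e-6)
  ))
  invisible(NULL)
})
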